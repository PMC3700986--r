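# Hybrid Gibbs + Metropolis-Hastings sampler over (Z, theta, gamma), with an
# exact-enumeration oracle and convergence diagnostics.

#' Sampler configuration
#'
#' Defaults mirror the full protocol (10000 burn-in, 50000 kept, 2 chains);
#' pass smaller values for desk-scale runs.
#'
#' @param burn_in,kept iteration counts (both positive).
#' @param chains number of independent chains.
#' @param seed integer seed; chain `i` uses `seed + i - 1`.
#' @param move_probs probabilities of the four move types (add-pathway,
#'   remove-pathway, toggle-gene, swap-genes); must sum to one.
#' @param store_every thinning interval for stored indicator draws (0 disables
#'   storage; marginal probabilities always use every kept iteration).
#' @param mh_per_sweep number of Metropolis-Hastings indicator updates per
#'   Gibbs sweep of the latent vector.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(burn_in = 10000, kept = 50000, chains = 2, seed = 1,
                           move_probs = c(0.2, 0.2, 0.4, 0.2),
                           store_every = max(1L, floor(kept / 500)),
                           mh_per_sweep = 10) {
  stopifnot(burn_in > 0, kept > 0, chains >= 1, mh_per_sweep >= 1,
            abs(sum(move_probs) - 1) < 1e-8)
  structure(list(burn_in = as.integer(burn_in), kept = as.integer(kept),
                 chains = as.integer(chains), seed = as.integer(seed),
                 move_probs = move_probs, store_every = as.integer(store_every),
                 mh_per_sweep = as.integer(mh_per_sweep)),
            class = "sampler_config")
}

# pathway membership as list of integer vectors + neighbor lists, for C++
.sampler_structure <- function(structure) {
  S <- structure$S
  R <- structure$R
  pw <- lapply(seq_len(ncol(S)), function(k) which(S[, k] == 1L))
  nbr <- lapply(seq_len(nrow(S)), function(j) which(R[j, ] == 1L))
  list(pathways = pw, neighbors = nbr)
}

.check_xy <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both phenotype classes must be present")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  list(X = X, y = y)
}

#' Run the iBVS sampler
#'
#' Alternates one full truncated-normal Gibbs sweep of the latent probit
#' vector `Z` with one Metropolis-Hastings update of the pathway/gene
#' indicators (add-pathway, remove-pathway, toggle-gene, or within-pathway
#' swap; proposals violating the validity constraints are rejected).  The
#' pathway-level likelihood uses the integrated PLS g-prior form of
#' [log_marginal_Z()].
#'
#' @param X standardized n x p expression matrix.
#' @param y 0/1 phenotype vector.
#' @param structure a [pathway_structure()].
#' @param hyper an [ibvs_hyper()]; `c = NULL` resolves to `nrow(X)`.
#' @param config a [sampler_config()].
#' @return object of class `ibvs_draws`: pooled and per-chain gene/pathway
#'   inclusion frequencies, log-posterior and model-size traces, acceptance
#'   counts per move type, thinned indicator draws, and the configuration.
#' @export
run_chain <- function(X, y, structure, hyper = ibvs_hyper(),
                      config = sampler_config()) {
  xy <- .check_xy(X, y)
  cc <- if (is.null(hyper$c)) nrow(xy$X) else hyper$c
  ss <- .sampler_structure(structure)
  chains <- vector("list", config$chains)
  for (i in seq_len(config$chains)) {
    set.seed(config$seed + i - 1L)
    chains[[i]] <- cpp_run_ibvs(xy$X, xy$y, ss$pathways, ss$neighbors,
                                cc, hyper$h, hyper$d, hyper$f, hyper$pi_theta,
                                config$move_probs, config$burn_in, config$kept,
                                config$store_every, config$mh_per_sweep)
  }
  gene_freq <- rowMeans(sapply(chains, `[[`, "gene_freq"))
  pathway_freq <- rowMeans(sapply(chains, `[[`, "pathway_freq"))
  names(gene_freq) <- structure$gene_ids
  names(pathway_freq) <- structure$pathway_ids
  structure(list(
    gene_freq = gene_freq, pathway_freq = pathway_freq,
    chains = chains,
    logpost = sapply(chains, `[[`, "logpost"),
    model_size = sapply(chains, `[[`, "model_size"),
    accepted = Reduce(`+`, lapply(chains, `[[`, "accepted")),
    proposed = Reduce(`+`, lapply(chains, `[[`, "proposed")),
    stuck = sum(sapply(chains, `[[`, "stuck")),
    invalid = sum(sapply(chains, `[[`, "invalid")),
    gene_ids = structure$gene_ids, pathway_ids = structure$pathway_ids,
    method = "ibvs", config = config, hyper = hyper), class = "ibvs_draws")
}

#' @export
print.ibvs_draws <- function(x, ...) {
  cat(sprintf("ibvs_draws (%s): %d chain(s) x %d kept iterations\n",
              x$method, ncol(x$logpost), nrow(x$logpost)))
  cat("acceptance by move type:",
      paste(sprintf("%.2f", x$accepted / pmax(x$proposed, 1)), collapse = " "),
      "\n")
  top <- sort(x$gene_freq, decreasing = TRUE)
  cat("top genes:", paste(sprintf("%s=%.2f", names(head(top, 5)), head(top, 5)),
                          collapse = " "), "\n")
  invisible(x)
}

#' One Gibbs sweep of the latent probit utilities
#'
#' Updates each `Z[i]` from its univariate conditional
#' `N(mu_i, 1/Omega_ii)` truncated to `(0, Inf)` when `y[i] = 1` and to
#' `(-Inf, 0]` otherwise, with `Omega` the precision of the integrated
#' covariance `Sigma = h 11' + I + c P_T`.
#'
#' @param Z current latent vector (sign-feasible).
#' @param y 0/1 outcomes.
#' @param Sigma covariance matrix (used only when `Omega` is missing).
#' @param Omega optional precision matrix.
#' @return updated latent vector.
#' @export
sample_Z_gibbs <- function(Z, y, Sigma = NULL, Omega = NULL) {
  if (is.null(Omega)) Omega <- solve(Sigma)
  out <- cpp_z_sweep(as.numeric(Z), as.integer(y), Omega)
  if (any(!is.finite(out))) stop("non-finite latent draw (numerical blow-up)")
  out
}

#' Propose a constrained move on the selection indicators
#'
#' Picks one of four move types (probabilities `move_probs`): add an
#' unselected pathway together with a random nonempty subset of its genes not
#' reachable through other selected pathways; remove a selected pathway and
#' the genes selected only through it; toggle one gene inside the selected
#' pathways; or swap a selected and an unselected gene within one selected
#' pathway.  Toggles/swaps that violate the validity constraints are flagged
#' `invalid` (they are rejected by [mh_step()]).
#'
#' @param state a [selection_state()].
#' @param structure a [pathway_structure()].
#' @param move_probs move-type probabilities.
#' @return list with the proposed `state`, `type` (1-4), `stuck`, `invalid`,
#'   and log forward/reverse proposal densities `log_q_fwd`, `log_q_rev`.
#' @export
propose_move <- function(state, structure, move_probs = c(0.2, 0.2, 0.4, 0.2)) {
  ss <- .sampler_structure(structure)
  out <- cpp_propose(state$theta, state$gamma, ss$pathways, ss$neighbors,
                     move_probs)
  list(state = selection_state(out$theta, out$gamma), type = out$type,
       stuck = out$stuck, invalid = out$invalid,
       log_q_fwd = out$log_q_fwd, log_q_rev = out$log_q_rev)
}

#' One Metropolis-Hastings update of (theta, gamma)
#'
#' Accepts a [propose_move()] proposal with probability
#' `min(1, exp(delta log-marginal + delta log-prior + log proposal ratio))`.
#'
#' @param state current [selection_state()].
#' @param Z current latent vector.
#' @param X standardized expression matrix.
#' @param y 0/1 outcomes.
#' @param structure a [pathway_structure()].
#' @param hyper an [ibvs_hyper()].
#' @param move_probs move-type probabilities.
#' @return list with the `state` after the step, `accepted`, and the proposal.
#' @export
mh_step <- function(state, Z, X, y, structure, hyper = ibvs_hyper(),
                    move_probs = c(0.2, 0.2, 0.4, 0.2)) {
  cc <- if (is.null(hyper$c)) nrow(X) else hyper$c
  r <- y - mean(y)
  prop <- propose_move(state, structure, move_probs)
  if (prop$stuck || prop$invalid) {
    return(list(state = state, accepted = FALSE, proposal = prop))
  }
  lp_new <- joint_log_prior(prop$state, structure, hyper = hyper)
  if (!is.finite(lp_new)) {
    return(list(state = state, accepted = FALSE, proposal = prop))
  }
  lp_cur <- joint_log_prior(state, structure, hyper = hyper)
  lm_cur <- log_marginal_Z(Z, build_design(X, state, structure, r), cc, hyper$h)
  lm_new <- log_marginal_Z(Z, build_design(X, prop$state, structure, r), cc, hyper$h)
  la <- (lm_new + lp_new) - (lm_cur + lp_cur) + (prop$log_q_rev - prop$log_q_fwd)
  acc <- la >= 0 || log(runif(1)) < la
  list(state = if (acc) prop$state else state, accepted = acc, proposal = prop)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' @param chains matrix (iterations x chains) or list of equal-length numeric
#'   vectors of a scalar statistic, from at least two chains.
#' @return R-hat; `NaN` with a warning when the within-chain variance is zero.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2L || n < 10L) stop("need >= 2 chains of length >= 10")
  W <- mean(apply(chains, 2L, var))
  B <- n * var(colMeans(chains))
  if (W == 0) {
    warning("zero within-chain variance; R-hat undefined")
    return(NaN)
  }
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}

# GHK estimator of P(Z in the orthant implied by y) for Z ~ N(0, Sigma).
.ghk_orthant <- function(Sigma, y, nsim = 4000) {
  n <- length(y)
  L <- t(chol(Sigma))
  eta <- matrix(0, nsim, n)
  logw <- numeric(nsim)
  for (i in seq_len(n)) {
    mu <- if (i > 1) eta[, seq_len(i - 1), drop = FALSE] %*% L[i, seq_len(i - 1)] else
      numeric(nsim)
    a <- -drop(mu) / L[i, i]       # eta_i > a gives z_i > 0
    if (y[i] == 1) {
      pr <- pnorm(a, lower.tail = FALSE)
      u <- runif(nsim)
      eta[, i] <- qnorm(pmin(1 - .eps, pnorm(a) + u * pr))
    } else {
      pr <- pnorm(a)
      u <- runif(nsim)
      eta[, i] <- qnorm(pmax(.eps, u * pr))
    }
    logw <- logw + log(pmax(pr, 1e-300))
  }
  mx <- max(logw)
  exp(mx) * mean(exp(logw - mx))
}

#' Exact posterior over all valid configurations (testing oracle)
#'
#' Enumerates every valid `(theta, gamma)` pair, scores it by the joint log
#' prior plus the log probability that `Z ~ N(0, Sigma(theta, gamma))` falls in
#' the orthant implied by `y` (GHK estimator with a fixed inner sample), and
#' normalizes.  Only feasible for small systems.
#'
#' @param X standardized expression matrix.
#' @param y 0/1 outcomes.
#' @param structure a [pathway_structure()].
#' @param hyper an [ibvs_hyper()].
#' @param nsim inner GHK sample size.
#' @param seed RNG seed for the inner sample.
#' @param max_states guard on the enumeration size.
#' @return list with `gene_prob`, `pathway_prob`, and the full `table`
#'   (`theta`, `gamma`, posterior probability).
#' @export
enumerate_posterior <- function(X, y, structure, hyper = ibvs_hyper(),
                                nsim = 4000, seed = 1, max_states = 2^16) {
  xy <- .check_xy(X, y)
  cc <- if (is.null(hyper$c)) nrow(xy$X) else hyper$c
  S <- structure$S
  K <- ncol(S)
  p <- nrow(S)
  r <- xy$y - mean(xy$y)
  set.seed(seed)
  states <- list()
  for (tcode in 0:(2^K - 1)) {
    theta <- as.integer(intToBits(tcode)[1:K])
    memb <- if (any(theta == 1L)) which(rowSums(S[, theta == 1L, drop = FALSE]) > 0) else
      integer(0)
    m <- length(memb)
    if (2^m * 2^K > max_states * 4) stop("state space too large to enumerate")
    for (gcode in 0:(2^m - 1)) {
      gamma <- integer(p)
      if (m > 0) gamma[memb] <- as.integer(intToBits(gcode)[1:m])
      st <- selection_state(theta, gamma)
      if (!is_valid_configuration(st, S)$valid) next
      states[[length(states) + 1L]] <- st
    }
  }
  if (length(states) > max_states) stop("state space too large to enumerate")
  logp <- vapply(states, function(st) {
    lp <- joint_log_prior(st, structure, hyper = hyper)
    T <- build_design(xy$X, st, structure, r)
    Q <- .orth(T)
    n <- nrow(xy$X)
    Sig <- hyper$h * matrix(1, n, n) + diag(n)
    if (ncol(Q) > 0) Sig <- Sig + cc * tcrossprod(Q)
    lp + log(max(.ghk_orthant(Sig, xy$y, nsim), 1e-300))
  }, numeric(1))
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  gene_prob <- setNames(numeric(p), structure$gene_ids)
  pw_prob <- setNames(numeric(K), structure$pathway_ids)
  for (i in seq_along(states)) {
    gene_prob <- gene_prob + w[i] * states[[i]]$gamma
    pw_prob <- pw_prob + w[i] * states[[i]]$theta
  }
  list(gene_prob = gene_prob, pathway_prob = pw_prob,
       table = data.frame(
         theta = vapply(states, function(s) paste(s$theta, collapse = ""), ""),
         gamma = vapply(states, function(s) paste(s$gamma, collapse = ""), ""),
         prob = w))
}
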