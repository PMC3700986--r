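# Probability model: PLS design construction, PLS g-prior, MRF and Bernoulli
# priors, and the integrated marginal likelihood of the latent probit vector.

#' First partial-least-squares component of a gene submatrix
#'
#' The PLS direction is `w = X'r / ||X'r||` and the (un-normalized) score is
#' `t = X w`: the projection of the samples onto the direction of maximal
#' covariance with the response.  When `X'r` vanishes the first principal
#' component direction is used instead (with a message).
#'
#' @param X_sub n x m matrix of standardized gene columns.
#' @param r length-n centered response vector.
#' @return length-n score vector.
#' @export
pls_first_component <- function(X_sub, r) {
  X_sub <- as.matrix(X_sub)
  stopifnot(ncol(X_sub) >= 1L, nrow(X_sub) == length(r))
  w <- drop(crossprod(X_sub, r))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {
    message("degenerate PLS direction; falling back to first principal component")
    v <- svd(X_sub)$v[, 1]
    return(drop(X_sub %*% v))
  }
  drop(X_sub %*% (w / nw))
}

#' Build the pathway-level design matrix for a selection state
#'
#' One column per selected pathway (ascending pathway order): the first PLS
#' component of the submatrix of that pathway's *selected* genes against the
#' centered response.  Genes shared between selected pathways contribute to
#' every pathway containing them.
#'
#' @param X standardized n x p expression matrix.
#' @param state valid [selection_state()].
#' @param S p x K membership matrix or `pathway_structure`.
#' @param r length-n centered response (observed phenotype minus its mean).
#' @return n x k matrix (k = number of selected pathways) with attribute
#'   `"pathways"` mapping columns to pathway indices.
#' @export
build_design <- function(X, state, S, r) {
  if (inherits(S, "pathway_structure")) S <- S$S
  v <- is_valid_configuration(state, S)
  if (!v$valid) stop("invalid selection state (constraint ", v$code, ")")
  sel_pw <- which(state$theta == 1L)
  cols <- lapply(sel_pw, function(k) {
    idx <- which(S[, k] == 1L & state$gamma == 1L)
    pls_first_component(X[, idx, drop = FALSE], r)
  })
  T <- if (length(cols)) do.call(cbind, cols) else matrix(0, nrow(X), 0)
  attr(T, "pathways") <- sel_pw
  T
}

#' PLS g-prior covariance of pathway-level effects
#'
#' Returns `c * (T'T)^+`, the generalized g-prior covariance with the
#' Moore-Penrose pseudo-inverse in place of the ordinary inverse, so the prior
#' is well defined for any design (including rank-deficient ones).
#'
#' @param T n x k design matrix.
#' @param c positive g-prior scale.
#' @return k x k covariance matrix.
#' @export
pls_gprior_covariance <- function(T, c) {
  stopifnot(c > 0)
  c * .pinv(crossprod(T))
}

#' MRF (Ising) log prior mass of a gene selection vector
#'
#' Unnormalized log mass `d * sum(gamma) + f * sum(gamma_j gamma_l)` where the
#' pair sum runs over network edges whose endpoints share a selected pathway.
#' Genes outside every selected pathway are fixed at zero by the validity
#' constraints and contribute nothing.  Invalid states get `-Inf`.
#'
#' @param state a [selection_state()].
#' @param R p x p adjacency.
#' @param S p x K membership.
#' @param d,f MRF sparsity / smoothing parameters.
#' @return log mass (unnormalized).
#' @export
mrf_log_prior <- function(state, R, S, d, f) {
  if (inherits(S, "pathway_structure")) { R <- S$R; S <- S$S }
  if (!is_valid_configuration(state, S)$valid) return(-Inf)
  gamma <- state$gamma
  sel <- which(gamma == 1L)
  edges <- 0
  for (j in sel) {
    nb <- neighbors_within_selected(j, state, R, S)
    edges <- edges + sum(gamma[nb[nb > j]])
  }
  d * length(sel) + f * edges
}

#' Independent Bernoulli log prior of the pathway indicators
#'
#' @param theta length-K 0/1 vector.
#' @param pi_theta prior pathway inclusion probability in (0,1).
#' @return log prior mass.
#' @export
theta_log_prior <- function(theta, pi_theta) {
  stopifnot(pi_theta > 0, pi_theta < 1)
  sum(theta * log(pi_theta) + (1 - theta) * log(1 - pi_theta))
}

#' Joint log prior over (theta, gamma)
#'
#' Sum of [theta_log_prior()] and [mrf_log_prior()] on valid configurations;
#' `-Inf` (zero mass) otherwise.
#'
#' @param state a [selection_state()].
#' @param S membership matrix or `pathway_structure`.
#' @param R adjacency (ignored when `S` is a `pathway_structure`).
#' @param hyper an [ibvs_hyper()].
#' @return log prior mass.
#' @export
joint_log_prior <- function(state, S, R = NULL, hyper = ibvs_hyper()) {
  if (inherits(S, "pathway_structure")) { R <- S$R; S <- S$S }
  if (!is_valid_configuration(state, S)$valid) return(-Inf)
  theta_log_prior(state$theta, hyper$pi_theta) +
    mrf_log_prior(state, R, S, hyper$d, hyper$f)
}

#' Integrated log marginal density of the latent probit vector
#'
#' With the intercept and pathway effects integrated out, the latent vector is
#' `Z ~ N(0, Sigma)` with `Sigma = h 11' + I + c P_T`, where `P_T` is the
#' orthogonal projector onto the column space of the design `T`.  Evaluated in
#' the low-rank eigen form (eigenvalue `1 + c` on `col(T)`, Sherman-Morrison
#' for the rank-one intercept term) rather than via a dense factorization.
#'
#' @param Z length-n latent vector.
#' @param T n x k design matrix (zero columns for the null model).
#' @param c g-prior scale.
#' @param h intercept prior variance.
#' @return log density.
#' @export
log_marginal_Z <- function(Z, T, c, h) {
  n <- length(Z)
  Q <- .orth(as.matrix(T))
  k <- ncol(Q)
  cc <- c / (1 + c)
  u <- if (k > 0) rep(1, n) - cc * drop(Q %*% crossprod(Q, rep(1, n))) else rep(1, n)
  s <- 1 + h * sum(u)
  logdet <- k * log1p(c) + log(s)
  quad <- sum(Z^2)
  if (k > 0) quad <- quad - cc * sum(crossprod(Q, Z)^2)
  quad <- quad - (h / s) * sum(u * Z)^2
  -0.5 * (n * log(2 * pi) + logdet + quad)
}
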