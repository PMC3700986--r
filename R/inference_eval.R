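# Posterior summaries, cross-validated marker-count selection, ROC/AUC
# evaluation, and the gene-only YS-BVS baseline.

#' Marginal selection probabilities from posterior draws
#'
#' Per-gene and per-pathway inclusion frequencies across kept draws (Bayesian
#' model averaging).  A list of draws objects (replicate datasets) is averaged
#' element-wise.
#'
#' @param draws an `ibvs_draws` object or a list of them.
#' @return list with `gene` and `pathway` named probability vectors (the
#'   `pathway` element is `NULL` for gene-only baselines).
#' @export
marginal_selection_probs <- function(draws) {
  if (inherits(draws, "ibvs_draws")) draws <- list(draws)
  avg <- function(field, ids) {
    m <- matrix(unlist(lapply(draws, `[[`, field)), ncol = length(draws))
    setNames(rowMeans(m), ids)
  }
  gene <- avg("gene_freq", draws[[1]]$gene_ids)
  pathway <- if (!is.null(draws[[1]]$pathway_freq)) {
    avg("pathway_freq", draws[[1]]$pathway_ids)
  }
  list(gene = gene, pathway = pathway)
}

# Ridge-stabilized logistic regression (Newton/IRLS with a small L2 penalty on
# the slopes) so the cross-validation curve never crashes under separation.
.ridge_logistic <- function(x, y, lambda = 1e-2, maxit = 50, tol = 1e-8) {
  X1 <- cbind(1, as.matrix(x))
  q <- ncol(X1)
  pen <- diag(c(0, rep(lambda, q - 1L)), q)
  b <- numeric(q)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    H <- crossprod(X1, X1 * w) + pen
    g <- crossprod(X1, y - mu) - pen %*% b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

.predict_logistic <- function(b, x) plogis(drop(cbind(1, as.matrix(x)) %*% b))

#' Cross-validated selection of the marker-count cutoff
#'
#' Starting from the top-ranked gene, genes are added one at a time (up to
#' `max_size`).  Each repeat draws an ordered pair of distinct replicate
#' datasets, fits a ridge-stabilized logistic model with the current top genes
#' on the first and measures the misclassification rate (threshold 0.5) on
#' the second.  Errors are averaged over repeats; the best size is the
#' smallest minimizer.
#'
#' @param datasets list of replicate datasets, each with elements `X` and `y`
#'   (e.g. [build_scenario()] outputs).
#' @param ranking gene indices ordered by decreasing posterior probability.
#' @param max_size largest model size examined (default 30).
#' @param repeats number of random train/test pairs (default 200).
#' @param seed RNG seed.
#' @return list with `error` (mean misclassification per size) and
#'   `best_size`.
#' @export
cv_model_size <- function(datasets, ranking, max_size = 30, repeats = 200,
                          seed = 1) {
  stopifnot(length(datasets) >= 2L)
  set.seed(seed)
  max_size <- min(max_size, length(ranking))
  err <- matrix(NA_real_, repeats, max_size)
  for (rep_i in seq_len(repeats)) {
    pair <- sample(length(datasets), 2L)        # ordered pair, no replacement
    tr <- datasets[[pair[1]]]
    te <- datasets[[pair[2]]]
    for (m in seq_len(max_size)) {
      idx <- ranking[seq_len(m)]
      b <- .ridge_logistic(tr$X[, idx, drop = FALSE], tr$y)
      pred <- .predict_logistic(b, te$X[, idx, drop = FALSE]) > 0.5
      err[rep_i, m] <- mean(pred != (te$y == 1L))
    }
  }
  mean_err <- colMeans(err)
  list(error = mean_err, best_size = which.min(mean_err))
}

#' ROC curve and AUC for gene selection scores
#'
#' Sweeps thresholds over the scores; the trapezoid AUC equals the
#' Mann-Whitney statistic with tied scores averaged.
#'
#' @param scores per-gene selection scores (e.g. marginal probabilities).
#' @param labels 0/1 causal labels.
#' @return list with `roc` (data frame of FPR/TPR points) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both label classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse tied scores into single threshold steps
  last <- rev(!duplicated(rev(s)))
  tp <- cumsum(l)[last]
  fp <- cumsum(1L - l)[last]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Gene-only Bayesian variable selection baseline (YS-BVS)
#'
#' Probit BVS that ignores pathway membership and the gene network: the prior
#' on the selected coefficients is `N(0, c (X_g' X_g)^+)` on the raw selected
#' columns (generalized-inverse g-prior, no PLS summarization), gene
#' indicators are independent Bernoulli, and the sampler combines gene
#' add/remove/swap Metropolis-Hastings moves with the same truncated-normal
#' Gibbs sweep of the latent utilities.
#'
#' @param X standardized n x p expression matrix.
#' @param y 0/1 phenotype vector.
#' @param hyper an [ibvs_hyper()]; `gene_rate` defaults to `plogis(hyper$d)`,
#'   the MRF's isolated-gene inclusion rate, for a comparable prior.
#' @param config a [sampler_config()] (`move_probs` reinterpreted as
#'   add/remove/swap, renormalized over the first three entries).
#' @param gene_rate prior gene inclusion probability.
#' @return object of class `ibvs_draws` with `method = "ys_bvs"` (gene
#'   marginals only).
#' @export
ys_bvs_run <- function(X, y, hyper = ibvs_hyper(), config = sampler_config(),
                       gene_rate = plogis(hyper$d)) {
  xy <- .check_xy(X, y)
  cc <- if (is.null(hyper$c)) nrow(xy$X) else hyper$c
  mp <- c(0.35, 0.35, 0.30)
  ids <- colnames(xy$X)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(xy$X)))
  chains <- vector("list", config$chains)
  for (i in seq_len(config$chains)) {
    set.seed(config$seed + i - 1L)
    chains[[i]] <- cpp_run_ys(xy$X, xy$y, cc, hyper$h, gene_rate, mp,
                              config$burn_in, config$kept, config$store_every)
  }
  gene_freq <- rowMeans(sapply(chains, `[[`, "gene_freq"))
  names(gene_freq) <- ids
  structure(list(
    gene_freq = gene_freq, pathway_freq = NULL, chains = chains,
    logpost = sapply(chains, `[[`, "logpost"),
    model_size = sapply(chains, `[[`, "model_size"),
    accepted = Reduce(`+`, lapply(chains, `[[`, "accepted")),
    proposed = Reduce(`+`, lapply(chains, `[[`, "proposed")),
    stuck = sum(sapply(chains, `[[`, "stuck")), invalid = 0L,
    gene_ids = ids, pathway_ids = NULL,
    method = "ys_bvs", config = config, hyper = hyper), class = "ibvs_draws")
}
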