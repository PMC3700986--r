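# Shared fixtures: a tiny two-pathway system and independent oracles.

# 4 genes in 2 pathways ({g1,g2}, {g3,g4}) with one network edge per pathway.
toy_structure <- function() {
  R <- matrix(0L, 4, 4)
  R[1, 2] <- R[2, 1] <- 1L
  R[3, 4] <- R[4, 3] <- 1L
  pathway_structure(list(pwA = c("g1", "g2"), pwB = c("g3", "g4")),
                    adjacency = R, gene_ids = paste0("g", 1:4))
}

toy_data <- function(n = 14, beta = c(1.5, 0, 0, 0), xseed = 5, yseed = 6) {
  set.seed(xseed)
  X <- standardize_expression(
    matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("g", 1:4))))
  list(X = X, y = simulate_outcome(X, beta, seed = yseed)$y)
}

# Iterative NIPALS extraction of the first PLS component (independent of the
# closed-form implementation under test).
nipals_first <- function(X, y, maxit = 200, tol = 1e-12) {
  u <- y
  w_old <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    w <- drop(crossprod(X, u))
    w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    q <- sum(t * y) / sum(t^2)
    u <- y * q
    if (sum((w - w_old)^2) < tol) break
    w_old <- w
  }
  drop(X %*% w)
}

# Exact hypergeometric tail by enumerating all draws of size n from N.
hyper_tail_enum <- function(N, K, n, x) {
  draws <- combn(N, n)
  inK <- colSums(draws <= K)     # treat items 1..K as pathway members
  mean(inK >= x)
}

# AUC by brute-force pair counting (ties count half).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Rejection sampler for a truncated multivariate normal (orthant given y).
rtmvn_reject <- function(Sigma, y, nkeep = 2000, seed = 1) {
  set.seed(seed)
  L <- t(chol(Sigma))
  n <- length(y)
  out <- matrix(NA_real_, 0, n)
  while (nrow(out) < nkeep) {
    Z <- t(L %*% matrix(rnorm(n * 5000), n))
    ok <- rowSums(sweep(Z > 0, 2, y == 1, `==`)) == n
    out <- rbind(out, Z[ok, , drop = FALSE])
  }
  out[seq_len(nkeep), , drop = FALSE]
}
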