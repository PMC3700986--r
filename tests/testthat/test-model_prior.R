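test_that("first PLS component matches its closed form and a NIPALS oracle", {
  set.seed(1)
  n <- 40
  r <- rnorm(n); r <- r - mean(r)
  # single column: score proportional to the column
  x1 <- rnorm(n)
  t1 <- pls_first_component(cbind(x1), r)
  expect_equal(abs(cor(t1, x1)), 1, tolerance = 1e-12)
  # orthogonal columns with r aligned to the first
  q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  t2 <- pls_first_component(q, q[, 1])
  expect_equal(abs(cor(t2, q[, 1])), 1, tolerance = 1e-10)
  # NIPALS agreement up to sign on random matrices
  for (i in 1:5) {
    X <- matrix(rnorm(n * 6), n, 6)
    a <- pls_first_component(X, r)
    b <- nipals_first(X, r)
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  # degenerate direction falls back to the first principal component
  X0 <- matrix(rnorm(n * 2), n, 2)
  r0 <- residuals(lm(rnorm(n) ~ X0))          # orthogonal to both columns
  expect_message(pls_first_component(X0, r0 * 1e-14), "principal component")
})

test_that("design matrix has one PLS column per selected pathway", {
  st <- toy_structure()
  td <- toy_data(n = 30)
  r <- td$y - mean(td$y)
  null_T <- build_design(td$X, selection_state(c(0, 0), rep(0, 4)), st, r)
  expect_equal(ncol(null_T), 0)
  s1 <- selection_state(c(1, 0), c(1, 1, 0, 0))
  T1 <- build_design(td$X, s1, st, r)
  expect_equal(ncol(T1), 1)
  expect_equal(as.numeric(T1), unname(pls_first_component(td$X[, 1:2], r)))
  expect_error(build_design(td$X, selection_state(c(1, 0), rep(0, 4)), st, r),
               "invalid")
})

test_that("PLS g-prior covariance uses the Moore-Penrose inverse", {
  n <- 10
  Q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  expect_equal(pls_gprior_covariance(Q, 3), 3 * diag(2), tolerance = 1e-10)
  # rank-deficient Gram matrix [[1,1],[1,1]] -> pseudo-inverse 0.25 everywhere
  v <- rep(1 / sqrt(n), n)
  T <- cbind(v, v)
  expect_equal(unname(pls_gprior_covariance(T, 2)),
               2 * matrix(0.25, 2, 2), tolerance = 1e-10)
  # Penrose identity A A^+ A = A
  set.seed(2)
  T2 <- matrix(rnorm(n * 3), n, 3); T2[, 3] <- T2[, 1] + T2[, 2]
  A <- crossprod(T2)
  Ap <- pls_gprior_covariance(T2, 1)
  expect_lt(max(abs(A %*% Ap %*% A - A)), 1e-8)
})

test_that("MRF prior decouples at f = 0 and rewards active edges by f", {
  st <- toy_structure()
  th <- c(1L, 1L)
  base <- selection_state(th, c(1, 0, 1, 0))
  one_more <- selection_state(th, c(1, 1, 1, 0))
  d <- -1.2; f0 <- 0
  # with f = 0 the mass difference for adding a gene is exactly d... plus no
  # edge term
  expect_equal(mrf_log_prior(one_more, st$R, st$S, d, f0) -
                 mrf_log_prior(base, st$R, st$S, d, f0), d)
  # g1-g2 are neighbors within selected pwA: turning the edge on adds f
  f <- 0.7
  expect_equal(mrf_log_prior(one_more, st$R, st$S, d, f) -
                 mrf_log_prior(base, st$R, st$S, d, f), d + f)
  expect_identical(mrf_log_prior(selection_state(c(1, 0), rep(0, 4)),
                                 st$R, st$S, d, f), -Inf)
})

test_that("MRF conditional marginals match brute-force enumeration", {
  # 2 pathways x 3 genes, all pathways selected; compare the f = 0 field to
  # independent-Bernoulli weights conditioned on validity
  S <- matrix(0L, 6, 2); S[1:3, 1] <- 1L; S[4:6, 2] <- 1L
  R <- matrix(0L, 6, 6); R[1, 2] <- R[2, 1] <- R[4, 5] <- R[5, 4] <- 1L
  th <- c(1L, 1L)
  d <- -0.8; f <- 0.6
  grid <- expand.grid(rep(list(0:1), 6))
  lm <- apply(grid, 1, function(g)
    mrf_log_prior(selection_state(th, as.integer(g)), R, S, d, f))
  w <- exp(lm); w[!is.finite(lm)] <- 0
  expect_gt(sum(w), 0)
  w <- w / sum(w)
  marg <- colSums(w * grid)
  # independent oracle: enumerate unnormalized Ising weights directly
  ow <- apply(grid, 1, function(g) {
    g <- as.integer(g)
    if (sum(g[1:3]) == 0 || sum(g[4:6]) == 0) return(0)  # validity (a)
    edges <- g[1] * g[2] + g[4] * g[5]
    exp(d * sum(g) + f * edges)
  })
  ow <- ow / sum(ow)
  expect_equal(unname(marg), unname(colSums(ow * grid)), tolerance = 1e-12)
})

test_that("pathway prior is product Bernoulli", {
  expect_equal(theta_log_prior(rep(0, 10), 0.1), 10 * log(0.9))
  expect_equal(theta_log_prior(c(1, 0, 1), 0.5), -3 * log(2))
  st <- toy_structure()
  hy <- ibvs_hyper(d = -1, f = 0.3, pi_theta = 0.2)
  s <- selection_state(c(1, 0), c(1, 1, 0, 0))
  expect_equal(joint_log_prior(s, st, hyper = hy),
               theta_log_prior(s$theta, 0.2) +
                 mrf_log_prior(s, st$R, st$S, -1, 0.3))
  expect_identical(joint_log_prior(selection_state(c(1, 1), rep(0, 4)),
                                   st, hyper = hy), -Inf)
  expect_equal(joint_log_prior(selection_state(c(0, 0), rep(0, 4)), st,
                               hyper = hy), 2 * log(0.8))
})

test_that("fast marginal likelihood equals the dense MVN oracle", {
  dense_logpdf <- function(Z, T, c, h) {
    n <- length(Z)
    P <- if (ncol(T)) T %*% ibvs:::.pinv(crossprod(T)) %*% t(T) else
      matrix(0, n, n)
    Sig <- h * matrix(1, n, n) + diag(n) + c * P
    L <- chol(Sig)
    -0.5 * (n * log(2 * pi)) - sum(log(diag(L))) -
      0.5 * sum(backsolve(L, Z, transpose = TRUE)^2)
  }
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    k <- sample(0:3, 1)
    T <- if (k > 0) matrix(rnorm(n * k), n, k) else matrix(0, n, 0)
    if (k >= 2 && i %% 3 == 0) T[, k] <- T[, 1]          # rank-deficient
    Z <- rnorm(n, sd = 2)
    c <- runif(1, 0.5, 200)
    h <- 10^runif(1, -2, 6)
    expect_equal(log_marginal_Z(Z, T, c, h), dense_logpdf(Z, T, c, h),
                 tolerance = 1e-8)
    expect_equal(ibvs:::cpp_logmarg_Z(Z, T, c, h), dense_logpdf(Z, T, c, h),
                 tolerance = 1e-8)
  }
  # null design, vanishing intercept variance: iid standard normal density
  Z <- rnorm(6)
  expect_equal(log_marginal_Z(Z, matrix(0, 6, 0), c = 3, h = 1e-12),
               sum(dnorm(Z, log = TRUE)), tolerance = 1e-6)
  # c -> 0 collapses to the null-model density for any design
  T <- matrix(rnorm(12), 6, 2)
  expect_equal(log_marginal_Z(Z, T, c = 1e-12, h = 2),
               log_marginal_Z(Z, matrix(0, 6, 0), c = 1, h = 2),
               tolerance = 1e-6)
})

test_that("projector properties and invariances of the marginal", {
  set.seed(4)
  n <- 12
  T <- matrix(rnorm(n * 3), n, 3)
  P <- T %*% ibvs:::.pinv(crossprod(T)) %*% t(T)
  expect_lt(max(abs(P %*% P - P)), 1e-8)
  expect_lt(max(abs(P - t(P))), 1e-10)
  expect_equal(sum(diag(P)), qr(T)$rank)
  Z <- rnorm(n)
  base <- log_marginal_Z(Z, T, 10, 5)
  expect_equal(log_marginal_Z(Z, T[, c(3, 1, 2)], 10, 5), base, tolerance = 1e-10)
  expect_equal(log_marginal_Z(Z, T %*% diag(c(-1, 1, -2)), 10, 5), base,
               tolerance = 1e-10)
  # likelihood increases with c when Z lies in col(T) and carries enough
  # energy (the k*log(1+c) volume penalty must be dominated)
  Zin <- drop(T %*% c(1, -1, 0.5))
  Zin <- Zin * sqrt(1000) / sqrt(sum(Zin^2))
  lls <- sapply(c(1, 5, 25, 125), function(cc) log_marginal_Z(Zin, T, cc, 5))
  expect_true(all(diff(lls) > 0))
})
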