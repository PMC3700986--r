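test_that("truncated-normal Gibbs sweep reproduces half-normal moments", {
  n <- 2000
  y <- rep(1L, n)
  Om <- diag(n)
  set.seed(1)
  Z <- rep(0.5, n)
  draws <- c()
  for (s in 1:50) {
    Z <- sample_Z_gibbs(Z, y, Omega = Om)
    draws <- c(draws, Z)
  }
  expect_true(all(draws > 0))
  expect_equal(mean(draws), sqrt(2 / pi), tolerance = 0.01)
  expect_equal(var(draws), 1 - 2 / pi, tolerance = 0.02)
  # mixed signs respect the orthant
  y2 <- rep(c(1L, 0L), n / 2)
  Z2 <- sample_Z_gibbs(rnorm(n) * (2 * y2 - 1) * 0.1, y2, Omega = Om)
  expect_true(all(Z2[y2 == 1] > 0))
  expect_true(all(Z2[y2 == 0] <= 0))
})

test_that("correlated two-dimensional sweep matches a rejection oracle", {
  Sig <- matrix(c(1, 0.7, 0.7, 1.5), 2, 2)
  y <- c(1L, 0L)
  oracle <- rtmvn_reject(Sig, y, nkeep = 4000, seed = 2)
  set.seed(3)
  Om <- solve(Sig)
  Z <- c(0.5, -0.5)
  keep <- matrix(NA_real_, 4000, 2)
  for (i in 1:1000) Z <- sample_Z_gibbs(Z, y, Omega = Om)  # burn-in
  for (i in 1:4000) {
    Z <- sample_Z_gibbs(Z, y, Omega = Om)
    keep[i, ] <- Z
  }
  expect_equal(colMeans(keep), colMeans(oracle), tolerance = 0.04)
  expect_equal(apply(keep, 2, var), apply(oracle, 2, var), tolerance = 0.08)
})

test_that("only pathway addition is legal from the null state", {
  st <- toy_structure()
  null_st <- selection_state(c(0, 0), rep(0, 4))
  set.seed(4)
  types <- replicate(200, {
    pr <- propose_move(null_st, st)
    if (pr$stuck) NA_integer_ else pr$type
  })
  expect_true(all(types[!is.na(types)] == 1L))
  expect_true(any(is.na(types)))          # other move types report stuck
  # an accepted M1 proposal is always valid
  set.seed(5)
  pr <- propose_move(null_st, st, move_probs = c(1, 0, 0, 0))
  expect_true(is_valid_configuration(pr$state, st$S)$valid)
})

test_that("toggles that would empty a pathway are flagged invalid", {
  st <- toy_structure()
  s <- selection_state(c(1, 0), c(1, 0, 0, 0))   # single selected gene
  set.seed(6)
  seen_invalid <- FALSE
  for (i in 1:100) {
    pr <- propose_move(s, st, move_probs = c(0, 0, 1, 0))
    if (pr$invalid) {
      seen_invalid <- TRUE
      step <- mh_step(s, rnorm(4), toy_data(4)$X, c(0, 1, 0, 1), st)
      break
    }
  }
  expect_true(seen_invalid)
})

test_that("MH step rejects invalid proposals and is otherwise stochastic", {
  st <- toy_structure()
  td <- toy_data(n = 20)
  s <- selection_state(c(1, 0), c(1, 0, 0, 0))
  set.seed(7)
  Z <- ifelse(td$y == 1, 0.5, -0.5)
  states <- replicate(50, {
    out <- mh_step(s, Z, td$X, td$y, st)
    paste(out$state$gamma, collapse = "")
  })
  expect_true(all(nchar(states) == 4))
  # every state that the step returns is valid
  set.seed(8)
  cur <- s
  for (i in 1:200) {
    out <- mh_step(cur, Z, td$X, td$y, st)
    cur <- out$state
    expect_true(is_valid_configuration(cur, st$S)$valid)
  }
})

test_that("with a flat likelihood the chain samples the exact prior", {
  st <- toy_structure()
  td <- toy_data(n = 30)
  hy <- ibvs_hyper(c = 1e-8, d = 0, f = 0.5, pi_theta = 0.4)
  # enumerate the prior over all 64 configurations
  grid <- expand.grid(rep(list(0:1), 6))
  lp <- apply(grid, 1, function(s)
    joint_log_prior(selection_state(as.integer(s[1:2]), as.integer(s[3:6])),
                    st, hyper = hy))
  w <- exp(lp); w[!is.finite(lp)] <- 0; w <- w / sum(w)
  prior_gene <- colSums(w * grid[, 3:6])
  prior_pw <- colSums(w * grid[, 1:2])
  d <- run_chain(td$X, td$y, st, hy,
                 sampler_config(burn_in = 2000, kept = 40000, chains = 2,
                                seed = 9))
  expect_lt(max(abs(d$gene_freq - prior_gene)), 0.02)
  expect_lt(max(abs(d$pathway_freq - prior_pw)), 0.02)
})

test_that("MCMC marginals match the enumeration oracle", {
  st <- toy_structure()
  td <- toy_data(n = 14)
  hy <- ibvs_hyper(c = 5, d = 0, f = 0.5, pi_theta = 0.4)
  en1 <- enumerate_posterior(td$X, td$y, st, hy, nsim = 80000, seed = 3)
  en2 <- enumerate_posterior(td$X, td$y, st, hy, nsim = 80000, seed = 4)
  en <- list(gene_prob = (en1$gene_prob + en2$gene_prob) / 2,
             pathway_prob = (en1$pathway_prob + en2$pathway_prob) / 2,
             table = en1$table)
  d <- run_chain(td$X, td$y, st, hy,
                 sampler_config(burn_in = 5000, kept = 120000, chains = 2,
                                seed = 8))
  expect_lt(max(abs(en$gene_prob - d$gene_freq)), 0.02)
  expect_lt(max(abs(en$pathway_prob - d$pathway_freq)), 0.02)
  expect_equal(sum(en$table$prob), 1, tolerance = 1e-12)
})

test_that("enumeration oracle is symmetric on exchangeable null genes", {
  set.seed(10)
  st <- toy_structure()
  X <- standardize_expression(
    matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("g", 1:4))))
  y <- rep(c(0L, 1L), 6)                  # independent of X
  hy <- ibvs_hyper(c = 2, d = 0, f = 0, pi_theta = 0.4)
  en <- enumerate_posterior(X, y, st, hy, nsim = 120000, seed = 11)
  expect_lt(diff(range(en$gene_prob)), 0.1)   # limited by inner-MC error
  # a strong causal gene clearly exceeds one half
  td <- toy_data(n = 25, beta = c(2.5, 0, 0, 0))
  en2 <- enumerate_posterior(td$X, td$y, st, ibvs_hyper(c = 10, d = 0, f = 0.5,
                                                        pi_theta = 0.4),
                             nsim = 20000, seed = 12)
  expect_gt(en2$gene_prob[1], 0.5)
})

test_that("chains are reproducible and every recorded state is valid", {
  st <- toy_structure()
  td <- toy_data(n = 20)
  cfg <- sampler_config(burn_in = 500, kept = 2000, chains = 2, seed = 13,
                        store_every = 10)
  a <- run_chain(td$X, td$y, st, config = cfg)
  b <- run_chain(td$X, td$y, st, config = cfg)
  expect_identical(a$gene_freq, b$gene_freq)
  expect_identical(a$logpost, b$logpost)
  for (ch in a$chains) {
    for (i in seq_len(nrow(ch$draws_gamma))) {
      expect_true(is_valid_configuration(
        selection_state(ch$draws_theta[i, ], ch$draws_gamma[i, ]), st$S)$valid)
    }
  }
  expect_true(all(is.finite(a$logpost)))
})

test_that("all valid states are visited on a small system", {
  st <- toy_structure()
  td <- toy_data(n = 16)
  d <- run_chain(td$X, td$y, st, ibvs_hyper(c = 2, d = 0, f = 0, pi_theta = 0.5),
                 sampler_config(burn_in = 1000, kept = 20000, chains = 1,
                                seed = 14, store_every = 1))
  states <- unique(apply(cbind(d$chains[[1]]$draws_theta,
                               d$chains[[1]]$draws_gamma), 1, paste,
                         collapse = ""))
  # 16 valid configurations exist for 2 two-gene pathways
  expect_equal(length(states), 16)
})

test_that("Gelman-Rubin diagnostic behaves canonically", {
  set.seed(15)
  x <- rnorm(2000)
  expect_equal(gelman_rubin(cbind(x, x)), 1, tolerance = 0.01)
  far <- cbind(rnorm(500), rnorm(500, mean = 10))
  expect_gt(gelman_rubin(far), 1.1)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_equal(gelman_rubin(iid), 1, tolerance = 0.05)
  expect_warning(r <- gelman_rubin(cbind(rep(1, 50), rep(1, 50))), "zero")
  expect_true(is.nan(r))
  expect_error(gelman_rubin(matrix(rnorm(20), 20, 1)), ">= 2 chains")
})

test_that("null expression data leaves gene inclusion near the prior level", {
  # average two null replicates; the supervised PLS direction chases noise on
  # any single dataset, so pathway inclusion sits above its prior while gene
  # marginals stay near theirs
  freqs <- sapply(1:2, function(i) {
    sim <- build_scenario(1, seed = 15 + i)
    y0 <- simulate_outcome(sim$X, rep(0, 315), seed = 17 + i)$y
    run_chain(sim$X, y0, sim$structure,
              config = sampler_config(burn_in = 1000, kept = 4000,
                                      chains = 1, seed = 18 + i))$gene_freq
  })
  prior_rate <- plogis(ibvs_hyper()$d)
  expect_lt(mean(freqs), 3 * prior_rate)
  expect_lt(max(rowMeans(freqs)), 0.6)
})
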