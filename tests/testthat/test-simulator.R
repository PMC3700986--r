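test_that("merging pathway DAGs unions genes, edges and memberships", {
  d1 <- make_pathway("pwA", c("a", "b", "c"), topology = "chain")
  d2 <- make_pathway("pwB", c("d", "e", "f"), topology = "chain")
  m <- merge_pathways_to_dag(list(d1, d2))
  expect_length(m$gene_ids, 6)
  expect_equal(nrow(m$edges), 4)
  expect_length(m$membership, 2)
  # single pathway merges to itself
  one <- merge_pathways_to_dag(list(d1))
  expect_equal(one$gene_ids, d1$gene_ids)
  expect_equal(one$edges, d1$edges)
  # shared gene gets two memberships
  d3 <- make_pathway("pwC", c("c", "g"), topology = "chain")
  m2 <- merge_pathways_to_dag(list(d1, d3))
  st <- as_pathway_structure(m2)
  expect_equal(sum(st$S["c", ]), 2)
})

test_that("merging breaks directed cycles by dropping the late edge", {
  d1 <- make_pathway("pwA", c("a", "b"), topology = "chain")
  d2 <- structure(list(gene_ids = c("b", "a"),
                       edges = data.frame(parent = "b", child = "a"),
                       membership = list(pwB = c("b", "a")),
                       g_lo = c(b = NA, a = 0.1), g_hi = c(b = NA, a = 0.2),
                       pos_w = c(b = FALSE, a = FALSE)),
                  class = "pathway_dag")
  expect_message(m <- merge_pathways_to_dag(list(d1, d2)), "cycle")
  expect_equal(nrow(m$edges), 1)
  expect_equal(m$edges$parent, "a")
})

test_that("structural-equation simulation has the stated covariance", {
  # independent roots: near-zero correlations
  roots <- make_pathway("pwA", paste0("r", 1:5), topology = "none")
  Xr <- simulate_expression(roots, 10000, seed = 1)
  cr <- cor(Xr)
  expect_lt(max(abs(cr[upper.tri(cr)])), 0.05)
  # two-gene chain: |cor| equals sqrt(g) in closed form
  ch <- make_pathway("pwB", c("a", "b"), topology = "chain")
  Xc <- simulate_expression(ch, 10000, seed = 2, g_override = c(b = 0.49))
  expect_equal(abs(cor(Xc[, "a"], Xc[, "b"])), 0.7, tolerance = 0.03)
  # every column standardized
  expect_lt(max(abs(colMeans(Xc))), 1e-10)
  expect_lt(max(abs(apply(Xc, 2, var) - 1)), 1e-8)
  expect_error(simulate_expression(ch, 1), "at least 2")
})

test_that("effect calibration hits the target SNR exactly", {
  set.seed(3)
  X <- standardize_expression(matrix(rnorm(600), 200, 3))
  cal1 <- calibrate_effect_sizes(X, 1, 1, target_snr = 4)
  expect_equal(cal1$beta, 2, tolerance = 0.05)       # single unit-variance gene
  cal2 <- calibrate_effect_sizes(X, c(1, 2), c(1, 1), target_snr = 8)
  beta <- numeric(3); beta[1:2] <- cal2$beta
  expect_equal(compute_snr(X, beta), 8, tolerance = 1e-6)  # exact round trip
  expect_equal(compute_snr(X, c(0, 0, 0)), 0)
  expect_error(calibrate_effect_sizes(X, 1, 0, 4), "null space")
})

test_that("probit outcomes follow the latent threshold rule", {
  set.seed(4)
  X <- standardize_expression(matrix(rnorm(4000), 2000, 2))
  out0 <- simulate_outcome(X, c(0, 0), seed = 5)
  expect_equal(mean(out0$y), 0.5, tolerance = 0.05)  # symmetric latent
  expect_equal(out0$y, as.integer(out0$U > 0))
  out1 <- simulate_outcome(X, c(0, 0), beta0 = 10, seed = 5)
  expect_true(all(out1$y == 1))                      # dominant intercept
})

test_that("high-SNR outcomes match the exact sign-agreement rate", {
  # P(sign(X beta) != y) = arccos(rho) / pi with rho = sqrt(SNR / (SNR + 1)),
  # the orthant probability of the bivariate normal (X beta, U)
  set.seed(6)
  X <- standardize_expression(matrix(rnorm(2e4 * 2), 2e4, 2))
  cal <- calibrate_effect_sizes(X, 1:2, 1, target_snr = 54.5)
  beta <- numeric(2); beta[1:2] <- cal$beta
  out <- simulate_outcome(X, beta, seed = 7)
  err <- mean((drop(X %*% beta) > 0) != (out$y == 1))
  exact <- acos(sqrt(54.5 / 55.5)) / pi
  expect_equal(err, exact, tolerance = 0.1)
  expect_lt(err, 0.06)
})

test_that("scenario datasets match their printed designs", {
  s1 <- build_scenario(1, seed = 11)
  expect_equal(dim(s1$X), c(100, 315))
  expect_equal(ncol(s1$structure$S), 9)
  expect_length(s1$causal, 8)
  expect_equal(s1$snr, 54.5, tolerance = 1e-8)
  s1l <- build_scenario(1, effect = "low", seed = 11)
  expect_equal(s1l$snr, 3.4, tolerance = 1e-8)
  s2 <- build_scenario(2, seed = 12)
  expect_equal(sort(s2$causal), 1:28)
  expect_equal(sum(s2$structure$S[, 1]), 19)   # the two fully causal pathways
  expect_equal(sum(s2$structure$S[, 2]), 9)
  s3 <- build_scenario(3, seed = 13)
  expect_equal(dim(s3$X), c(100, 2000))
  expect_equal(ncol(s3$structure$S), 90)
  expect_length(s3$causal, 8)
  expect_error(build_scenario(7), "unknown scenario")
})

test_that("scenario 4 places causal groups at the printed indices/effects", {
  s4 <- build_scenario(4, seed = 14)
  expect_equal(s4$causal,
               sort(c(40:49, 305:314, 950:959, 1320:1329, 1710:1719)))
  expect_equal(unname(s4$beta[40]), 1.0)
  expect_equal(unname(s4$beta[305]), 2.5)
  expect_equal(unname(s4$beta[950]), 1.5)
  expect_equal(unname(s4$beta[1320]), 3.5)
  expect_equal(unname(s4$beta[1710]), 1.2)
  # groups 3-5 live in pathways without internal network edges
  for (g in c(950:959, 1320:1329, 1710:1719)) {
    expect_equal(sum(s4$structure$R[g, ]), 0)
  }
  # each causal group is contained in a single pathway
  for (grp in list(40:49, 305:314, 950:959, 1320:1329, 1710:1719)) {
    shared <- colSums(s4$structure$S[grp, , drop = FALSE]) == length(grp)
    expect_true(any(shared))
  }
})

test_that("regeneration is seed-deterministic with a fixed causal set", {
  a <- build_scenario(1, seed = 21)
  b <- build_scenario(1, seed = 21)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  c3 <- build_scenario(1, seed = 22)
  expect_false(identical(a$X, c3$X))
  expect_identical(a$causal, c3$causal)
})

test_that("the weak-correlation pathway stays inside the stated band", {
  # population correlations in the weak pathway are capped at 0.1; sampling
  # noise alone puts ~4.9% of pairs outside (-0.20, 0.20) at n = 100
  # (2 * pnorm(-0.2 * sqrt(97)) = 0.049), so the achievable in-band fraction
  # is bounded by ~0.95 even for independent genes
  frac <- sapply(1:6, function(i) {
    sim <- build_scenario(1, seed = 30 + i)
    idx <- which(sim$structure$S[, "pw5"] == 1L)
    idx <- setdiff(idx, 80)        # drop the shared lead gene
    cc <- cor(sim$X[, idx])
    mean(abs(cc[upper.tri(cc)]) < 0.20)
  })
  noise_floor <- 1 - 2 * pnorm(-0.2 * sqrt(97))
  expect_gte(mean(frac), noise_floor - 0.01)
  expect_gte(mean(frac), 0.94)
})
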