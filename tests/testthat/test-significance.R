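# Permutation tests: statistic mechanics and small-scale behaviour.
# (Operating characteristics at the study scales are exercised in
# test-acceptance.R.)

test_that("test statistic is the mean pairwise distance", {
  D1 <- diag(2); E1 <- matrix(c(2, 1, 1, 2), 2)
  D2 <- matrix(c(4, 1, 1, 9), 2); E2 <- diag(2)
  T <- test_statistic(list(D1, D2), list(E1, E2))
  expect_equal(T, (sqrt(3) + sqrt(74)) / 2, tolerance = 1e-9)
  expect_equal(test_statistic(list(D1, D2), list(D1, D2)), 0)
  # invariant to simultaneous reordering of both lists
  expect_equal(test_statistic(list(D2, D1), list(E2, E1)), T)
})

test_that("p-value is the strict exceedance proportion", {
  sim <- dgp3(n = 60, seed = 29)
  g <- global_test(sim$X, sim$Y, R = 10, ntree = 30, seed = 3)
  expect_equal(g$p.value, sum(g$perm_stats > g$statistic) / 10)
  expect_equal(g$smoothed_p,
               (1 + sum(g$perm_stats > g$statistic)) / (1 + 10))
  # p = 0 is reportable under the strict inequality
  expect_gte(g$p.value, 0)
})

test_that("global test output is well formed and reproducible", {
  sim <- dgp3(n = 80, seed = 31)
  g1 <- global_test(sim$X, sim$Y, R = 12, ntree = 40, seed = 7)
  g2 <- global_test(sim$X, sim$Y, R = 12, ntree = 40, seed = 7)
  expect_s3_class(g1, "cov_forest_test")
  expect_equal(g1$type, "global")
  expect_length(g1$perm_stats, 12)
  expect_true(g1$p.value >= 0 && g1$p.value <= 1)
  expect_equal(g1$p.value, mean(g1$perm_stats > g1$statistic))
  expect_identical(g1$statistic, g2$statistic)
  expect_identical(g1$perm_stats, g2$perm_stats)
  expect_true(g1$nodesize %in% candidate_grid(floor(0.632 * 80), 5))
})

test_that("identity permutation with identical seed reproduces T exactly", {
  sim <- dgp3(n = 60, seed = 37)
  s <- covforest:::cf_build_sample(sim$X, sim$Y)
  params <- covforest:::cf_default_params(s$n, s$p, ntree = 30, nodesize = 12)
  params$nodesize <- 12L
  f1 <- covforest:::cf_fit_light(s$Xenc, s$ncat, s$Y, params, 5,
                                 fallback_uncond = TRUE)
  f2 <- covforest:::cf_fit_light(s$Xenc[seq_len(s$n), , drop = FALSE], s$ncat,
                                 s$Y, params, 5, fallback_uncond = TRUE)
  sroot <- array(cov(s$Y), c(s$q, s$q, s$n))
  ut <- covforest:::upper_tri_rowmajor(s$q)
  expect_identical(covforest:::cf_stat(f1$oob_est, sroot, ut),
                   covforest:::cf_stat(f2$oob_est, sroot, ut))
})

test_that("partial test validates the control set", {
  sim <- dgp4(n = 60, p = 3, seed = 41)
  expect_error(partial_test(sim$X, sim$Y, control = c("x1", "x2", "x3"),
                            R = 2, ntree = 10), "proper subset")
  expect_error(partial_test(sim$X, sim$Y, control = "nope", R = 2, ntree = 10),
               "unknown control")
  # empty control delegates to the global test
  g <- partial_test(sim$X, sim$Y, control = character(0), R = 5, ntree = 30,
                    seed = 3)
  expect_equal(g$type, "global")
})

test_that("a duplicated tested covariate yields a large p-value", {
  # the tested covariate is an exact copy of a control covariate: the full
  # model has no information beyond the control model
  sim <- dgp4(n = 100, p = 2, seed = 43)
  X <- sim$X
  X$x3 <- X$x1
  # the observed T must sit inside the permutation distribution (the full
  # model adds no information), i.e. behave like a null draw
  ps <- vapply(c(11, 12, 13), function(sd) {
    pt <- partial_test(X, sim$Y, control = c("x1", "x2"), R = 40, ntree = 50,
                       seed = sd)
    expect_equal(pt$type, "partial")
    pt$p.value
  }, numeric(1))
  expect_true(all(ps > 0))
  expect_gt(mean(ps), 0.05)
})

test_that("permutation seeds give independent replicate forests", {
  sim <- dgp3(n = 60, seed = 47)
  g <- global_test(sim$X, sim$Y, R = 8, ntree = 30, seed = 13)
  # permuted statistics are not all identical (distinct forests/permutations)
  expect_gt(length(unique(g$perm_stats)), 1)
})
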