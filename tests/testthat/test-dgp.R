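# Synthetic data generators.

test_that("quadratic-form generator has the stated covariance structure", {
  sim <- dgp1(n = 300, seed = 101)
  expect_equal(dim(sim$sigma), c(2, 2, 300))
  psi <- sim$params$psi; b <- sim$params$b
  for (i in c(1, 150, 300)) {
    u <- b %*% c(1, sim$X$x1[i])
    expect_equal(sim$sigma[, , i], psi + u %*% t(u), tolerance = 1e-12)
    # Sigma - Psi is PSD of rank <= 1
    ev <- eigen(sim$sigma[, , i] - psi, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) > -1e-12)
    expect_lte(sum(ev > 1e-10), 1)
  }
  # B = 0 gives the homoscedastic null
  sim0 <- dgp1(n = 50, b = matrix(0, 2, 2), seed = 3)
  for (i in c(1, 50)) expect_equal(sim0$sigma[, , i], diag(2))
})

test_that("the quadratic variant collapses x and -(1+x) pairs", {
  # x + x^2 is equal at x and -(1 + x); check endpoints 0 and -1
  sim <- dgp2(n = 10, seed = 5)
  b <- sim$params$b; psi <- sim$params$psi
  s_at <- function(x) {
    u <- b %*% c(1, x + x^2)
    psi + u %*% t(u)
  }
  expect_equal(s_at(0), s_at(-1), tolerance = 1e-12)
  # dgp2 at x = 0 equals dgp1 at x = 0
  u <- b %*% c(1, 0)
  expect_equal(s_at(0), psi + u %*% t(u))
})

test_that("tree-regime generator yields eight shared-covariance leaves", {
  sim <- dgp3(n = 600, q = 5, seed = 7)
  expect_equal(ncol(sim$X), 7)
  leaf <- sim$params$leaf
  expect_equal(sort(unique(leaf)), 1:8)
  for (l in c(1, 4, 8)) {
    rows <- which(leaf == l)
    if (length(rows) >= 2) {
      for (i in rows[-1])
        expect_equal(sim$sigma[, , i], sim$sigma[, , rows[1]])
    }
  }
  # every matrix positive definite, AR(1) correlation decay
  for (i in c(1, 300, 600)) {
    S <- sim$sigma[, , i]
    expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
    C <- cov2cor(S)
    rho <- C[1, 2]
    expect_equal(C[1, 3], rho^2, tolerance = 1e-10)
    expect_equal(C[1, 5], rho^4, tolerance = 1e-10)
  }
  # leaf correlations distinct and within (0, 1)
  expect_equal(length(unique(sim$params$leaf_rho)), 8)
  expect_true(all(sim$params$leaf_rho > 0 & sim$params$leaf_rho < 1))
})

test_that("compound-symmetry generator links correlation to covariates", {
  sim <- dgp4(n = 400, p = 3, q = 5, seed = 9)
  rho <- sim$params$rho
  expect_true(all(rho > 0 & rho < 1))
  expect_equal(rho, plogis(drop(as.matrix(sim$X) %*% sim$params$beta)))
  for (i in c(1, 200, 400)) {
    S <- sim$sigma[, , i]
    expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
    C <- cov2cor(S)
    off <- C[upper.tri(C)]
    expect_equal(max(abs(off - rho[i])), 0, tolerance = 1e-10)
  }
  # coefficient 0 for covariates beyond the third
  sim5 <- dgp4(n = 20, p = 5, q = 3, seed = 11)
  expect_equal(sim5$params$beta, c(2, 1, 0.5, 0, 0))
})

test_that("generators are deterministic given a seed and restore RNG state", {
  set.seed(42)
  before <- .Random.seed
  s1 <- dgp3(n = 50, seed = 77)
  expect_identical(.Random.seed, before)
  s2 <- dgp3(n = 50, seed = 77)
  expect_identical(s1$X, s2$X)
  expect_identical(s1$Y, s2$Y)
  expect_identical(s1$sigma, s2$sigma)
})

test_that("responses empirically match the generating covariance", {
  # many draws at a fixed covariate value: empirical covariance converges
  reps <- 4000
  sim <- dgp4(n = reps, p = 2, q = 3, seed = 13)
  # bin observations with rho in a narrow band and compare pooled moments
  rho <- sim$params$rho
  band <- which(abs(rho - 0.5) < 0.02)
  if (length(band) > 100) {
    emp <- unname(cov(sim$Y[band, ]))
    expected <- apply(sim$sigma[, , band], c(1, 2), mean)
    expect_equal(emp, expected, tolerance = 4 / sqrt(length(band)) * 3)
  }
  expect_true(length(band) > 100)
})

test_that("noise covariates are independent add-ons", {
  sim <- dgp3(n = 200, seed = 15)
  aug <- add_noise_covariates(sim, 5, seed = 16)
  expect_equal(ncol(aug$X), 12)
  expect_identical(aug$Y, sim$Y)
  expect_identical(aug$sigma, sim$sigma)
  expect_identical(add_noise_covariates(sim, 0), sim)
  # appended columns uncorrelated with the responses (loose bound)
  cors <- abs(cor(as.matrix(aug$X[, 8:12]), sim$Y))
  expect_true(all(cors < 3 / sqrt(200) * 1.5))
})
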