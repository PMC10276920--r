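# OOB nearest-neighbour sets (BOP) and covariance estimation.

test_that("training-row BOPs match independent tree-traversal oracle", {
  toy <- make_toy(20, p = 2, q = 2, seed = 5)
  fit <- cov_forest(toy$X, toy$Y, ntree = 3, nodesize = 6, seed = 13,
                    degenerate = "unconditional")
  for (i in c(1, 7, 20)) {
    got <- tryCatch(sort(bop_for_training(fit, i)), error = function(e) integer(0))
    expect_equal(got, o_bop_training(fit, i))
  }
})

test_that("new-observation BOPs are unions of per-tree OOB co-members", {
  toy <- make_toy(20, p = 2, q = 2, seed = 6)
  fit <- cov_forest(toy$X, toy$Y, ntree = 3, nodesize = 6, seed = 17,
                    degenerate = "unconditional")
  xnew <- toy$X[c(2, 11), , drop = FALSE]
  got <- bop_for_new(fit, xnew)
  for (k in 1:2) {
    xenc <- covforest:::cf_encode_newdata(fit$sample, xnew[k, , drop = FALSE])
    expect_equal(sort(got[[k]]), o_bop_new(fit, xenc[1, ]))
  }
})

test_that("training rows are excluded from their own neighbour sets", {
  toy <- make_toy(40, p = 2, q = 2, seed = 7)
  fit <- cov_forest(toy$X, toy$Y, ntree = 30, nodesize = 10, seed = 19)
  for (i in seq_len(40)) expect_false(i %in% bop_for_training(fit, i))
})

test_that("root-only forests give near-unconditional BOPs and estimates", {
  toy <- make_toy(50, p = 2, q = 2, seed = 8)
  n <- 50
  fit <- cov_forest(toy$X, toy$Y, ntree = 200, nodesize = n, seed = 23)
  # every OOB observation shares the root: BOP for a new point = all rows
  b <- bop_for_new(fit, toy$X[1, , drop = FALSE])[[1]]
  expect_equal(sort(b), 1:n)
  pred <- predict(fit, toy$X[1:2, , drop = FALSE])
  expect_equal(unname(pred$sigma[, , 1]), unname(cov(toy$Y)), tolerance = 1e-10)
})

test_that("identical responses give zero covariance estimates", {
  toy <- make_toy(30, p = 1, q = 2, seed = 9)
  toy$Y <- matrix(rep(c(1, 2), each = 30), 30, 2)
  fit <- cov_forest(toy$X, toy$Y, ntree = 20, nodesize = 10, seed = 29)
  pred <- predict(fit, toy$X[1:3, , drop = FALSE])
  expect_equal(max(abs(pred$sigma)), 0)
})

test_that("estimates are symmetric PSD and consistent between calls", {
  toy <- make_toy(60, p = 2, q = 3, seed = 10)
  fit <- cov_forest(toy$X, toy$Y, ntree = 50, nodesize = 15, seed = 31)
  oo <- oob_estimates(fit)
  for (i in c(1, 30, 60)) {
    S <- unname(oo$sigma[, , i])
    expect_equal(S, t(S))
    expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  }
  # predict on training X uses all trees (not the OOB-only restriction),
  # but must still be deterministic and PSD
  p1 <- predict(fit, toy$X)
  p2 <- predict(fit, toy$X)
  expect_equal(p1$sigma, p2$sigma)
})

test_that("multiset pooling weights duplicated neighbours", {
  toy <- make_toy(40, p = 1, q = 2, seed = 12)
  f_set <- cov_forest(toy$X, toy$Y, ntree = 40, nodesize = 10, seed = 37)
  f_multi <- cov_forest(toy$X, toy$Y, ntree = 40, nodesize = 10, seed = 37,
                        bop_multiset = TRUE)
  # same trees, but pooled neighbour sets are at least as large
  expect_identical(f_set$trees, f_multi$trees)
  expect_true(all(f_multi$oob$bop_size >= f_set$oob$bop_size))
  expect_true(any(f_multi$oob$bop_size > f_set$oob$bop_size))
})

test_that("deeper trees weakly localize the neighbour sets", {
  toy <- make_toy(150, p = 2, q = 2, seed = 13)
  sizes <- vapply(c(75, 30, 10), function(ns) {
    f <- cov_forest(toy$X, toy$Y, ntree = 40, nodesize = ns, seed = 41)
    median(f$oob$bop_size)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("unseen categorical levels are routed down both children", {
  set.seed(14)
  n <- 60
  X <- data.frame(g = sample(c("a", "b"), n, replace = TRUE), x = runif(n))
  Y <- matrix(rnorm(2 * n), n, 2)
  Y[X$g == "b", ] <- Y[X$g == "b", ] * 3
  fit <- cov_forest(X, Y, ntree = 20, nodesize = 20, seed = 43)
  expect_warning(pred <- predict(fit, data.frame(g = "zz", x = 0.5)), "unseen")
  expect_true(all(is.finite(pred$sigma)))
  # merged BOP is at least as large as either seen level's
  suppressWarnings({
    b_new <- bop_for_new(fit, data.frame(g = "zz", x = 0.5))[[1]]
  })
  b_a <- bop_for_new(fit, data.frame(g = "a", x = 0.5))[[1]]
  b_b <- bop_for_new(fit, data.frame(g = "b", x = 0.5))[[1]]
  expect_true(all(b_a %in% b_new) && all(b_b %in% b_new))
})

test_that("degenerate neighbour sets error by default and can fall back", {
  toy <- make_toy(20, p = 1, q = 2, seed = 15)
  # a single tree: rows in-bag for it have no OOB trees at all
  expect_error(cov_forest(toy$X, toy$Y, ntree = 1, nodesize = 5, seed = 47),
               "increase `ntree`")
  f <- cov_forest(toy$X, toy$Y, ntree = 1, nodesize = 5, seed = 47,
                  degenerate = "unconditional")
  oo <- oob_estimates(f)
  expect_true(any(oo$degenerate))
  i <- which(oo$degenerate)[1]
  expect_equal(unname(oo$sigma[, , i]), unname(cov(toy$Y)), tolerance = 1e-10)
})
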