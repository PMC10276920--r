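# Tree growing and forest structure.

test_that("chosen root split attains the exhaustive maximum of the score", {
  # exhaustive candidate mode (mtry = p, nsplit >= all cut points) must
  # match independent brute-force enumeration over all splits
  for (case in 1:12) {
    set.seed(case)
    n <- sample(8:12, 1)
    p <- sample(1:3, 1)
    toy <- make_toy(n, p = p, q = 2, seed = case + 100)
    fit <- cov_forest(toy$X, toy$Y, ntree = 1, mtry = p, nsplit = 500,
                      nodesize = 3, sampsize = n - 1, min_child = 2,
                      seed = case, degenerate = "unconditional")
    tree <- fit$trees[[1]]
    inbag <- fit$inbag[, 1]
    expect_equal(length(unique(inbag)), n - 1) # distinct subsample
    v <- tree$var[1] + 1
    l <- inbag[toy$X[inbag, v] <= tree$thr[1]]
    r <- setdiff(inbag, l)
    achieved <- o_split_score(l, r, toy$Y)
    expect_equal(achieved, o_best_split(toy$X, toy$Y, inbag), tolerance = 1e-10)
  }
})

test_that("a covariate separating two covariance regimes is split first", {
  set.seed(99)
  n <- 120
  g <- rep(c(0, 1), each = n / 2)
  # regime 0: independent unit-variance responses; regime 1: strongly
  # correlated and inflated-variance responses
  Y <- matrix(rnorm(2 * n), n, 2)
  Y[g == 1, 2] <- 0.95 * Y[g == 1, 1] + 0.1 * rnorm(n / 2)
  Y[g == 1, ] <- 3 * Y[g == 1, ]
  X <- data.frame(signal = g + runif(n, -0.1, 0.1), junk = runif(n))
  # exhaustive cut points so the regime boundary is always a candidate
  fit <- cov_forest(X, Y, ntree = 30, mtry = 2, nsplit = 200, nodesize = 30,
                    seed = 5)
  first_vars <- vapply(fit$trees, function(t) t$var[1] + 1, numeric(1))
  expect_true(all(first_vars == 1))
  # every chosen threshold keeps the uncorrelated regime intact on the left
  thr <- vapply(fit$trees, function(t) t$thr[1], numeric(1))
  expect_true(all(thr > 0.1 & thr < 1.1))
})

test_that("children partition parents and routing is consistent", {
  toy <- make_toy(60, p = 3, q = 2, seed = 21)
  fit <- cov_forest(toy$X, toy$Y, ntree = 5, nodesize = 8, seed = 2,
                    degenerate = "unconditional")
  s <- fit$sample
  for (b in 1:5) {
    tree <- fit$trees[[b]]
    inbag <- fit$inbag[, b]
    # recursively check member partition via independent routing
    routed <- vapply(seq_len(s$n), function(i) o_route(tree, s$Xenc[i, ], s$ncat),
                     integer(1))
    expect_equal(routed - 1L, unname(fit$term[, b]))
    # every terminal's in-bag members reach exactly that terminal
    for (nd in which(tree$var < 0)) {
      mem <- inbag[routed[inbag] == nd]
      expect_true(all(routed[mem] == nd))
    }
    # internal nodes have both children, terminals none
    internal <- tree$var >= 0
    expect_true(all(tree$left[internal] >= 0 & tree$right[internal] >= 0))
    expect_true(all(tree$left[!internal] < 0 & tree$right[!internal] < 0))
  }
})

test_that("forests are reproducible from the master seed", {
  toy <- make_toy(50, p = 2, q = 2, seed = 31)
  f1 <- cov_forest(toy$X, toy$Y, ntree = 20, nodesize = 10, seed = 77)
  f2 <- cov_forest(toy$X, toy$Y, ntree = 20, nodesize = 10, seed = 77)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
  expect_equal(f1$oob$sigma, f2$oob$sigma)
  f3 <- cov_forest(toy$X, toy$Y, ntree = 20, nodesize = 10, seed = 78)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("subsamples are distinct, of size floor(0.632 n), and cover OOB", {
  n <- 100
  toy <- make_toy(n, p = 2, q = 2, seed = 41)
  fit <- cov_forest(toy$X, toy$Y, ntree = 60, nodesize = 20, seed = 3)
  expect_equal(fit$params$sampsize, floor(0.632 * n))
  for (b in c(1, 30, 60))
    expect_equal(length(unique(fit$inbag[, b])), floor(0.632 * n))
  # every row is OOB in at least one tree at this ntree (prob ~ 1)
  oob_count <- vapply(seq_len(n), function(i)
    sum(colSums(fit$inbag == i) == 0), numeric(1))
  expect_true(all(oob_count > 0))
})

test_that("nodesize at or above sampsize yields root-only trees", {
  toy <- make_toy(40, p = 2, q = 2, seed = 51)
  fit <- cov_forest(toy$X, toy$Y, ntree = 3, nodesize = floor(0.632 * 40),
                    seed = 1, degenerate = "unconditional")
  for (tree in fit$trees) expect_equal(tree$var, -1L)
})

test_that("categorical covariates split on level subsets", {
  set.seed(61)
  n <- 90
  grp <- sample(c("a", "b", "c"), n, replace = TRUE)
  Y <- matrix(rnorm(2 * n), n, 2)
  Y[grp == "c", 2] <- Y[grp == "c", 1] * 0.9 + rnorm(sum(grp == "c"), 0, 0.2)
  X <- data.frame(grp = grp, stringsAsFactors = FALSE)
  fit <- cov_forest(X, Y, ntree = 25, nodesize = 30, seed = 9)
  expect_true(any(vapply(fit$trees, function(t) t$var[1] == 0, logical(1))))
  # masks describe proper, non-empty level subsets
  for (tree in fit$trees) {
    for (nd in which(tree$var == 0)) {
      mask <- tree$mask[nd]
      expect_true(mask > 0 && mask < 7) # 3 levels -> proper subset of {0,1,2}
    }
  }
  # binary covariate admits exactly one distinct partition: both orientations
  # of the single split agree
  X2 <- data.frame(g2 = rep(c("m", "f"), length.out = n))
  fit2 <- cov_forest(X2, Y, ntree = 5, nodesize = 40, seed = 11,
                     degenerate = "unconditional")
  for (tree in fit2$trees)
    if (tree$var[1] == 0) expect_equal(tree$mask[1], 1) # canonical: level 0 left
})

test_that("constant covariates cannot be split", {
  toy <- make_toy(30, p = 1, q = 2, seed = 71)
  toy$X$x1 <- 1.0
  fit <- cov_forest(toy$X, toy$Y, ntree = 3, nodesize = 5, seed = 1,
                    degenerate = "unconditional")
  for (tree in fit$trees) expect_equal(tree$var, -1L)
})

test_that("input validation rejects malformed samples", {
  toy <- make_toy(20, p = 2, q = 2, seed = 81)
  expect_error(cov_forest(toy$X[1:10, ], toy$Y, ntree = 2), "same number of rows")
  expect_error(cov_forest(toy$X, toy$Y[, 1, drop = FALSE], ntree = 2), "q >= 2")
  Yna <- toy$Y; Yna[3, 1] <- NA
  expect_error(cov_forest(toy$X, Yna, ntree = 2), "missing")
  expect_error(cov_forest(toy$X, toy$Y, ntree = 2, sampsize = 25), "smaller than n")
})
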