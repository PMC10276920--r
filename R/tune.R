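# Nodesize tuning by stability of out-of-bag covariance estimates.

#' Dyadic nodesize candidate grid
#'
#' Candidates are `round(sampsize * 2^-k)` for `k = 1, 2, ...`, kept while
#' strictly larger than `q` (a node covariance built from `q` or fewer
#' observations is singular or nearly so), returned in increasing order.
#' Rounding is half-away-from-zero.
#'
#' @param sampsize per-tree subsample size.
#' @param q number of response variables.
#' @return Increasing integer vector of candidate nodesize values.
#' @examples
#' candidate_grid(63, 5) # 8 16 32
#' @export
candidate_grid <- function(sampsize, q) {
  sampsize <- as.integer(sampsize); q <- as.integer(q)
  vals <- integer(0)
  k <- 1L
  repeat {
    v <- as.integer(floor(sampsize * 2^-k + 0.5)) # round half away from zero
    if (v <= q) break
    vals <- c(vals, v)
    k <- k + 1L
  }
  vals <- sort(unique(vals))
  if (length(vals) == 0L)
    stop("empty nodesize grid: sampsize / 2 <= q; increase the sample size ",
         "or reduce the number of responses", call. = FALSE)
  vals
}

# internal tuning engine shared by tune_nodesize() and cov_forest().
# Fits one light forest per candidate level with a common master seed, so
# the per-tree subsamples are identical across levels (common random
# numbers), and measures MAD_j between consecutive levels' OOB estimates.
cf_tune <- function(sample, args) {
  grid <- candidate_grid(args$sampsize, sample$q)
  M <- length(grid)
  params <- list(ntree = args$ntree, mtry = args$mtry, nsplit = args$nsplit,
                 sampsize = args$sampsize, min_child = args$min_child)
  ests <- vector("list", M)
  ok <- rep(TRUE, sample$n) # rows with usable estimates at every level
  for (j in seq_len(M)) {
    params$nodesize <- grid[j]
    f <- cf_fit_light(sample$Xenc, sample$ncat, sample$Y, params, args$seed,
                      bop_multiset = isTRUE(args$bop_multiset))
    ests[[j]] <- f$oob_est
    ok <- ok & !f$degenerate
  }
  if (!any(ok))
    stop("no training row has usable out-of-bag estimates at all nodesize ",
         "levels; increase `ntree`", call. = FALSE)
  if (M == 1L) {
    warning("single-candidate nodesize grid: no MAD criterion computable",
            call. = FALSE)
    return(list(nodesize = grid[1L], grid = grid, mad = numeric(0),
                n_used = sum(ok)))
  }
  ut <- upper_tri_rowmajor(sample$q)
  flat <- lapply(ests, function(a) {
    m <- apply(a[, , ok, drop = FALSE], 3L, function(S) S[ut])
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
    m
  })
  madj <- vapply(seq_len(M - 1L), function(j) {
    mean(colMeans(abs(flat[[j]] - flat[[j + 1L]])))
  }, numeric(1))
  sel <- which.min(madj) # ties: smallest j (which.min is first-minimum)
  list(nodesize = grid[sel], grid = grid, mad = madj, n_used = sum(ok))
}

#' Tune the nodesize parameter by out-of-bag estimate stability
#'
#' The conditional covariance matrix is unobserved, so nodesize cannot be
#' tuned against a prediction error. Instead, one forest is fitted per
#' candidate level `s(1) < ... < s(M)` (see [candidate_grid()]) and, for
#' consecutive levels,
#' `MAD_j = mean_i MAD(Sigma_hat^{s(j)}_i, Sigma_hat^{s(j+1)}_i)`
#' with [mad_between()] averaged over training rows. The selected
#' nodesize is `s(j*)` for the `j*` minimizing `MAD_j` (`j` in
#' `1..M-1`; ties go to the smallest `j`): the level at which halving the
#' node size no longer changes the estimates much. All candidate forests
#' share per-tree subsamples (common random numbers via the master seed)
#' to reduce Monte Carlo noise in `MAD_j`. Rows lacking a usable
#' out-of-bag estimate at any level are dropped from every `MAD_j`
#' average.
#'
#' @inheritParams cov_forest
#' @return An object of class `cov_forest_tuning`: list with the selected
#'   `nodesize`, the candidate `grid`, the `mad` values (length `M - 1`),
#'   and `n_used`, the number of rows entering the averages.
#' @examples
#' sim <- dgp1(n = 150, seed = 3)
#' tune_nodesize(sim$X, sim$Y, ntree = 50, seed = 1)
#' @export
tune_nodesize <- function(X, Y, ntree = 1000, mtry = NULL, nsplit = NULL,
                          sampsize = NULL, min_child = 2, seed = NULL,
                          bop_multiset = FALSE) {
  sample <- cf_build_sample(X, Y)
  params <- cf_default_params(sample$n, sample$p, ntree = ntree, mtry = mtry,
                              nsplit = nsplit, sampsize = sampsize,
                              min_child = min_child)
  seed <- cf_default_seed(seed)
  res <- cf_tune(sample, c(params, list(seed = seed, bop_multiset = bop_multiset)))
  structure(res, class = "cov_forest_tuning")
}

#' @export
print.cov_forest_tuning <- function(x, ...) {
  cat("Nodesize tuning (OOB estimate stability)\n")
  cat("  grid:    ", paste(x$grid, collapse = " "), "\n")
  if (length(x$mad))
    cat("  MAD_j:   ", paste(signif(x$mad, 4), collapse = " "), "\n")
  cat("  selected:", x$nodesize, "\n")
  invisible(x)
}
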