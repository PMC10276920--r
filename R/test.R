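# Permutation tests for the effect of covariates on the conditional
# covariance matrix.
#
# Global test, H0: Sigma_X = Sigma_root (the unconditional sample
# covariance of Y). Partial test, H0: Sigma_X = Sigma_{X^c} for a control
# subset X^c. The test statistic is the mean over observations of the
# upper-triangle Euclidean distance between the paired estimates; its null
# distribution is obtained by refitting forests on row-permuted X.

#' Mean distance between two sets of covariance estimates
#'
#' `T = (1/n) * sum_i d(full_i, control_i)` with `d` the upper-triangle
#' Euclidean distance ([upper_tri_distance()]). This is the permutation
#' test statistic: larger values mean the full-model estimates deviate
#' more from the control-model estimates.
#'
#' @param full,control covariance estimates to compare: `q x q x n` arrays
#'   or lists of `q x q` matrices, pairwise aligned.
#' @return Nonnegative scalar.
#' @export
test_statistic <- function(full, control) {
  full <- as_cov_array(full)
  control <- as_cov_array(control)
  if (!all(dim(full) == dim(control)))
    stop("estimate sets must have matching dimensions", call. = FALSE)
  ut <- upper_tri_rowmajor(dim(full)[1])
  n <- dim(full)[3]
  d <- vapply(seq_len(n), function(i) {
    sqrt(sum((full[, , i][ut] - control[, , i][ut])^2))
  }, numeric(1))
  mean(d)
}

# fast internal version operating on cubes, no validation
cf_stat <- function(full, control, ut) {
  n <- dim(full)[3]
  s <- 0
  for (i in seq_len(n)) s <- s + sqrt(sum((full[, , i][ut] - control[, , i][ut])^2))
  s / n
}

# accept q x q x n array or list of matrices
as_cov_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x)) {
    q <- nrow(x[[1]])
    arr <- array(0, c(q, q, length(x)))
    for (i in seq_along(x)) arr[, , i] <- x[[i]]
    return(arr)
  }
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  stop("expected a q x q x n array or a list of square matrices", call. = FALSE)
}

# shared permutation engine. control_cols = NULL -> global test.
cf_perm_test <- function(sample, control_cols, R, ntree, mtry, nsplit,
                         nodesize, sampsize, min_child, seed, bop_multiset,
                         alpha, tune_ntree) {
  seed <- cf_default_seed(seed)
  params_full <- cf_default_params(sample$n, sample$p, ntree = ntree,
                                   mtry = mtry, nsplit = nsplit,
                                   nodesize = NULL, sampsize = sampsize,
                                   min_child = min_child)
  global <- is.null(control_cols)
  ut <- upper_tri_rowmajor(sample$q)

  # nodesize tuning on the original data only; the tuned values are reused
  # for every permutation replicate
  tune_args <- function(params) {
    list(ntree = if (is.null(tune_ntree)) params$ntree else tune_ntree,
         mtry = params$mtry, nsplit = params$nsplit,
         sampsize = params$sampsize, min_child = params$min_child,
         seed = seed, bop_multiset = bop_multiset)
  }
  ns_full <- nodesize
  if (is.null(ns_full)) ns_full <- cf_tune(sample, tune_args(params_full))$nodesize
  params_full$nodesize <- as.integer(ns_full)

  fit_full <- function(Xenc, fseed) {
    cf_fit_light(Xenc, sample$ncat, sample$Y, params_full, fseed,
                 bop_multiset = bop_multiset, fallback_uncond = TRUE)$oob_est
  }

  if (global) {
    sigma_root <- cov(sample$Y)
    root_arr <- array(sigma_root, c(sample$q, sample$q, sample$n))
    control_of <- function(Xenc, fseed) root_arr
    ns_ctrl <- NA_integer_
  } else {
    Xc <- sample$Xenc[, control_cols, drop = FALSE]
    ncat_c <- sample$ncat[control_cols]
    params_ctrl <- cf_default_params(sample$n, length(control_cols),
                                     ntree = ntree,
                                     mtry = min(ceiling(length(control_cols) / 3),
                                                length(control_cols)),
                                     nsplit = nsplit, nodesize = NULL,
                                     sampsize = sampsize, min_child = min_child)
    ctrl_sample <- list(Xenc = Xc, ncat = ncat_c, Y = sample$Y,
                        n = sample$n, p = length(control_cols), q = sample$q)
    ns_ctrl <- nodesize
    if (is.null(ns_ctrl)) ns_ctrl <- cf_tune(ctrl_sample, tune_args(params_ctrl))$nodesize
    params_ctrl$nodesize <- as.integer(ns_ctrl)
    control_of <- function(Xenc, fseed) {
      cf_fit_light(Xenc[, control_cols, drop = FALSE], ncat_c, sample$Y,
                   params_ctrl, fseed, bop_multiset = bop_multiset,
                   fallback_uncond = TRUE)$oob_est
    }
  }

  # permutations and per-replicate forest seeds derive from the master seed
  draws <- with_preserved_rng(seed, {
    list(fseed = sample.int(.Machine$integer.max, R + 1L),
         perms = replicate(R, sample.int(sample$n), simplify = FALSE))
  })

  # permutation scheme: the global test permutes whole rows of X; the
  # partial test permutes the rows of the *tested* (non-control) columns
  # only, keeping the control columns aligned with Y so that the null
  # holds the control-covariate effect fixed. Both forests are refit per
  # permutation (the control forest with a fresh seed on its unchanged
  # data), so every T_r carries the same two-forest Monte Carlo noise as
  # the observed T.
  permute_x <- function(perm) {
    if (global) {
      sample$Xenc[perm, , drop = FALSE]
    } else {
      Xp <- sample$Xenc
      tested <- setdiff(seq_len(sample$p), control_cols)
      Xp[, tested] <- Xp[perm, tested, drop = FALSE]
      Xp
    }
  }
  Tobs <- cf_stat(fit_full(sample$Xenc, draws$fseed[1L]),
                  control_of(sample$Xenc, draws$fseed[1L]), ut)
  Tr <- numeric(R)
  for (r in seq_len(R)) {
    Xp <- permute_x(draws$perms[[r]])
    fs <- draws$fseed[r + 1L]
    Tr[r] <- cf_stat(fit_full(Xp, fs), control_of(Xp, fs), ut)
  }
  p <- mean(Tr > Tobs) # strict inequality: p = 0 is reportable
  structure(list(type = if (global) "global" else "partial",
                 statistic = Tobs, perm_stats = Tr, p.value = p, R = R,
                 alpha = alpha, reject = p < alpha,
                 smoothed_p = (1 + sum(Tr > Tobs)) / (1 + R),
                 nodesize = params_full$nodesize, nodesize_control = ns_ctrl,
                 control = if (global) NULL else sample$xnames[control_cols],
                 seed = seed),
            class = "cov_forest_test")
}

#' Permutation test for the global effect of covariates
#'
#' Tests whether the conditional covariance estimates differ from the
#' unconditional sample covariance of `Y` (`Sigma_root`). The observed
#' statistic is the mean upper-triangle distance between the out-of-bag
#' estimates and `Sigma_root`; its null distribution is built by
#' refitting one forest on each of `R` row-permutations of `X` (so
#' `R + 1` forests in total). The p-value is the proportion of permuted
#' statistics strictly exceeding the observed one, so an estimated
#' p-value of exactly 0 is possible. Nodesize is tuned once on the
#' original data and reused for every permutation.
#'
#' @inheritParams cov_forest
#' @param R number of permutations (default 500).
#' @param alpha significance level used by the printed decision.
#' @param tune_ntree number of trees for the tuning forests (defaults to
#'   `ntree`).
#' @return An object of class `cov_forest_test` with the observed
#'   statistic, the permutation statistics, `p.value` (and a conventional
#'   `(1 + #)/(1 + R)` `smoothed_p` for users needing a nonzero
#'   estimate), and the tuned nodesize.
#' @examples
#' sim <- dgp3(n = 100, seed = 11)
#' global_test(sim$X, sim$Y, R = 20, ntree = 50, seed = 2)
#' @export
global_test <- function(X, Y, R = 500, ntree = 1000, mtry = NULL,
                        nsplit = NULL, nodesize = NULL, sampsize = NULL,
                        min_child = 2, seed = NULL, bop_multiset = FALSE,
                        alpha = 0.05, tune_ntree = NULL) {
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  sample <- cf_build_sample(X, Y)
  cf_perm_test(sample, NULL, as.integer(R), ntree, mtry, nsplit, nodesize,
               sampsize, min_child, seed, bop_multiset, alpha, tune_ntree)
}

#' Permutation test for the partial effect of a covariate subset
#'
#' Tests whether the covariates outside `control` carry information about
#' the conditional covariance matrix beyond the control set:
#' H0 is that the estimates given all covariates equal the estimates
#' given the control covariates only. Two forests are fitted per sample
#' (full and control-only; `2R + 2` forests in total); both nodesizes are
#' tuned once on the original data and reused across permutations. Each
#' permutation permutes the rows of the *tested* (non-control) columns
#' jointly while the control columns stay aligned with `Y` — so the null
#' holds the control effect fixed — and refits both forests (the control
#' forest with a fresh seed, keeping the same two-forest Monte Carlo
#' noise in every permuted statistic).
#'
#' @inheritParams global_test
#' @param control covariates to control for: column names or indices.
#'   Must be a nonempty proper subset of the covariates; an empty set
#'   delegates to [global_test()].
#' @return An object of class `cov_forest_test`.
#' @export
partial_test <- function(X, Y, control, R = 500, ntree = 1000, mtry = NULL,
                         nsplit = NULL, nodesize = NULL, sampsize = NULL,
                         min_child = 2, seed = NULL, bop_multiset = FALSE,
                         alpha = 0.05, tune_ntree = NULL) {
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  sample <- cf_build_sample(X, Y)
  if (missing(control) || length(control) == 0L)
    return(global_test(X, Y, R = R, ntree = ntree, mtry = mtry,
                       nsplit = nsplit, nodesize = nodesize,
                       sampsize = sampsize, min_child = min_child,
                       seed = seed, bop_multiset = bop_multiset,
                       alpha = alpha, tune_ntree = tune_ntree))
  if (is.character(control)) {
    control_cols <- match(control, sample$xnames)
    if (anyNA(control_cols))
      stop("unknown control covariates: ",
           paste(control[is.na(control_cols)], collapse = ", "), call. = FALSE)
  } else {
    control_cols <- as.integer(control)
    if (any(control_cols < 1L | control_cols > sample$p))
      stop("control column indices out of range", call. = FALSE)
  }
  control_cols <- sort(unique(control_cols))
  if (length(control_cols) >= sample$p)
    stop("`control` must be a proper subset of the covariates ",
         "(some covariate must be left to test)", call. = FALSE)
  cf_perm_test(sample, control_cols, as.integer(R), ntree, mtry, nsplit,
               nodesize, sampsize, min_child, seed, bop_multiset, alpha,
               tune_ntree)
}

#' @export
print.cov_forest_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s effect)\n", x$type))
  if (!is.null(x$control))
    cat("  controlling for:", paste(x$control, collapse = ", "), "\n")
  cat(sprintf("  T = %.6g   R = %d permutations\n", x$statistic, x$R))
  cat(sprintf("  p-value = %.4g  (%s H0 at alpha = %g)\n", x$p.value,
              if (x$reject) "reject" else "fail to reject", x$alpha))
  invisible(x)
}
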