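# Accuracy metrics comparing estimated and true covariance matrix sets.

#' Mean absolute error of estimated correlations
#'
#' Converts each covariance matrix to a correlation matrix and averages
#' `|rho_hat - rho|` over the `q(q-1)/2` off-diagonal upper-triangle
#' entries and all observations. Zero-variance estimates contribute a
#' correlation of 0 (with a warning); true covariances must have strictly
#' positive variances.
#'
#' @param est,truth covariance sets: `q x q x n` arrays or lists of
#'   `q x q` matrices, pairwise aligned, `q >= 2`.
#' @return Nonnegative scalar (at most 2).
#' @export
mae_cor <- function(est, truth) {
  est <- as_cov_array(est); truth <- as_cov_array(truth)
  check_metric_pair(est, truth)
  q <- dim(est)[1]
  off <- upper.tri(matrix(0, q, q))
  warned <- FALSE
  tot <- 0
  n <- dim(est)[3]
  for (i in seq_len(n)) {
    tot <- tot + sum(abs(safe_cor(est[, , i]) - cov2cor(truth[, , i]))[off])
    if (!warned && any(diag(est[, , i]) <= 0)) warned <- TRUE
  }
  if (warned)
    warning("zero-variance covariance estimate(s): correlations taken as 0",
            call. = FALSE)
  tot / (n * q * (q - 1) / 2)
}

# correlation conversion guarding zero variances
safe_cor <- function(S) {
  d <- diag(S)
  if (all(d > 0)) return(cov2cor(S))
  sdv <- sqrt(pmax(d, 0))
  C <- S / outer(sdv, sdv)
  C[!is.finite(C)] <- 0
  diag(C) <- ifelse(d > 0, 1, 0)
  C
}

#' Normalized mean absolute error of estimated standard deviations
#'
#' Averages `|sd_hat - sd| / sd` over the `q` response standard
#' deviations (matrix diagonals) and all observations. Scale-free: a
#' common rescaling of estimates and truth leaves it unchanged.
#'
#' @inheritParams mae_cor
#' @return Nonnegative scalar.
#' @export
mae_sd <- function(est, truth) {
  est <- as_cov_array(est); truth <- as_cov_array(truth)
  check_metric_pair(est, truth)
  n <- dim(est)[3]
  tot <- 0
  for (i in seq_len(n)) {
    sdt <- sqrt(diag(truth[, , i]))
    if (any(sdt <= 0)) stop("true standard deviations must be positive", call. = FALSE)
    tot <- tot + sum(abs(sqrt(pmax(diag(est[, , i]), 0)) - sdt) / sdt)
  }
  tot / (n * dim(est)[1])
}

#' Stein's loss between two covariance matrices
#'
#' `tr(est %*% solve(truth)) - log det(est %*% solve(truth)) - q`: twice
#' the Kullback-Leibler divergence of `N(0, est)` from `N(0, truth)` (the
#' direction is fixed with the estimate as first argument). Zero if and
#' only if the matrices are equal; requires both to be positive definite.
#'
#' @param est,truth positive-definite `q x q` matrices.
#' @return Nonnegative scalar.
#' @examples
#' stein_loss(2 * diag(2), diag(2)) # 4 - 2 * log(2) - 2
#' @export
stein_loss <- function(est, truth) {
  check_sym_pair(est, truth)
  q <- nrow(est)
  ct <- tryCatch(chol(truth), error = function(e)
    stop("`truth` must be positive definite", call. = FALSE))
  ce <- tryCatch(chol(est), error = function(e)
    stop("`est` must be positive definite (singular estimate); consider ",
         "regularizing", call. = FALSE))
  tinv <- chol2inv(ct)
  sum(diag(est %*% tinv)) - 2 * (sum(log(diag(ce))) - sum(log(diag(ct)))) - q
}

#' Accuracy report for a set of covariance estimates
#'
#' Convenience wrapper computing [mae_cor()], [mae_sd()] and the mean
#' [stein_loss()] over aligned estimate/truth sets.
#'
#' @inheritParams mae_cor
#' @return List with `mae_cor`, `mae_sd`, `mean_stein`, `n` and `q`.
#' @export
accuracy_report <- function(est, truth) {
  est <- as_cov_array(est); truth <- as_cov_array(truth)
  check_metric_pair(est, truth)
  n <- dim(est)[3]
  stein <- vapply(seq_len(n), function(i) stein_loss(est[, , i], truth[, , i]),
                  numeric(1))
  list(mae_cor = mae_cor(est, truth), mae_sd = mae_sd(est, truth),
       mean_stein = mean(stein), n = n, q = dim(est)[1])
}

check_metric_pair <- function(est, truth) {
  if (!all(dim(est) == dim(truth)))
    stop("`est` and `truth` must have matching dimensions", call. = FALSE)
  if (dim(est)[1] < 2L) stop("metrics require q >= 2", call. = FALSE)
}
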