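# Fit-the-fit variable importance.
#
# The covariance regression problem has no observed target, so importances
# cannot be read off the estimation forest directly. Instead the estimated
# covariance matrices (flattened upper triangles) are re-predicted by a
# multivariate regression forest with a Mahalanobis-distance splitting
# rule, and OOB permutation importance is computed on that forest.

#' Variable importance for a covariance regression forest
#'
#' Trains a multivariate regression forest on the original covariates with
#' the flattened upper triangles of the out-of-bag covariance estimates as
#' a multivariate response, then computes out-of-bag permutation
#' importance: for each covariate, its out-of-bag values are permuted
#' within each tree and the mean increase in per-response standardized
#' squared prediction error (averaged over the `q(q+1)/2` responses and
#' over trees) is recorded. Covariates with higher importance contribute
#' more to the estimated covariance structure.
#'
#' The re-prediction forest splits nodes by Mahalanobis impurity: node
#' impurity is `sum_i (z_i - zbar)' V^-1 (z_i - zbar)` with `z` the
#' flattened responses, `zbar` the node mean, and `V` the root-node
#' covariance of `z` (regularized by adding `eps * diag(V)` when
#' ill-conditioned); the chosen split maximizes the parent-minus-children
#' impurity decrease. Keeping `V` fixed at the root makes the metric
#' comparable across nodes and the rule linear-time per candidate.
#'
#' @param object a fitted [cov_forest()].
#' @param ntree trees in the re-prediction forest (default: as the fitted
#'   forest).
#' @param mtry covariates tried per node (default `ceiling(p/3)`).
#' @param nsplit random cut points per covariate (default: as the fitted
#'   forest).
#' @param nodesize stop-splitting threshold of the re-prediction forest
#'   (default 5, the usual regression-forest default; this forest is not
#'   tuned).
#' @param seed master seed for the re-prediction forest (default: derived
#'   from the fitted forest's seed).
#' @param eps diagonal regularization factor for the Mahalanobis metric.
#' @return An object of class `cov_forest_vimp`: a data frame with one
#'   row per covariate and columns `variable`, `importance` (raw mean
#'   error increase), `normalized` (importance / max importance, in
#'   `[0, 1]`), and `rank` (1 = most important).
#' @examples
#' sim <- dgp3(n = 150, seed = 5)
#' fit <- cov_forest(sim$X, sim$Y, ntree = 60, nodesize = 20, seed = 9)
#' vimp(fit, ntree = 60)
#' @export
vimp <- function(object, ntree = NULL, mtry = NULL, nsplit = NULL,
                 nodesize = 5, seed = NULL, eps = 1e-6) {
  stopifnot(inherits(object, "cov_forest"))
  s <- object$sample
  Z <- flatten_cov_array(object$oob$sigma)
  if (nrow(unique(Z)) < 2L) {
    warning("fewer than 2 distinct covariance estimates: importances are ",
            "all zero", call. = FALSE)
    res <- data.frame(variable = s$xnames, importance = 0, normalized = 0,
                      rank = seq_len(s$p))
    return(structure(res, class = c("cov_forest_vimp", "data.frame")))
  }
  if (is.null(ntree)) ntree <- object$params$ntree
  if (is.null(mtry)) mtry <- ceiling(s$p / 3)
  if (is.null(nsplit)) nsplit <- object$params$nsplit
  if (is.null(seed)) seed <- object$seed + 0x5f3759
  params <- cf_default_params(s$n, s$p, ntree = ntree, mtry = mtry,
                              nsplit = nsplit, nodesize = nodesize,
                              min_child = object$params$min_child)
  raw <- cpp_vimp_forest(s$Xenc, as.integer(s$ncat), Z,
                         params$ntree, params$mtry, params$nsplit,
                         as.integer(nodesize), params$sampsize,
                         params$min_child, as.numeric(seed), eps)$importance
  mx <- max(raw)
  normalized <- if (mx > 0) pmax(raw, 0) / mx else rep(0, s$p)
  res <- data.frame(variable = s$xnames, importance = raw,
                    normalized = normalized,
                    rank = rank(-raw, ties.method = "first"))
  structure(res[order(res$rank), , drop = FALSE],
            class = c("cov_forest_vimp", "data.frame"))
}

#' @export
print.cov_forest_vimp <- function(x, digits = 4, ...) {
  cat("Fit-the-fit variable importance\n")
  df <- data.frame(variable = x$variable,
                   importance = signif(x$importance, digits),
                   normalized = signif(x$normalized, digits),
                   rank = x$rank)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
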