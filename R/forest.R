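# Forest fitting and prediction.

# Light internal fit: trains a forest and returns the training-row OOB BOP
# covariance estimates without materializing tree structures. Used by the
# tuning loop and the permutation tests, where thousands of forests are
# fitted and only the estimates matter.
cf_fit_light <- function(Xenc, ncat, Y, params, seed, bop_multiset = FALSE,
                         exclude_self = TRUE, fallback_uncond = FALSE) {
  cpp_cov_forest(Xenc, as.integer(ncat), Y,
                 params$ntree, params$mtry, params$nsplit,
                 as.integer(params$nodesize), params$sampsize,
                 params$min_child, as.numeric(seed),
                 FALSE, bop_multiset, exclude_self, fallback_uncond, FALSE)
}

#' Fit a covariance regression forest
#'
#' Grows `ntree` unsupervised CART-style trees on random subsamples drawn
#' without replacement. At each node the split maximizing
#' `sqrt(n_L * n_R) * d(Sigma_L, Sigma_R)` is chosen among `nsplit` random
#' cut points (numeric covariates) or random level subsets (categorical
#' covariates) of `mtry` randomly drawn covariates, where `d` is
#' [upper_tri_distance()] and `Sigma_L`, `Sigma_R` are the child sample
#' covariances of `Y`. The conditional covariance estimate for any target
#' observation is the sample covariance of its bag of observations for
#' prediction (BOP): the union, over trees, of out-of-bag observations
#' sharing the target's terminal node. Out-of-bag estimates for the
#' training rows are computed at fit time (for row `i`, only trees where
#' `i` is itself out-of-bag contribute, and `i` is excluded from its own
#' neighbour set).
#'
#' When `nodesize` is `NULL` it is selected by [tune_nodesize()]: one
#' forest per candidate level is fitted with common subsamples and the
#' level at which consecutive OOB estimates stabilize is kept.
#'
#' @param X covariate matrix or data frame (numeric and/or categorical
#'   columns); categorical level sets are fixed at fit time.
#' @param Y numeric response matrix with at least two columns.
#' @param ntree number of trees (default 1000).
#' @param mtry number of covariates tried per node; default `ceiling(p/3)`.
#' @param nsplit number of random cut points / level subsets per covariate
#'   per node; default `max(ceiling(n/50), 10)`.
#' @param nodesize stop-splitting threshold: nodes holding `nodesize` or
#'   fewer rows are terminal. `NULL` (default) tunes it.
#' @param sampsize subsample size per tree, drawn without replacement;
#'   default `floor(0.632 * n)`.
#' @param min_child smallest admissible child node (default 2, so both
#'   child covariances are defined).
#' @param seed master seed; all tree-level randomness derives from it, so
#'   fits are exactly reproducible.
#' @param bop_multiset if `TRUE`, BOP members contributed by several trees
#'   are counted with multiplicity (pooled semantics); the default `FALSE`
#'   follows the set-union definition.
#' @param degenerate what to do when a BOP has fewer than 2 members:
#'   `"error"` (default) or `"unconditional"` (fall back to the sample
#'   covariance of all of `Y`).
#' @param tune_args list of overrides passed to [tune_nodesize()] (e.g.
#'   `ntree` for the tuning forests).
#' @return An object of class `cov_forest`: the trees, per-tree in-bag
#'   index sets, terminal-node memberships, out-of-bag covariance
#'   estimates (`$oob`), the parameters used, and the tuning trace when
#'   nodesize was tuned.
#' @seealso [predict.cov_forest()], [oob_estimates()], [vimp()],
#'   [global_test()], [partial_test()]
#' @examples
#' sim <- dgp1(n = 120, seed = 7)
#' fit <- cov_forest(sim$X, sim$Y, ntree = 50, nodesize = 20, seed = 1)
#' fit
#' est <- predict(fit, sim$X[1:3, , drop = FALSE])
#' est$sigma[, , 1]
#' @export
cov_forest <- function(X, Y, ntree = 1000, mtry = NULL, nsplit = NULL,
                       nodesize = NULL, sampsize = NULL, min_child = 2,
                       seed = NULL, bop_multiset = FALSE,
                       degenerate = c("error", "unconditional"),
                       tune_args = list()) {
  degenerate <- match.arg(degenerate)
  sample <- cf_build_sample(X, Y)
  params <- cf_default_params(sample$n, sample$p, ntree = ntree, mtry = mtry,
                              nsplit = nsplit, nodesize = nodesize,
                              sampsize = sampsize, min_child = min_child)
  seed <- cf_default_seed(seed)

  tuning <- NULL
  if (is.null(params$nodesize)) {
    targs <- modifyList(list(ntree = params$ntree, mtry = params$mtry,
                             nsplit = params$nsplit, sampsize = params$sampsize,
                             min_child = params$min_child, seed = seed,
                             bop_multiset = bop_multiset), tune_args)
    tuning <- cf_tune(sample, targs)
    params$nodesize <- tuning$nodesize
  }
  params$nodesize <- as.integer(params$nodesize)
  if (params$nodesize <= sample$q)
    warning("nodesize <= q: terminal-node covariance estimates may be singular",
            call. = FALSE)

  fit <- cpp_cov_forest(sample$Xenc, as.integer(sample$ncat), sample$Y,
                        params$ntree, params$mtry, params$nsplit,
                        params$nodesize, params$sampsize, params$min_child,
                        as.numeric(seed), TRUE, bop_multiset, TRUE,
                        degenerate == "unconditional", TRUE)
  if (degenerate == "error" && any(fit$degenerate))
    stop(sum(fit$degenerate), " training row(s) have an out-of-bag ",
         "neighbour set with fewer than 2 members; increase `ntree` or use ",
         'degenerate = "unconditional"', call. = FALSE)

  oob <- list(sigma = cf_name_cov_array(fit$oob_est, sample$ynames),
              bop_size = as.integer(fit$bop_size),
              degenerate = as.logical(fit$degenerate))
  structure(list(trees = fit$trees, inbag = fit$inbag, term = fit$term,
                 oob = oob, bops = fit$bops, params = params, seed = seed,
                 bop_multiset = bop_multiset, degenerate = degenerate,
                 sample = sample, tuning = tuning, call = match.call()),
            class = "cov_forest")
}

cf_name_cov_array <- function(arr, ynames) {
  dimnames(arr) <- list(ynames, ynames, NULL)
  arr
}

#' @export
print.cov_forest <- function(x, ...) {
  p <- x$params
  cat("Covariance regression forest\n")
  cat(sprintf("  observations: %d   covariates: %d   responses: %d\n",
              x$sample$n, x$sample$p, x$sample$q))
  cat(sprintf("  trees: %d   mtry: %d   nsplit: %d   sampsize: %d\n",
              p$ntree, p$mtry, p$nsplit, p$sampsize))
  cat(sprintf("  nodesize: %d%s\n", p$nodesize,
              if (!is.null(x$tuning)) sprintf(" (tuned over {%s})",
                paste(x$tuning$grid, collapse = ", ")) else ""))
  cat(sprintf("  median OOB neighbour-set size: %d\n",
              as.integer(stats::median(x$oob$bop_size))))
  invisible(x)
}

#' Out-of-bag covariance estimates of the training rows
#'
#' Returns the per-row conditional covariance estimates computed from each
#' training row's out-of-bag BOP (only trees where the row itself is
#' out-of-bag contribute, and the row is excluded from its own set).
#'
#' @param object a fitted [cov_forest()].
#' @return List with `sigma` (`q x q x n` array), `bop_size` and
#'   `degenerate` flags.
#' @export
oob_estimates <- function(object) {
  stopifnot(inherits(object, "cov_forest"))
  object$oob
}

#' Estimate conditional covariance matrices for new observations
#'
#' Routes each new observation down every tree, collects the out-of-bag
#' training observations sharing its terminal nodes (the BOP), and returns
#' the sample covariance of their responses. Categorical levels unseen at
#' fit time are routed down both children and the contributions merged.
#'
#' @param object a fitted [cov_forest()].
#' @param newdata covariate data with the training schema.
#' @param ... unused.
#' @return An object of class `cov_forest_prediction`: list with `sigma`
#'   (`q x q x m` array of estimates), `bop_size`, and `degenerate` flags.
#'   `as.data.frame()` turns it into a flattened upper-triangle table with
#'   columns `sigma_<Yj>_<Yk>` (j <= k) plus `bop_size`.
#' @export
predict.cov_forest <- function(object, newdata, ...) {
  Xenc <- cf_encode_newdata(object$sample, newdata)
  pr <- cpp_cov_forest_predict(object$trees, as.integer(object$sample$ncat),
                               Xenc, object$sample$Y, object$inbag,
                               object$term, object$bop_multiset,
                               object$degenerate == "unconditional", FALSE)
  if (object$degenerate == "error" && any(pr$degenerate))
    stop(sum(pr$degenerate), " new observation(s) have a neighbour set with ",
         "fewer than 2 members; increase `ntree` or use ",
         'degenerate = "unconditional"', call. = FALSE)
  structure(list(sigma = cf_name_cov_array(pr$est, object$sample$ynames),
                 bop_size = as.integer(pr$bop_size),
                 degenerate = as.logical(pr$degenerate),
                 ynames = object$sample$ynames),
            class = "cov_forest_prediction")
}

#' @export
print.cov_forest_prediction <- function(x, ...) {
  cat(sprintf("Conditional covariance estimates for %d observation(s) (q = %d)\n",
              dim(x$sigma)[3], dim(x$sigma)[1]))
  invisible(x)
}

#' @export
as.data.frame.cov_forest_prediction <- function(x, ...) {
  flat <- flatten_cov_array(x$sigma)
  colnames(flat) <- flat_names(x$ynames)
  df <- as.data.frame(flat)
  df$bop_size <- x$bop_size
  df
}

#' Bag of observations for prediction
#'
#' `bop_for_training()` returns, for training row `i`, the union over the
#' trees where `i` is out-of-bag of the out-of-bag observations sharing
#' `i`'s terminal node, excluding `i` itself (unless the forest was fitted
#' with self-inclusion). `bop_for_new()` returns the analogous union over
#' all trees for new observations.
#'
#' @param object a fitted [cov_forest()].
#' @param i training row index.
#' @return An integer vector of training row indices (`bop_for_training`),
#'   or a list of such vectors, one per row of `newdata` (`bop_for_new`).
#' @export
bop_for_training <- function(object, i) {
  stopifnot(inherits(object, "cov_forest"))
  i <- as.integer(i)
  if (i < 1L || i > object$sample$n) stop("`i` out of range", call. = FALSE)
  members <- object$bops[[i]]
  if (length(members) == 0L)
    stop("training row ", i, " has an empty out-of-bag neighbour set; ",
         "increase `ntree`", call. = FALSE)
  members
}

#' @rdname bop_for_training
#' @param newdata covariate data with the training schema.
#' @export
bop_for_new <- function(object, newdata) {
  stopifnot(inherits(object, "cov_forest"))
  Xenc <- cf_encode_newdata(object$sample, newdata)
  pr <- cpp_cov_forest_predict(object$trees, as.integer(object$sample$ncat),
                               Xenc, object$sample$Y, object$inbag,
                               object$term, object$bop_multiset, TRUE, TRUE)
  pr$bops
}
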