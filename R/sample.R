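# Input validation and covariate encoding shared by all fitting entry
# points. Categorical covariates are encoded as integer level codes (0-based
# for the C++ core); level sets are fixed at fit time.

MAX_CAT_LEVELS <- 31L

# Build the internal paired-sample representation from user inputs.
# X: data.frame or matrix (numeric and/or categorical columns)
# Y: numeric matrix/data.frame with q >= 2 columns
cf_build_sample <- function(X, Y) {
  if (is.matrix(X)) X <- as.data.frame(X, stringsAsFactors = FALSE)
  if (!is.data.frame(X)) stop("`X` must be a matrix or data frame", call. = FALSE)
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("`Y` must be numeric", call. = FALSE)
  if (nrow(X) != nrow(Y))
    stop("`X` and `Y` must have the same number of rows", call. = FALSE)
  if (ncol(Y) < 2L)
    stop("`Y` must have at least two response columns (q >= 2)", call. = FALSE)
  if (nrow(Y) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (anyNA(Y)) stop("`Y` contains missing values", call. = FALSE)
  if (anyNA(X)) stop("`X` contains missing values", call. = FALSE)
  if (anyDuplicated(names(X))) stop("duplicate covariate names", call. = FALSE)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  if (anyDuplicated(colnames(Y))) stop("duplicate response names", call. = FALSE)

  p <- ncol(X)
  if (p < 1L) stop("`X` must have at least one covariate", call. = FALSE)
  xlevels <- vector("list", p)
  ncat <- integer(p)
  Xenc <- matrix(0, nrow(X), p, dimnames = list(NULL, names(X)))
  for (j in seq_len(p)) {
    col <- X[[j]]
    if (is.numeric(col)) {
      Xenc[, j] <- as.numeric(col)
    } else if (is.factor(col) || is.character(col) || is.logical(col)) {
      lev <- sort(unique(as.character(col)))
      if (length(lev) > MAX_CAT_LEVELS)
        stop("categorical covariate `", names(X)[j], "` has more than ",
             MAX_CAT_LEVELS, " levels", call. = FALSE)
      if (length(lev) < 1L) stop("empty categorical covariate", call. = FALSE)
      xlevels[[j]] <- lev
      ncat[j] <- length(lev)
      Xenc[, j] <- match(as.character(col), lev) - 1
    } else {
      stop("unsupported column type in `X`: ", names(X)[j], call. = FALSE)
    }
  }
  structure(list(X = X, Xenc = Xenc, ncat = ncat, xlevels = xlevels,
                 Y = Y, n = nrow(Y), p = p, q = ncol(Y),
                 xnames = names(X), ynames = colnames(Y)),
            class = "cf_sample")
}

# Encode new covariate data against the training schema. Unseen categorical
# levels are encoded as -1: the C++ router sends such rows down both
# children of a split on that covariate and merges the contributions.
cf_encode_newdata <- function(sample, newdata) {
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata, stringsAsFactors = FALSE)
  if (!is.data.frame(newdata)) stop("`newdata` must be a matrix or data frame", call. = FALSE)
  missing_cols <- setdiff(sample$xnames, names(newdata))
  if (length(missing_cols) > 0L)
    stop("`newdata` is missing covariates: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  newdata <- newdata[sample$xnames]
  if (anyNA(newdata)) stop("`newdata` contains missing values", call. = FALSE)
  Xenc <- matrix(0, nrow(newdata), sample$p, dimnames = list(NULL, sample$xnames))
  unseen <- FALSE
  for (j in seq_len(sample$p)) {
    col <- newdata[[j]]
    if (sample$ncat[j] == 0L) {
      if (!is.numeric(col))
        stop("covariate `", sample$xnames[j], "` must be numeric", call. = FALSE)
      Xenc[, j] <- as.numeric(col)
    } else {
      code <- match(as.character(col), sample$xlevels[[j]]) - 1
      if (anyNA(code)) unseen <- TRUE
      code[is.na(code)] <- -1
      Xenc[, j] <- code
    }
  }
  if (unseen)
    warning("`newdata` contains categorical levels unseen at fit time; ",
            "affected rows are routed down both children at splits on that ",
            "covariate", call. = FALSE)
  Xenc
}

# subsample-based defaults mirroring the method's recommended settings
cf_default_params <- function(n, p, ntree = 1000L, mtry = NULL, nsplit = NULL,
                              nodesize = NULL, sampsize = NULL, min_child = 2L) {
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  if (is.null(sampsize)) sampsize <- floor(0.632 * n)
  if (is.null(nsplit)) nsplit <- max(ceiling(n / 50), 10L)
  mtry <- as.integer(mtry); nsplit <- as.integer(nsplit)
  sampsize <- as.integer(sampsize); ntree <- as.integer(ntree)
  min_child <- as.integer(min_child)
  if (ntree < 1L) stop("`ntree` must be >= 1", call. = FALSE)
  if (mtry < 1L || mtry > p) stop("`mtry` must be in [1, p]", call. = FALSE)
  if (nsplit < 1L) stop("`nsplit` must be >= 1", call. = FALSE)
  if (min_child < 2L) stop("`min_child` must be >= 2", call. = FALSE)
  if (sampsize >= n) stop("`sampsize` must be smaller than n", call. = FALSE)
  if (sampsize < 2L * min_child)
    stop("`sampsize` too small: fewer than 2 * min_child in-bag rows", call. = FALSE)
  list(ntree = ntree, mtry = mtry, nsplit = nsplit, nodesize = nodesize,
       sampsize = sampsize, min_child = min_child)
}

# draw a master seed without perturbing the caller's RNG stream more than once
cf_default_seed <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.numeric(seed)
    if (!is.finite(seed)) stop("`seed` must be a finite number", call. = FALSE)
    return(seed)
  }
  sample.int(.Machine$integer.max, 1L)
}

# evaluate an expression with the global RNG state restored afterwards
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
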