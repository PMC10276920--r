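# Small matrix kernels shared by the splitting rule, the tuning criterion
# and the test statistic. These are also the reference implementations used
# to validate the compiled tree code.

check_sym_pair <- function(D, E) {
  if (!is.matrix(D) || !is.matrix(E) || nrow(D) != ncol(D) || nrow(E) != ncol(E))
    stop("inputs must be square matrices", call. = FALSE)
  if (!all(dim(D) == dim(E))) stop("dimension mismatch", call. = FALSE)
}

#' Euclidean distance between the upper triangles of two symmetric matrices
#'
#' Computes `sqrt(sum_{i <= j} (D_ij - E_ij)^2)`, i.e. the Euclidean
#' distance over the upper-triangular entries including the diagonal, each
#' counted once. This is the distance the splitting rule and the
#' permutation-test statistic are built on; counting each off-diagonal
#' entry once avoids double-weighting the covariances of a symmetric
#' matrix.
#'
#' @param D,E symmetric numeric matrices of equal dimension.
#' @return A nonnegative scalar; zero if and only if `D == E` on the upper
#'   triangle.
#' @examples
#' upper_tri_distance(diag(2), matrix(c(2, 1, 1, 2), 2)) # sqrt(3)
#' @export
upper_tri_distance <- function(D, E) {
  check_sym_pair(D, E)
  ut <- upper.tri(D, diag = TRUE)
  sqrt(sum((D[ut] - E[ut])^2))
}

#' Mean absolute difference between the upper triangles of two symmetric
#' matrices
#'
#' Computes `2 / (q * (q + 1)) * sum_{i <= j} |D_ij - E_ij|`: the average
#' per-entry absolute difference over the upper triangle including the
#' diagonal. Used by the nodesize tuning criterion to measure the
#' stability of out-of-bag covariance estimates across consecutive
#' nodesize levels.
#'
#' @inheritParams upper_tri_distance
#' @return A nonnegative scalar.
#' @export
mad_between <- function(D, E) {
  check_sym_pair(D, E)
  ut <- upper.tri(D, diag = TRUE)
  mean(abs(D[ut] - E[ut]))
}

#' Unbiased sample covariance matrix of selected rows
#'
#' The node covariance used by the splitting rule: the textbook unbiased
#' (denominator `n - 1`) sample covariance of the selected response rows,
#' centred at the node mean.
#'
#' @param rows integer vector of row indices (at least 2).
#' @param Y numeric response matrix.
#' @return A symmetric positive semi-definite `q x q` matrix.
#' @export
node_covariance <- function(rows, Y) {
  Y <- as.matrix(Y)
  if (length(rows) < 2L)
    stop("degenerate node: need at least 2 rows for a covariance", call. = FALSE)
  cov(Y[rows, , drop = FALSE])
}

#' Covariance-heterogeneity score of a candidate split
#'
#' `sqrt(n_L * n_R) * upper_tri_distance(Sigma_L, Sigma_R)` where
#' `Sigma_L`, `Sigma_R` are the unbiased sample covariances of the two
#' child nodes. Trees are grown by maximizing this score over candidate
#' splits; the `sqrt(n_L * n_R)` factor favours balanced children.
#' Returns `NA` (candidate rejected, not an error) when either side has
#' fewer than `min_child` rows.
#'
#' @param left_rows,right_rows integer index vectors for the two children.
#' @param Y numeric response matrix.
#' @param min_child minimum child size for a split to be evaluable
#'   (default 2, the smallest size with a defined covariance).
#' @return Nonnegative scalar score, or `NA_real_` for an infeasible
#'   candidate.
#' @export
split_score <- function(left_rows, right_rows, Y, min_child = 2L) {
  nl <- length(left_rows); nr <- length(right_rows)
  if (nl < min_child || nr < min_child) return(NA_real_)
  sqrt(nl * nr) * upper_tri_distance(node_covariance(left_rows, Y),
                                     node_covariance(right_rows, Y))
}

#' Flatten the upper triangle of a symmetric matrix
#'
#' Row-major upper-triangle order: `(S[1,1], S[1,2], ..., S[1,q], S[2,2],
#' ..., S[q,q])`. This fixed order is used for the multivariate response
#' of the importance re-prediction forest and for flattened-covariance
#' output tables. [unflatten_upper_tri()] inverts it.
#'
#' @param S symmetric `q x q` matrix.
#' @return Numeric vector of length `q * (q + 1) / 2`.
#' @export
flatten_upper_tri <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("`S` must be square", call. = FALSE)
  S[upper_tri_rowmajor(nrow(S))]
}

#' @rdname flatten_upper_tri
#' @param v flattened upper triangle as produced by [flatten_upper_tri()].
#' @param q matrix dimension.
#' @export
unflatten_upper_tri <- function(v, q) {
  if (length(v) != q * (q + 1) / 2) stop("length of `v` does not match `q`", call. = FALSE)
  S <- matrix(0, q, q)
  S[upper_tri_rowmajor(q)] <- v
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

# linear indices of the upper triangle (diag included) in row-major order,
# i.e. (1,1),(1,2),...,(1,q),(2,2),...: column-major R indices computed once
upper_tri_rowmajor <- function(q) {
  idx <- integer(q * (q + 1) / 2)
  k <- 1L
  for (i in seq_len(q)) {
    for (j in i:q) {
      idx[k] <- i + (j - 1L) * q
      k <- k + 1L
    }
  }
  idx
}

# names for flattened covariance columns: sigma_Y1_Y1, sigma_Y1_Y2, ...
flat_names <- function(ynames) {
  q <- length(ynames)
  nm <- character(q * (q + 1) / 2)
  k <- 1L
  for (i in seq_len(q)) {
    for (j in i:q) {
      nm[k] <- paste0("sigma_", ynames[i], "_", ynames[j])
      k <- k + 1L
    }
  }
  nm
}

# flatten an array of covariance matrices (q x q x n) into n x m rows
flatten_cov_array <- function(arr) {
  q <- dim(arr)[1]
  idx <- upper_tri_rowmajor(q)
  t(apply(arr, 3L, function(S) S[idx]))
}
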