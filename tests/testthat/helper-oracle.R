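# Independent reference implementations used as oracles. These deliberately
# re-derive everything from first principles (two-pass covariances, full
# enumeration of splits, plain R tree routing) and never call the package's
# compiled core.

# two-pass sample covariance
o_cov <- function(rows, Y) {
  Yr <- Y[rows, , drop = FALSE]
  mu <- colMeans(Yr)
  cent <- sweep(Yr, 2, mu)
  crossprod(cent) / (nrow(Yr) - 1)
}

o_utd <- function(D, E) {
  ut <- upper.tri(D, diag = TRUE)
  sqrt(sum((D[ut] - E[ut])^2))
}

o_split_score <- function(left, right, Y) {
  if (length(left) < 2 || length(right) < 2) return(NA_real_)
  sqrt(length(left) * length(right)) * o_utd(o_cov(left, Y), o_cov(right, Y))
}

# exhaustive best split over all covariates, all numeric midpoints and all
# proper categorical level subsets; returns the maximal score
o_best_split <- function(X, Y, rows, min_child = 2) {
  best <- -Inf
  for (v in seq_len(ncol(X))) {
    col <- X[[v]]
    if (is.numeric(col)) {
      vals <- sort(unique(col[rows]))
      if (length(vals) < 2) next
      cuts <- (vals[-1] + vals[-length(vals)]) / 2
      for (cc in cuts) {
        l <- rows[col[rows] <= cc]
        r <- setdiff(rows, l)
        if (length(l) < min_child || length(r) < min_child) next
        s <- o_split_score(l, r, Y)
        if (!is.na(s) && s > best) best <- s
      }
    } else {
      lev <- sort(unique(as.character(col[rows])))
      if (length(lev) < 2) next
      # all proper subsets containing the first level (canonical halves)
      rest <- lev[-1]
      for (j in 0:(2^length(rest) - 1)) {
        sub <- c(lev[1], rest[bitwAnd(bitwShiftR(j, seq_along(rest) - 1), 1) == 1])
        if (length(sub) == length(lev)) next
        l <- rows[as.character(col[rows]) %in% sub]
        r <- setdiff(rows, l)
        if (length(l) < min_child || length(r) < min_child) next
        s <- o_split_score(l, r, Y)
        if (!is.na(s) && s > best) best <- s
      }
    }
  }
  best
}

# route a row through an exported tree structure (plain R re-implementation)
o_route <- function(tree, xenc, ncat) {
  nd <- 1L
  repeat {
    v <- tree$var[nd]
    if (v < 0L) return(nd)
    code <- xenc[v + 1L]
    goleft <- if (ncat[v + 1L] == 0L) code <= tree$thr[nd]
              else code >= 0 && bitwAnd(bitwShiftR(as.integer(tree$mask[nd]), as.integer(code)), 1L) == 1L
    nd <- if (goleft) tree$left[nd] + 1L else tree$right[nd] + 1L
  }
}

# independent BOP construction for training row i (1-based) from exported
# tree structures: union over trees where i is OOB of OOB co-members of its
# terminal node, excluding i
o_bop_training <- function(fit, i) {
  s <- fit$sample
  members <- integer(0)
  for (b in seq_along(fit$trees)) {
    inbag <- fit$inbag[, b]
    if (i %in% inbag) next
    term_i <- o_route(fit$trees[[b]], s$Xenc[i, ], s$ncat)
    oob <- setdiff(seq_len(s$n), inbag)
    co <- oob[vapply(oob, function(j)
      o_route(fit$trees[[b]], s$Xenc[j, ], s$ncat) == term_i, logical(1))]
    members <- union(members, setdiff(co, i))
  }
  sort(members)
}

o_bop_new <- function(fit, xenc) {
  s <- fit$sample
  members <- integer(0)
  for (b in seq_along(fit$trees)) {
    term <- o_route(fit$trees[[b]], xenc, s$ncat)
    oob <- setdiff(seq_len(s$n), fit$inbag[, b])
    co <- oob[vapply(oob, function(j)
      o_route(fit$trees[[b]], s$Xenc[j, ], s$ncat) == term, logical(1))]
    members <- union(members, co)
  }
  sort(members)
}

# small random covariance-regression dataset for property tests
make_toy <- function(n, p = 2, q = 2, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(runif(n * p), n, p))
  names(X) <- paste0("x", seq_len(p))
  Y <- matrix(rnorm(n * q), n, q)
  list(X = X, Y = Y)
}

random_spd <- function(q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(q * q), q)
  crossprod(A) + diag(q) * 0.1
}
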