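# Heteroscedastic multivariate normal data generators with known true
# per-observation covariance matrices. These are first-class, tested
# generators: every estimation and testing component of the package can be
# validated against them without external data.
#
# The concrete constants (Psi and B for the quadratic-form generators, the
# depth-3 tree and leaf correlations of the AR(1) generator, the logit
# coefficients of the compound-symmetry generator) are this package's own
# frozen choices, selected so that both correlations and variances vary
# with the covariates; they are synthetic defaults, not estimates from any
# external dataset.

# frozen generator constants
DGP_PSI <- diag(2)
DGP_B <- rbind(c(1.0, 0.9),
               c(0.5, -0.8))
DGP3_LEAF_RHO <- c(0.05, 0.17, 0.29, 0.41, 0.53, 0.66, 0.78, 0.90)
DGP4_BETA <- c(2, 1, 0.5)

new_cov_sim <- function(X, Y, sigma, generator, params, seed) {
  colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  structure(list(X = X, Y = Y, sigma = sigma, generator = generator,
                 params = params, seed = seed),
            class = "cov_sim")
}

#' @export
print.cov_sim <- function(x, ...) {
  cat(sprintf("Simulated covariance-regression dataset (%s): n = %d, p = %d, q = %d\n",
              x$generator, nrow(x$Y), ncol(x$X), ncol(x$Y)))
  invisible(x)
}

# draw Y_i ~ N(0, sigma_i) row by row
draw_mvn <- function(sigma) {
  n <- dim(sigma)[3]; q <- dim(sigma)[1]
  Y <- matrix(rnorm(n * q), n, q)
  for (i in seq_len(n)) Y[i, ] <- Y[i, ] %*% chol(sigma[, , i])
  Y
}

#' Quadratic-form covariance generators (single covariate)
#'
#' `dgp1()` draws a single covariate `x` uniformly on `[-1, 1]` and sets
#' `Sigma_x = Psi + B (1, x)' (1, x) B'`, so the covariance matrix is a
#' quadratic function of the covariate: `Sigma_x - Psi` is positive
#' semi-definite of rank at most one. `dgp2()` is identical except that
#' the regressor is `(1, x + x^2)`, adding a quadratic term (so, e.g.,
#' `x = -1` and `x = 0` share the same covariance). Responses are drawn
#' from `N(0, Sigma_x)` row by row.
#'
#' @param n sample size.
#' @param psi symmetric positive-definite `q x q` baseline covariance
#'   (default: identity, q = 2).
#' @param b `q x 2` coefficient matrix; the default has distinct nonzero
#'   rows so that both correlations and variances vary over `x`.
#' @param seed RNG seed (the caller's RNG state is restored afterwards).
#' @return An object of class `cov_sim`: list with covariate data frame
#'   `X`, response matrix `Y`, the true `q x q x n` covariance array
#'   `sigma`, and the generator record.
#' @export
dgp1 <- function(n, psi = DGP_PSI, b = DGP_B, seed = NULL) {
  dgp_quadratic(n, psi, b, quadratic = FALSE, seed = seed, name = "dgp1")
}

#' @rdname dgp1
#' @export
dgp2 <- function(n, psi = DGP_PSI, b = DGP_B, seed = NULL) {
  dgp_quadratic(n, psi, b, quadratic = TRUE, seed = seed, name = "dgp2")
}

dgp_quadratic <- function(n, psi, b, quadratic, seed, name) {
  psi <- as.matrix(psi); b <- as.matrix(b)
  q <- nrow(psi)
  if (ncol(psi) != q || q < 2L) stop("`psi` must be square with q >= 2", call. = FALSE)
  if (!isSymmetric(psi, tol = 1e-10)) stop("`psi` must be symmetric", call. = FALSE)
  if (min(eigen(psi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("`psi` must be positive definite", call. = FALSE)
  if (nrow(b) != q || ncol(b) != 2L) stop("`b` must be q x 2", call. = FALSE)
  seed <- cf_default_seed(seed)
  with_preserved_rng(seed, {
    x <- runif(n, -1, 1)
    reg <- if (quadratic) x + x^2 else x
    sigma <- array(0, c(q, q, n))
    for (i in seq_len(n)) {
      u <- b %*% c(1, reg[i])
      sigma[, , i] <- psi + u %*% t(u)
    }
    Y <- draw_mvn(sigma)
    new_cov_sim(data.frame(x1 = x), Y, sigma, name,
                list(psi = psi, b = b), seed)
  })
}

#' AR(1) covariance generator driven by a depth-3 covariate tree
#'
#' Seven independent standard-normal covariates; each observation is
#' routed down a fixed depth-3 binary tree (root split on `X1`, then `X2`
#' / `X3`, then `X4`..`X7`, all thresholded at 0) to one of eight leaves,
#' each carrying a distinct base correlation `rho` in `[0.05, 0.9]`. The
#' covariance has AR(1) structure with heterogeneous variances:
#' `Sigma_jk = sigma_j * sigma_k * rho^|j-k|` with
#' `sigma_j = 1 + rho * j / q`, so both correlations and variances are
#' functions of the covariates and observations in the same leaf share an
#' identical covariance matrix (eight recoverable regimes).
#'
#' @param n sample size.
#' @param q number of responses (default 5).
#' @param seed RNG seed.
#' @return A `cov_sim` object (with a `leaf` attribute column recording
#'   leaf membership in `params`).
#' @export
dgp3 <- function(n, q = 5, seed = NULL) {
  if (q < 2L) stop("`q` must be >= 2", call. = FALSE)
  seed <- cf_default_seed(seed)
  with_preserved_rng(seed, {
    X <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("x", 1:7)))
    leaf <- dgp3_leaf(X)
    rho <- DGP3_LEAF_RHO[leaf]
    sigma <- array(0, c(q, q, n))
    ar1 <- abs(outer(seq_len(q), seq_len(q), "-"))
    for (r in unique(rho)) {
      sdv <- 1 + r * seq_len(q) / q
      S <- outer(sdv, sdv) * r^ar1
      for (i in which(rho == r)) sigma[, , i] <- S
    }
    Y <- draw_mvn(sigma)
    new_cov_sim(as.data.frame(X), Y, sigma, "dgp3",
                list(q = q, leaf = leaf, leaf_rho = DGP3_LEAF_RHO), seed)
  })
}

# fixed depth-3 routing: X1 at the root, X2/X3 at depth two, X4..X7 at
# depth three, all split at 0; returns leaf in 1..8
dgp3_leaf <- function(X) {
  left1 <- X[, 1] <= 0
  left2 <- ifelse(left1, X[, 2] <= 0, X[, 3] <= 0)
  v3 <- ifelse(left1, ifelse(left2, 4L, 5L), ifelse(left2, 6L, 7L))
  left3 <- X[cbind(seq_len(nrow(X)), v3)] <= 0
  1L + 4L * (!left1) + 2L * (!left2) + (!left3)
}

#' Compound-symmetry covariance generator with logit-driven correlation
#'
#' Covariates are independent standard normal; the equicorrelation of
#' each observation is `rho_i = plogis(beta_0 + sum_k beta_k X_ik)` with
#' `beta_0 = 0` and `beta = (2, 1, 0.5)` (so `X1` has the strongest and
#' `X3` the weakest effect; covariates beyond the third have no effect).
#' Variances are functions of the correlation, `sigma_j = 1 + rho * j / q`,
#' giving `Sigma_jj = sigma_j^2` and `Sigma_jk = sigma_j * sigma_k * rho_i`.
#' Since `rho_i` lies in (0, 1), every generated matrix is positive
#' definite.
#'
#' @param n sample size.
#' @param p number of covariates (default 3; at least 2).
#' @param q number of responses (default 5).
#' @param seed RNG seed.
#' @return A `cov_sim` object.
#' @export
dgp4 <- function(n, p = 3, q = 5, seed = NULL) {
  if (p < 2L) stop("`p` must be >= 2", call. = FALSE)
  if (q < 2L) stop("`q` must be >= 2", call. = FALSE)
  seed <- cf_default_seed(seed)
  with_preserved_rng(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
    beta <- c(DGP4_BETA, rep(0, max(0, p - 3)))[seq_len(p)]
    rho <- plogis(drop(X %*% beta))
    sigma <- array(0, c(q, q, n))
    for (i in seq_len(n)) {
      sdv <- 1 + rho[i] * seq_len(q) / q
      S <- outer(sdv, sdv) * rho[i]
      diag(S) <- sdv^2
      sigma[, , i] <- S
    }
    Y <- draw_mvn(sigma)
    new_cov_sim(as.data.frame(X), Y, sigma, "dgp4",
                list(p = p, q = q, beta = beta, rho = rho), seed)
  })
}

#' Append independent noise covariates to a simulated dataset
#'
#' Adds `k` standard-normal covariate columns independent of the
#' responses; the true covariances are unchanged. Used to study the cost
#' of irrelevant covariates for the tests and the importance measure.
#'
#' @param dataset a `cov_sim` object.
#' @param k number of noise covariates to append (`k = 0` returns the
#'   dataset unchanged).
#' @param seed RNG seed.
#' @return A `cov_sim` object with columns `noise1..noisek` appended.
#' @export
add_noise_covariates <- function(dataset, k, seed = NULL) {
  stopifnot(inherits(dataset, "cov_sim"))
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be >= 0", call. = FALSE)
  if (k == 0L) return(dataset)
  seed <- cf_default_seed(seed)
  n <- nrow(dataset$Y)
  noise <- with_preserved_rng(seed, matrix(rnorm(n * k), n, k))
  colnames(noise) <- paste0("noise", seq_len(k))
  dataset$X <- cbind(dataset$X, as.data.frame(noise))
  dataset$params$noise <- k
  dataset
}
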