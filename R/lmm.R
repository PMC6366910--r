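#' @include kinship.R
NULL

#' Profiled log likelihood of the one-random-effect mixed model
#'
#' For the model `y = X beta + g + e` with `g ~ N(0, s2g K)` and
#' `e ~ N(0, s2e I)`, after rotating by the eigenvectors of K the covariance
#' is diagonal with weights `h2 * lambda_i + (1 - h2)`.  Given `h2`, beta and
#' the total variance profile out in closed form; this returns the profiled
#' restricted (REML) or full (ML) Gaussian log likelihood.
#'
#' @param yRot rotated phenotype vector (`t(U) %*% y`)
#' @param xRot rotated fixed-effect design matrix (`t(U) %*% X`)
#' @param eigenvalues eigenvalues of K, in the rotation's order
#' @param h2 candidate heritability in `[0, 1)`
#' @param reml use the restricted likelihood? (default `TRUE`)
#' @return log likelihood (a single number, deterministic)
#' @export
lmmProfileLoglik <- function(yRot, xRot, eigenvalues, h2, reml = TRUE) {
  if (h2 < 0 || h2 >= 1) .stopf("h2 must be in [0, 1)")
  n <- length(yRot)
  p <- ncol(xRot)
  v <- h2 * eigenvalues + (1 - h2)
  w <- 1 / v
  sw <- sqrt(w)
  Xw <- xRot * sw
  yw <- yRot * sw
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  if (reml) {
    XtX <- crossprod(Xw)
    XtX0 <- crossprod(xRot)
    sigma2 <- rss / (n - p)
    as.numeric(-0.5 * ((n - p) * log(2 * pi * sigma2) + sum(log(v)) +
                         determinant(XtX, logarithm = TRUE)$modulus -
                         determinant(XtX0, logarithm = TRUE)$modulus + (n - p)))
  } else {
    sigma2 <- rss / n
    -0.5 * (n * log(2 * pi * sigma2) + sum(log(v)) + n)
  }
}

# coarse grid + local refinement of the h2 profile
.maximizeH2 <- function(yRot, xRot, eigenvalues, reml = TRUE, tol = 1e-8) {
  hi <- 1 - 1e-8
  f <- function(h2) lmmProfileLoglik(yRot, xRot, eigenvalues, h2, reml)
  grid <- seq(0, 0.99, by = 0.01)
  vals <- vapply(grid, f, 0)
  k <- which.max(vals)
  lo <- grid[max(k - 1L, 1L)]
  up <- min(grid[min(k + 1L, length(grid))] + 1e-8, hi)
  opt <- stats::optimize(f, c(lo, up), maximum = TRUE, tol = tol)
  # allow the boundary h2 = 0 to win outright
  if (f(0) >= opt$objective) list(h2 = 0, loglik = f(0))
  else list(h2 = opt$maximum, loglik = opt$objective)
}

#' Fit the null linear mixed model
#'
#' Estimates the heritability `h2 = s2g / (s2g + s2e)` of
#' `y = X beta + g + e`, `g ~ N(0, s2g K)`, by 1-d optimization of the
#' profiled (by default restricted) log likelihood after rotating by the
#' eigendecomposition of K.  The returned rotation and weights are reused by
#' the mixed-model genome scan, with `h2` held fixed across positions.
#'
#' @param y numeric phenotype vector (no missing values; the caller drops)
#' @param X fixed-effect design matrix including the intercept; defaults to
#'   an intercept-only model
#' @param K kinship matrix
#' @param reml use REML (default) or ML
#' @return list with `h2`, `loglik`, `sigma2` (total variance), `beta`,
#'   `eigenvalues`, `rotation` (t(U)), and `weights` (1 / (h2 lambda + 1-h2))
#' @export
fitLmmNull <- function(y, X = NULL, K, reml = TRUE) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  if (anyNA(y) || anyNA(X)) .stopf("missing values must be dropped before fitting")
  if (nrow(K) != n) .stopf("kinship dimension does not match phenotype length")
  if (qr(X)$rank < ncol(X)) .stopf("singular fixed-effect design")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-6) .stopf("kinship matrix is not positive semidefinite")
  Ut <- t(e$vectors)
  yRot <- drop(Ut %*% y)
  xRot <- Ut %*% X
  best <- .maximizeH2(yRot, xRot, e$values, reml)
  v <- best$h2 * e$values + (1 - best$h2)
  sw <- sqrt(1 / v)
  fit <- stats::lm.fit(xRot * sw, yRot * sw)
  rss <- sum(fit$residuals^2)
  list(h2 = best$h2, loglik = best$loglik,
       sigma2 = rss / if (reml) (n - ncol(X)) else n,
       beta = fit$coefficients,
       eigenvalues = e$values, rotation = Ut, weights = 1 / v)
}
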