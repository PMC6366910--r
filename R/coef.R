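#' @include scan.R
NULL

# minimum-norm least squares (pseudo-inverse rule for collinear columns)
.pinvFit <- function(X, y, se = FALSE, tol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > tol * sv$d[1L]
  dinv <- ifelse(pos, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * (t(sv$u) %*% y))
  out <- list(coef = drop(beta))
  if (se) {
    res <- y - X %*% beta
    df <- length(y) - sum(pos)
    s2 <- sum(res^2) / max(df, 1L)
    XtXinv_diag <- rowSums((sv$v * rep(dinv, each = nrow(sv$v)))^2)
    out$se <- sqrt(s2 * XtXinv_diag)
  }
  out
}

# restrict a GenotypeProb to one chromosome and return pieces for fitting
.oneChr <- function(probs, chr) {
  if (is.null(chr)) chr <- names(probs@probs)[1L]
  if (!chr %in% names(probs@probs)) .stopf("chromosome '%s' not in probs", chr)
  list(chr = chr, G = probs@probs[[chr]], pos = probs@map[[chr]])
}

# shared preparation: alignment, complete cases, optional LMM rotation
.coefSetup <- function(probs, pheno, covar, kinship, chr) {
  pheno <- .alignPheno(probs, pheno)
  if (ncol(pheno) > 1L) .stopf("effect estimation takes a single phenotype")
  covar <- .alignCovar(probs, covar)
  oc <- .oneChr(probs, chr)
  y <- pheno[, 1L]
  keep <- which(stats::complete.cases(y, covar))
  y <- y[keep]
  C <- if (is.null(covar)) NULL else covar[keep, , drop = FALSE]
  G <- oc$G[keep, , , drop = FALSE]
  n <- length(keep)
  if (!is.null(kinship)) {
    K <- if (is.list(kinship)) kinship[[oc$chr]] else kinship
    K <- K[keep, keep]
    nf <- fitLmmNull(y, cbind(rep(1, n), C), K)
    tr <- sqrt(nf$weights) * nf$rotation
    y <- drop(tr %*% y)
    if (!is.null(C)) C <- tr %*% C
    ones <- tr %*% rep(1, n)
    d <- dim(G)
    G <- array(tr %*% matrix(G, n, d[2L] * d[3L]), d, dimnames = dimnames(G))
  } else {
    ones <- matrix(1, n, 1L)
  }
  list(chr = oc$chr, pos = oc$pos, G = G, y = y, C = C, ones = ones, n = n)
}

#' Per-position state/founder effect estimates
#'
#' Least-squares estimates of the state (or founder-dosage) effects at every
#' position of one chromosome, i.e. the fitted per-state phenotype means,
#' plus any covariate effects.  Because the probability columns sum to 1 the
#' intercept is absorbed into the state effects (the parameterization in
#' which one effect is plotted per founder).  Collinear columns are resolved
#' by the minimum-norm pseudo-inverse rule.  With `kinship`, estimation is
#' performed in the rotated, variance-weighted space of the chromosome's
#' null mixed model.
#'
#' @inheritParams scanQtl
#' @param chr chromosome to use (default: the first in `probs`)
#' @return an [EffectEstimates-class] with mode `"ols"`
#' @export
scanCoef <- function(probs, pheno, covar = NULL, kinship = NULL, chr = NULL) {
  st <- .coefSetup(probs, pheno, covar, kinship, chr)
  S <- dim(st$G)[2L]
  q <- if (is.null(st$C)) 0L else ncol(st$C)
  P <- dim(st$G)[3L]
  cn <- c(dimnames(st$G)[[2L]], colnames(st$C))
  co <- se <- matrix(NA_real_, P, S + q, dimnames = list(names(st$pos), cn))
  for (t in seq_len(P)) {
    X <- matrix(st$G[, , t], st$n, S)
    if (q) X <- cbind(X, st$C)
    f <- .pinvFit(X, st$y, se = TRUE)
    co[t, ] <- f$coef
    se[t, ] <- f$se
  }
  new("EffectEstimates", coef = co, se = se, pos = unname(st$pos),
      chr = st$chr, mode = "ols")
}

#' BLUPs of founder allele effects
#'
#' Treats the state/founder effects at each position as i.i.d. random
#' effects `u ~ N(0, s2u I)` on top of fixed intercept and covariates,
#' estimates the variance ratio by REML position by position, and returns
#' the posterior-mean effects -- estimates shrunk toward zero relative to
#' [scanCoef()].  With zero estimated effect variance the BLUPs are exactly
#' zero; as the variance ratio grows they approach the fixed estimates.
#'
#' @inheritParams scanCoef
#' @param varRatio optional fixed variance ratio `s2u / s2e`; when supplied,
#'   REML estimation is skipped and the BLUPs are evaluated at this ratio
#' @return an [EffectEstimates-class] with mode `"blup"`; columns are the
#'   founder/state BLUPs followed by the intercept and covariate effects
#' @export
scanBlup <- function(probs, pheno, covar = NULL, kinship = NULL, chr = NULL,
                     varRatio = NULL) {
  st <- .coefSetup(probs, pheno, covar, kinship, chr)
  S <- dim(st$G)[2L]
  q <- if (is.null(st$C)) 0L else ncol(st$C)
  P <- dim(st$G)[3L]
  X <- cbind(st$ones, st$C)
  colnames(X) <- c("intercept", colnames(st$C))
  p <- ncol(X)
  n <- st$n
  cn <- c(dimnames(st$G)[[2L]], colnames(X))
  co <- matrix(NA_real_, P, S + p, dimnames = list(names(st$pos), cn))
  for (t in seq_len(P)) {
    Z <- matrix(st$G[, , t], n, S)
    sv <- svd(Z, nu = min(n, S), nv = min(n, S))
    d2 <- sv$d^2
    Uy <- drop(crossprod(sv$u, st$y))
    UX <- crossprod(sv$u, X)
    # profiled REML criterion in the variance ratio gamma
    crit <- function(gamma) {
      cc <- gamma * d2 / (1 + gamma * d2)
      SIy <- st$y - sv$u %*% (cc * Uy)
      SIX <- X - sv$u %*% (cc * UX)
      XtSiX <- crossprod(X, SIX)
      XtSiy <- drop(crossprod(X, SIy))
      beta <- solve(XtSiX, XtSiy)
      rq <- sum(st$y * SIy) - sum(beta * XtSiy)
      ld <- determinant(XtSiX, logarithm = TRUE)$modulus
      -0.5 * (sum(log1p(gamma * d2)) + ld + (n - p) * log(max(rq, 1e-300)))
    }
    gamma <- if (!is.null(varRatio)) varRatio else {
      op <- stats::optimize(function(u) crit(u / (1 - u)),
                            c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
      if (crit(0) >= op$objective) 0 else op$maximum / (1 - op$maximum)
    }
    cc <- gamma * d2 / (1 + gamma * d2)
    SIy <- st$y - sv$u %*% (cc * Uy)
    SIX <- X - sv$u %*% (cc * UX)
    beta <- solve(crossprod(X, SIX), drop(crossprod(X, SIy)))
    r <- st$y - X %*% beta
    Ur <- drop(crossprod(sv$u, r))
    u <- gamma * drop(sv$v %*% (sv$d * (1 - cc) * Ur))
    co[t, ] <- c(u, beta)
  }
  new("EffectEstimates", coef = co, se = matrix(0, 0L, 0L),
      pos = unname(st$pos), chr = st$chr, mode = "blup")
}
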