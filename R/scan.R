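#' @include lmm.R
NULL

# coerce phenotype input to a named numeric matrix aligned with the probs
.alignPheno <- function(probs, pheno) {
  ids <- dimnames(probs@probs[[1L]])[[1L]]
  if (is.null(dim(pheno))) {
    pheno <- matrix(pheno, ncol = 1L,
                    dimnames = list(names(pheno), "pheno"))
  }
  pheno <- as.matrix(pheno)
  if (!is.null(rownames(pheno)) && !is.null(ids) &&
      any(ids %in% rownames(pheno))) {
    # align by ID; individuals without phenotype rows get NA (dropped pairwise)
    out <- matrix(NA_real_, length(ids), ncol(pheno),
                  dimnames = list(ids, colnames(pheno)))
    common <- intersect(ids, rownames(pheno))
    out[common, ] <- pheno[common, , drop = FALSE]
    pheno <- out
  } else if (nrow(pheno) != length(ids)) {
    .stopf("phenotypes do not align with the probability arrays")
  }
  if (is.null(colnames(pheno)))
    colnames(pheno) <- paste0("pheno", seq_len(ncol(pheno)))
  pheno
}

.alignCovar <- function(probs, covar) {
  if (is.null(covar)) return(NULL)
  ids <- dimnames(probs@probs[[1L]])[[1L]]
  covar <- as.matrix(covar)
  if (!is.null(rownames(covar)) && all(ids %in% rownames(covar)))
    covar <- covar[ids, , drop = FALSE]
  else if (nrow(covar) != length(ids))
    .stopf("covariates do not align with the probability arrays")
  storage.mode(covar) <- "double"
  covar
}

# sex indicator for the X-scan null ("special covariates" convention)
.sexCovar <- function(probs) {
  sx <- probs@sex
  if (!length(sx) || length(unique(sx)) < 2L) return(NULL)
  matrix(as.numeric(sx == "m"), ncol = 1L, dimnames = list(NULL, "sexM"))
}

# residual sum of squares of y on X (rank-deficiency tolerated)
.rss <- function(X, y) {
  sum(stats::lm.fit(X, y)$residuals^2)
}

# per-position RSS along one chromosome; G n x S x P, C may be NULL
.rssPositions <- function(G, C, y) {
  P <- dim(G)[3L]
  S <- dim(G)[2L]
  n <- dim(G)[1L]
  out <- numeric(P)
  for (t in seq_len(P)) {
    X <- matrix(G[, , t], n, S)
    if (!is.null(C)) X <- cbind(X, C)
    out[t] <- .rss(X, y)
  }
  out
}

# one phenotype, HK or LMM, optionally with permuted probability rows
# (pm: such that the scan behaves as if prob rows were reordered by pm)
.scanOne <- function(probs, y, covar, kinship, keep, pm = NULL,
                     maxOnly = FALSE) {
  chrs <- names(probs@probs)
  n <- length(keep)
  yk <- y[keep]
  lods <- vector("list", length(chrs))
  names(lods) <- chrs
  for (chr in chrs) {
    isX <- .isXchr(chr)
    C <- covar
    if (isX) {
      sx <- .sexCovar(probs)
      if (!is.null(sx)) C <- cbind(covar, sx[keep, , drop = FALSE])
    }
    G <- probs@probs[[chr]]
    rows <- if (is.null(pm)) keep else pm[keep]
    G <- G[rows, , , drop = FALSE]
    ones <- matrix(1, n, 1L)
    if (is.null(kinship)) {
      rss0 <- .rss(cbind(ones, C), yk)
      rss1 <- .rssPositions(G, C, yk)
    } else {
      K <- if (is.list(kinship)) kinship[[chr]] else kinship
      K <- K[keep, keep]
      X0 <- cbind(ones, C)
      nf <- fitLmmNull(yk, X0, K)
      tr <- sqrt(nf$weights) * nf$rotation   # scale rotated rows, n x n
      yT <- drop(tr %*% yk)
      X0T <- tr %*% X0
      CT <- if (is.null(C)) NULL else tr %*% C
      d <- dim(G)
      GT <- array(tr %*% matrix(G, n, d[2L] * d[3L]), d)
      rss0 <- .rss(X0T, yT)
      rss1 <- .rssPositions(GT, CT, yT)
    }
    lod <- n / 2 * (log10(rss0) - log10(rss1))
    lod[lod < 0 & lod > -1e-8] <- 0
    lods[[chr]] <- lod
  }
  if (!maxOnly) return(lods)
  vapply(lods, function(v) if (length(v)) max(v) else -Inf, 0)
}

#' Genome scan by Haley-Knott regression or a linear mixed model
#'
#' At every position, the phenotype is regressed on the genotype (or founder
#' dosage) probability columns plus covariates, and
#' `LOD = (n/2) log10(RSS0 / RSS1)` compares against the covariates-only
#' null.  Since the probability columns sum to 1, the intercept is dropped
#' from the alternative model (effects are per-state means).  Supplying
#' `kinship` (one overall matrix, or a list of leave-one-chromosome-out
#' matrices from [calcKinship()]) switches to the mixed model: the null
#' heritability is estimated by REML per chromosome, and the Haley-Knott
#' regression is carried out in the rotated, variance-weighted space.  On the
#' X chromosome, sex is added to both null and alternative models whenever
#' both sexes are present.  Missing phenotype values are dropped pairwise per
#' phenotype column.
#'
#' @param probs a [GenotypeProb-class] (raw states for the full model,
#'   allele dosages for the additive model)
#' @param pheno numeric vector or individuals x traits matrix
#' @param covar optional covariate matrix (no intercept column)
#' @param kinship optional kinship matrix or LOCO list
#' @return a [ScanResult-class]
#' @export
scanQtl <- function(probs, pheno, covar = NULL, kinship = NULL) {
  pheno <- .alignPheno(probs, pheno)
  covar <- .alignCovar(probs, covar)
  chrs <- names(probs@probs)
  npos <- vapply(chrs, function(chr) dim(probs@probs[[chr]])[3L], 0L)
  chrvec <- rep(chrs, npos)
  posvec <- unlist(lapply(chrs, function(chr) probs@map[[chr]]), use.names = FALSE)
  posnames <- unlist(lapply(chrs, function(chr) names(probs@map[[chr]])))
  lod <- matrix(NA_real_, sum(npos), ncol(pheno),
                dimnames = list(posnames, colnames(pheno)))
  ns <- integer(ncol(pheno))
  for (j in seq_len(ncol(pheno))) {
    y <- pheno[, j]
    keep <- which(stats::complete.cases(y, covar))
    if (length(keep) < 3L) .stopf("phenotype '%s': too few complete cases", colnames(pheno)[j])
    if (stats::var(y[keep]) == 0)
      .stopf("phenotype '%s' is constant", colnames(pheno)[j])
    Ck <- if (is.null(covar)) NULL else covar[keep, , drop = FALSE]
    lods <- .scanOne(probs, y, Ck, kinship, keep)
    lod[, j] <- unlist(lods, use.names = FALSE)
    ns[j] <- length(keep)
  }
  autoChr <- chrs[!vapply(chrs, .isXchr, TRUE)]
  Sauto <- if (length(autoChr)) dim(probs@probs[[autoChr[1L]]])[2L]
           else dim(probs@probs[[1L]])[2L]
  new("ScanResult", lod = lod, chr = chrvec, pos = posvec,
      model = if (probs@alleleProb) "additive" else "full",
      df = as.integer(Sauto - 1L), n = ns,
      method = if (is.null(kinship)) "hk" else "lmm")
}
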