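#' @include scan.R
NULL

#' Permutation test for genome-wide significance
#'
#' Each replicate applies one shared random permutation to the rows of the
#' genome-wide haplotype probability arrays, leaving the (phenotype,
#' covariate, kinship-row) tuples intact, rescans, and records the
#' genome-wide maximum LOD -- separately for autosomes and the X chromosome
#' when `xSeparate` is set.  Internally the equivalent inverse permutation is
#' applied to the phenotype side, which is cheaper and bit-identical.
#'
#' @inheritParams scanQtl
#' @param nPerm number of permutation replicates
#' @param xSeparate record X-chromosome maxima separately (the
#'   autosome/X-specific threshold technique)?
#' @param seed optional integer seed for reproducible permutations
#' @return a [ScanPerm-class] object; see [permThreshold()]
#' @export
scanPerm <- function(probs, pheno, covar = NULL, kinship = NULL,
                     nPerm = 1000, xSeparate = TRUE, seed = NULL) {
  if (nPerm < 1) .stopf("nPerm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pheno <- .alignPheno(probs, pheno)
  covar <- .alignCovar(probs, covar)
  chrs <- names(probs@probs)
  isX <- vapply(chrs, .isXchr, TRUE)
  useX <- xSeparate && any(isX)
  n <- nrow(pheno)
  maxA <- matrix(NA_real_, nPerm, ncol(pheno),
                 dimnames = list(NULL, colnames(pheno)))
  maxX <- if (useX) maxA else matrix(0, 0L, ncol(pheno))
  keeps <- lapply(seq_len(ncol(pheno)), function(j)
    which(stats::complete.cases(pheno[, j], covar)))
  perms <- replicate(nPerm, sample.int(n), simplify = FALSE)
  for (r in seq_len(nPerm)) {
    pm <- perms[[r]]
    for (j in seq_len(ncol(pheno))) {
      keep <- keeps[[j]]
      Ck <- if (is.null(covar)) NULL else covar[keep, , drop = FALSE]
      mx <- .scanOne(probs, pheno[, j], Ck, kinship, keep, pm = pm,
                     maxOnly = TRUE)
      maxA[r, j] <- if (useX) max(mx[!isX]) else max(mx)
      if (useX) maxX[r, j] <- max(mx[isX])
    }
  }
  lenA <- sum(vapply(chrs[!isX], function(chr) diff(range(probs@map[[chr]])), 0))
  lenX <- if (useX) sum(vapply(chrs[isX], function(chr) diff(range(probs@map[[chr]])), 0)) else 0
  new("ScanPerm", maxLod = maxA, maxLodX = maxX,
      lengthA = lenA, lengthX = lenX)
}

#' Significance thresholds from permutation maxima
#'
#' Empirical quantiles of the null genome-wide maxima.  When X maxima were
#' recorded separately, the autosome and X thresholds use the
#' length-apportioned significance levels `1 - (1-alpha)^(L_A/L_G)` and
#' `1 - (1-alpha)^(L_X/L_G)` (map lengths in cM), which recover `alpha`
#' itself when either part vanishes.
#'
#' @param perm a [ScanPerm-class] object
#' @param alpha significance level(s); thresholds are nondecreasing as
#'   `alpha` decreases
#' @return list with `autosome` (and `X`, when present): alphas x phenotypes
#'   threshold matrices
#' @export
permThreshold <- function(perm, alpha = 0.05) {
  nPerm <- nrow(perm@maxLod)
  hasX <- nrow(perm@maxLodX) > 0L
  LG <- perm@lengthA + perm@lengthX
  alphaA <- if (hasX && LG > 0) 1 - (1 - alpha)^(perm@lengthA / LG) else alpha
  alphaX <- if (hasX && LG > 0) 1 - (1 - alpha)^(perm@lengthX / LG) else alpha
  if (any(nPerm * pmin(alphaA, if (hasX) alphaX else alphaA) < 1))
    .warnf("requested alpha below the resolution of %d permutations", nPerm)
  qmat <- function(m, a) {
    out <- t(apply(m, 2L, stats::quantile, probs = 1 - a, names = FALSE))
    out <- matrix(out, length(a), ncol(m), byrow = TRUE,
                  dimnames = list(paste0("alpha", a), colnames(m)))
    out
  }
  out <- list(autosome = qmat(perm@maxLod, alphaA))
  if (hasX) out$X <- qmat(perm@maxLodX, alphaX)
  out
}

#' Find peaks in a genome scan
#'
#' Local maxima with LOD above a threshold, one per chromosome unless
#' separated from a higher peak by a LOD fall of more than `peakdrop`; each
#' peak gets a LOD-drop support interval.
#'
#' @param scan a [ScanResult-class]
#' @param threshold minimum LOD; either a single number or a named vector
#'   with elements `autosome` and `X`
#' @param peakdrop LOD fall required between two peaks on one chromosome
#'   (default `Inf`: a single peak per chromosome)
#' @param drop LOD-drop for the support interval (default 1.5)
#' @return data.frame with columns pheno, chr, pos, lod, ci_lo, ci_hi
#' @export
findPeaks <- function(scan, threshold, peakdrop = Inf, drop = 1.5) {
  res <- list()
  for (j in seq_len(ncol(scan@lod))) {
    for (chr in unique(scan@chr)) {
      idx <- which(scan@chr == chr)
      v <- scan@lod[idx, j]
      pos <- scan@pos[idx]
      thr <- if (length(threshold) > 1L)
        threshold[[if (.isXchr(chr)) "X" else "autosome"]] else threshold
      cand <- which(v >= thr)
      while (length(cand)) {
        m <- cand[which.max(v[cand])]
        lo <- m; while (lo > 1L && v[lo - 1L] > v[m] - peakdrop) lo <- lo - 1L
        hi <- m; while (hi < length(v) && v[hi + 1L] > v[m] - peakdrop) hi <- hi + 1L
        ci <- range(which(v >= v[m] - drop & seq_along(v) >= lo & seq_along(v) <= hi))
        res[[length(res) + 1L]] <- data.frame(
          pheno = colnames(scan@lod)[j], chr = chr, pos = pos[m], lod = v[m],
          ci_lo = pos[ci[1L]], ci_hi = pos[ci[2L]])
        cand <- setdiff(cand, lo:hi)
      }
    }
  }
  if (!length(res))
    return(data.frame(pheno = character(), chr = character(), pos = numeric(),
                      lod = numeric(), ci_lo = numeric(), ci_hi = numeric()))
  out <- do.call(rbind, res)
  out[order(out$pheno, out$chr, out$pos), , drop = FALSE]
}
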