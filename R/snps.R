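#' @include scan.R
NULL

#' Encode founder strain-distribution patterns
#'
#' Packs per-founder allele indicators into an integer SDP mask: bit `i`
#' (1-based founder `i`, value `2^(i-1)`) is set when founder `i` carries the
#' non-reference allele.  Monomorphic masks (0 or `2^n - 1`) are permitted
#' here but excluded from scans.
#'
#' @param alleles founders x SNPs matrix of 0/1 indicators (1 = alt)
#' @return integer vector of SDP masks
#' @export
sdpFromAlleles <- function(alleles) {
  alleles <- as.matrix(alleles)
  drop(2^(seq_len(nrow(alleles)) - 1L) %*% alleles)
}

.sdpBits <- function(sdp, nFounders) {
  vapply(seq_len(nFounders), function(i) bitwAnd(sdp, 2^(i - 1L)) > 0,
         logical(length(sdp))) * 1
}

#' Index SNPs into probability-position intervals and SDP classes
#'
#' Each SNP is assigned to the interval between its flanking probability
#' positions; SNPs in the same interval with the same strain-distribution
#' pattern have identical imputed genotype probabilities and are grouped
#' into one equivalence class with a single representative that is actually
#' scanned.  SNPs outside the map extent of their chromosome are dropped
#' (with a count in `attr(, "nDropped")`).
#'
#' @param probs a [GenotypeProb-class] whose positions define the intervals
#' @param snpinfo data.frame with columns `snp`, `chr`, `pos` (cM, on the
#'   same map as `probs`), and `sdp`
#' @return `snpinfo` with added columns `interval`, `classIndex` and
#'   `representative`, ordered by chromosome and position
#' @export
indexSnps <- function(probs, snpinfo) {
  need <- c("snp", "chr", "pos", "sdp")
  if (!all(need %in% names(snpinfo)))
    .stopf("snpinfo needs columns: %s", paste(need, collapse = ", "))
  nDropped <- 0L
  out <- list()
  for (chr in unique(snpinfo$chr)) {
    si <- snpinfo[snpinfo$chr == chr, , drop = FALSE]
    if (!chr %in% names(probs@map)) { nDropped <- nDropped + nrow(si); next }
    pos <- probs@map[[chr]]
    inside <- si$pos >= min(pos) & si$pos <= max(pos)
    nDropped <- nDropped + sum(!inside)
    si <- si[inside, , drop = FALSE]
    if (!nrow(si)) next
    si <- si[order(si$pos), , drop = FALSE]
    si$interval <- pmin(findInterval(si$pos, pos), length(pos) - 1L)
    key <- paste(si$interval, si$sdp)
    si$classIndex <- match(key, unique(key))
    si$representative <- !duplicated(key)
    out[[chr]] <- si
  }
  if (!length(out)) .stopf("no SNPs fall inside the probability map")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "nDropped") <- nDropped
  res
}

# linear interpolation of probability slices to a position
.interpSlice <- function(G, pos, p) {
  k <- pmin(findInterval(p, pos), length(pos) - 1L)
  if (length(pos) == 1L) return(matrix(G[, , 1L], dim(G)[1L], dim(G)[2L]))
  tfrac <- (p - pos[k]) / (pos[k + 1L] - pos[k])
  (1 - tfrac) * matrix(G[, , k], dim(G)[1L], dim(G)[2L]) +
    tfrac * matrix(G[, , k + 1L], dim(G)[1L], dim(G)[2L])
}

#' Impute SNP genotype probabilities from founder haplotype probabilities
#'
#' For each indexed SNP class, interpolates the haplotype probabilities
#' linearly (in cM) to the representative SNP's position and collapses
#' founders by the SNP's strain-distribution pattern.  From allele-dosage
#' probabilities the result has two states (`ref`, `alt`: the probability
#' that a random haplotype carries each allele); from raw diplotype
#' probabilities it has the three genotype states (`rr`, `ra`, `aa`).
#'
#' @param probs a [GenotypeProb-class] (single or multiple chromosomes)
#' @param snpinfo indexed SNP table from [indexSnps()]
#' @return list per chromosome of individuals x states x classes arrays,
#'   with the class-representative SNP ids as the third dimnames
#' @export
snpProbs <- function(probs, snpinfo) {
  design <- crossDesign(probs@design)
  nF <- design@nFounders
  out <- list()
  for (chr in unique(snpinfo$chr)) {
    si <- snpinfo[snpinfo$chr == chr & snpinfo$representative, , drop = FALSE]
    G <- probs@probs[[chr]]
    pos <- probs@map[[chr]]
    n <- dim(G)[1L]
    if (probs@alleleProb) {
      arr <- array(NA_real_, c(n, 2L, nrow(si)),
                   dimnames = list(dimnames(G)[[1L]], c("ref", "alt"), si$snp))
      for (k in seq_len(nrow(si))) {
        A <- .interpSlice(G, pos, si$pos[k])
        bits <- .sdpBits(si$sdp[k], nF)
        alt <- drop(A %*% bits)
        arr[, , k] <- cbind(1 - alt, alt)
      }
    } else {
      chromType <- if (.isXchr(chr)) "X" else "autosome"
      sf <- .stateFounderList(design, chromType,
                              if (chromType == "X") "both" else "female")
      arr <- array(NA_real_, c(n, 3L, nrow(si)),
                   dimnames = list(dimnames(G)[[1L]], c("rr", "ra", "aa"), si$snp))
      for (k in seq_len(nrow(si))) {
        P <- .interpSlice(G, pos, si$pos[k])
        bits <- .sdpBits(si$sdp[k], nF)
        nalt <- vapply(sf, function(f) sum(bits[f]), 0)
        ploidy <- vapply(sf, length, 0L)
        cat3 <- nalt + (2L - ploidy) * nalt   # hemizygous: dose 0/1 -> 0/2
        M <- vapply(0:2, function(g) as.numeric(cat3 == g), numeric(length(sf)))
        arr[, , k] <- P %*% M
      }
    }
    out[[chr]] <- arr
  }
  out
}

#' SNP association scan
#'
#' Haley-Knott (or mixed-model) regression on imputed SNP genotype
#' probabilities, one test per SNP equivalence class, expanded back to the
#' member SNPs by [topSnps()].  The additive model regresses on the two
#' haploid allele-probability columns (1 df); the general model on the three
#' genotype-category columns (2 df).
#'
#' @inheritParams scanQtl
#' @param snpinfo indexed SNP table from [indexSnps()]
#' @param model "additive" (1 df) or "general" (2 df)
#' @return a [ScanResult-class] with one row per SNP class (rownames are
#'   the representative SNP ids)
#' @export
scanSnps <- function(probs, pheno, snpinfo, covar = NULL, kinship = NULL,
                     model = c("additive", "general")) {
  model <- match.arg(model)
  mono <- snpinfo$sdp %in% c(0, 2^crossDesign(probs@design)@nFounders - 1)
  if (any(mono)) {
    .warnf("dropping %d monomorphic SNPs", sum(mono))
    snpinfo <- snpinfo[!mono, , drop = FALSE]
  }
  use <- if (model == "additive") {
    if (probs@alleleProb) probs else genoprobToAlleleprob(probs)
  } else {
    if (probs@alleleProb)
      .stopf("the general model needs raw diplotype probabilities")
    probs
  }
  sp <- snpProbs(use, snpinfo)
  # repackage the class arrays as a GenotypeProb so the scan core applies
  fakeMap <- lapply(names(sp), function(chr) {
    si <- snpinfo[snpinfo$chr == chr & snpinfo$representative, , drop = FALSE]
    stats::setNames(si$pos, si$snp)
  })
  names(fakeMap) <- names(sp)
  g2 <- new("GenotypeProb", probs = sp, map = fakeMap, design = use@design,
            alleleProb = TRUE, sex = use@sex, errorProb = use@errorProb,
            mapFunction = use@mapFunction)
  res <- scanQtl(g2, pheno, covar = covar, kinship = kinship)
  res@model <- "snp"
  res@df <- as.integer(dim(sp[[1L]])[2L] - 1L)
  res
}

#' Top SNPs within a LOD drop of the regional maximum
#'
#' Expands a SNP-class scan back to all member SNPs and returns those whose
#' class LOD is within `drop` of the maximum (default 1.5).
#'
#' @param snpScan result of [scanSnps()]
#' @param snpinfo the indexed SNP table used for the scan
#' @param drop LOD units below the maximum to retain (default 1.5)
#' @return data.frame of member SNPs with their class LOD, sorted by LOD
#' @export
topSnps <- function(snpScan, snpinfo, drop = 1.5) {
  reps <- rownames(snpScan@lod)
  lodByClass <- stats::setNames(snpScan@lod[, 1L], reps)
  key <- paste(snpinfo$chr, snpinfo$classIndex)
  repkey <- key[snpinfo$representative]
  repsnp <- snpinfo$snp[snpinfo$representative]
  lodAll <- lodByClass[repsnp[match(key, repkey)]]
  out <- cbind(snpinfo[, c("snp", "chr", "pos", "sdp")], lod = unname(lodAll))
  out <- out[!is.na(out$lod) & out$lod >= max(out$lod, na.rm = TRUE) - drop, , drop = FALSE]
  out[order(-out$lod), , drop = FALSE]
}
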