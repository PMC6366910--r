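#' @include hmm.R
NULL

#' Genotyping-error LOD scores
#'
#' For every observed marker genotype, the log10 likelihood ratio comparing
#' "this call is a typing error" to "this call is correct", given the state
#' posterior computed from all *other* markers (leave-one-out emission).
#' Under the package's error model an erroneous call is one of the two other
#' full genotype codes, each with probability 1/2.  Missing observations
#' score 0; large positive scores flag likely errors, negative scores mark
#' calls supported by their flanking markers.
#'
#' @inheritParams calcGenoprob
#' @return list (per chromosome) of individuals x markers score matrices
#' @export
calcErrorLod <- function(cross, errorProb = 1e-4,
                         mapFunction = c("haldane", "kosambi")) {
  mapFunction <- match.arg(mapFunction)
  design <- cross@design
  n <- length(cross@ids)
  out <- vector("list", length(cross@map))
  names(out) <- names(cross@map)
  tiny <- .Machine$double.xmin
  for (chr in names(cross@map)) {
    chromType <- if (.isXchr(chr)) "X" else "autosome"
    if (chromType == "X" && !design@handlesX)
      .stopf("design '%s' has no native X-chromosome support", design@code)
    pos <- cross@map[[chr]]
    P <- length(pos)
    geno <- cross@geno[[chr]]
    lod <- matrix(0, n, P, dimnames = list(cross@ids, names(pos)))
    for (rows in .hmmGroups(cross, chromType)) {
      meta <- .groupMeta(cross, rows, chromType)
      pieces <- .hmmPieces(cross, chr, pos, errorProb, mapFunction, rows,
                           chromType, meta$sex, meta$generation)
      fb <- .fwdbwd(length(rows), pieces$init, pieces$trans, pieces$emis,
                    keepFB = TRUE)
      sf <- .stateFounderList(design, chromType, meta$sex)
      fg <- cross@founderGeno[[chr]]
      for (t in seq_len(P)) {
        mar <- names(pos)[t]
        codes <- geno[rows, mar]
        obs <- codes > 0L
        if (!any(obs)) next
        # posterior over states given all OTHER markers
        pre <- if (t == 1L) matrix(pieces$init, length(rows), pieces$S, byrow = TRUE)
               else matrix(fb$fwd[, , t - 1L], length(rows), pieces$S) %*% pieces$trans[[t - 1L]]
        gt <- pre * matrix(fb$bwd[, , t], length(rows), pieces$S)
        gt <- gt / rowSums(gt)
        alleles <- if (is.null(fg)) c(1L, 2L) else fg[, mar]
        G <- .stateGenoMatrix(sf, alleles)            # S x 3
        pCorrect <- cbind(G, G[, 2L] + G[, 3L], G[, 1L] + G[, 2L])
        # error channel: true genotype replaced by one of the 2 other codes
        pErr3 <- (1 - G) / 2                          # towards AA, AB, BB
        pError <- cbind(pErr3, pErr3[, 2L] + pErr3[, 3L], pErr3[, 1L] + pErr3[, 2L])
        num <- (gt %*% pError)[cbind(seq_along(codes), pmax(codes, 1L))]
        den <- (gt %*% pCorrect)[cbind(seq_along(codes), pmax(codes, 1L))]
        sc <- log10(pmax(num, tiny)) - log10(pmax(den, tiny))
        sc[!obs] <- 0
        lod[rows, t] <- sc
      }
    }
    out[[chr]] <- lod
  }
  out
}

#' Count crossovers along reconstructed mosaics
#'
#' Counts adjacent-position state changes on a Viterbi (or maximal-marginal)
#' path, weighting each change by the minimum number of strand exchanges it
#' implies: diplotype changes sharing one founder count 1, founder-homozygote
#' to founder-homozygote switches count 2; for inbred-line and backcross
#' designs each state change counts 1 (a single segregating strand).
#'
#' @param path a [ViterbiPath-class] object
#' @return individuals x chromosomes matrix of crossover counts
#' @export
countCrossovers <- function(path) {
  design <- crossDesign(path@design)
  entry <- .designEntry(design@code)
  nchr <- length(path@paths)
  out <- matrix(0, nrow(path@paths[[1L]]), nchr,
                dimnames = list(rownames(path@paths[[1L]]), names(path@paths)))
  for (k in seq_len(nchr)) {
    chr <- names(path@paths)[k]
    chromType <- if (.isXchr(chr)) "X" else "autosome"
    sf <- .stateFounderList(design, chromType,
                            if (chromType == "X") "both" else "female")
    S <- length(sf)
    D <- matrix(0, S, S)
    for (a in seq_len(S)) for (b in seq_len(S)) {
      if (entry$type %in% c("do", "f2")) {
        fa <- sf[[a]]; fb <- sf[[b]]
        shared <- sum(pmin(tabulate(fa, 16L), tabulate(fb, 16L)))
        D[a, b] <- min(length(fa), length(fb)) - shared + abs(length(fa) - length(fb))
      } else {
        D[a, b] <- as.numeric(a != b)
      }
    }
    p <- path@paths[[k]]
    P <- ncol(p)
    if (P > 1L)
      out[, k] <- rowSums(matrix(D[cbind(as.vector(p[, -P]), as.vector(p[, -1L]))],
                                 nrow(p), P - 1L))
  }
  out
}
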