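#' @include designs.R
NULL

#' Insert pseudomarkers into a genetic map
#'
#' Adds evenly spaced positions so that no gap between adjacent positions
#' exceeds `step` cM; marker positions are preserved exactly.  With
#' `step = 0` the map is returned unchanged.  An interval of width g is cut
#' into `ceiling(g / step)` equal pieces, so markers at 0 and 7 cM with
#' `step = 5` yield positions 0, 3.5, 7.
#'
#' @param map list of named numeric vectors (positions in cM per chromosome)
#' @param step maximum allowed inter-position gap, in cM
#' @return map of the same shape, with pseudomarkers named `c<chr>.loc<pos>`
#' @export
insertPseudomarkers <- function(map, step) {
  if (step < 0) .stopf("step must be >= 0")
  if (step == 0) return(map)
  out <- lapply(names(map), function(chr) {
    pos <- map[[chr]]
    if (length(pos) < 2L) return(pos)
    newpos <- pos
    for (k in seq_len(length(pos) - 1L)) {
      g <- pos[k + 1L] - pos[k]
      if (g > step) {
        nseg <- ceiling(g / step)
        ins <- pos[k] + g * seq_len(nseg - 1L) / nseg
        names(ins) <- .locName(chr, ins)
        newpos <- c(newpos, ins)
      }
    }
    sort(newpos)
  })
  names(out) <- names(map)
  out
}

# scaled forward-backward, vectorized over individuals ------------------
# init: S; trans: list length P-1 of S x S; emis: list length P, each
# n x S or NULL (pseudomarker).  Returns posterior array, scaled forward
# and backward matrices and per-individual log likelihood.
.fwdbwd <- function(n, init, trans, emis, keepFB = FALSE) {
  S <- length(init)
  P <- length(emis)
  A <- array(0, c(n, S, P))
  a <- matrix(init, n, S, byrow = TRUE)
  if (!is.null(emis[[1L]])) a <- a * emis[[1L]]
  sc <- rowSums(a)
  if (any(sc <= 0)) .stopf("impossible genotype data (zero likelihood); check codes or increase errorProb")
  a <- a / sc; A[, , 1L] <- a; ll <- log(sc)
  if (P > 1L) for (t in 2:P) {
    a <- a %*% trans[[t - 1L]]
    if (!is.null(emis[[t]])) a <- a * emis[[t]]
    sc <- rowSums(a)
    if (any(sc <= 0)) .stopf("impossible genotype data (zero likelihood); check codes or increase errorProb")
    a <- a / sc; A[, , t] <- a; ll <- ll + log(sc)
  }
  B <- if (keepFB) array(0, c(n, S, P)) else NULL
  G <- array(0, c(n, S, P))
  b <- matrix(1, n, S)
  if (keepFB) B[, , P] <- b
  G[, , P] <- A[, , P]
  if (P > 1L) for (t in (P - 1L):1L) {
    eb <- b
    if (!is.null(emis[[t + 1L]])) eb <- eb * emis[[t + 1L]]
    b <- eb %*% t(trans[[t]])
    b <- b / rowSums(b)
    if (keepFB) B[, , t] <- b
    g <- A[, , t] * b
    G[, , t] <- g / rowSums(g)
  }
  list(post = G, fwd = A, bwd = B, loglik = ll)
}

# per-chromosome HMM ingredients for one homogeneous individual group
.hmmPieces <- function(cross, chr, posmap, errorProb, mapFunction,
                       rows, chromType, sex, generation) {
  design <- cross@design
  geno <- cross@geno[[chr]]
  pos <- posmap
  P <- length(pos)
  ismar <- names(pos) %in% colnames(geno)

  init <- initProbs(design, chromType, sex = sex, generation = generation)
  S <- length(init)

  trans <- NULL
  if (P > 1L) {
    r <- .cm2r(diff(pos), mapFunction)
    cache <- new.env(parent = emptyenv())
    trans <- lapply(r, function(ri) {
      key <- sprintf("%.15g", ri)
      tm <- get0(key, envir = cache)
      if (is.null(tm)) {
        tm <- transitionProbs(design, ri, chromType,
                              generation = generation, sex = sex)
        assign(key, tm, envir = cache)
      }
      tm
    })
  }

  fg <- cross@founderGeno[[chr]]
  nF <- design@nFounders
  emis <- vector("list", P)
  for (t in seq_len(P)) {
    if (!ismar[t]) next
    mar <- names(pos)[t]
    codes <- geno[rows, mar]
    if (all(codes == 0L)) next                 # fully missing marker
    if (is.null(fg) && nF > 2L)
      .stopf("design '%s' requires founder genotypes", design@code)
    alleles <- if (is.null(fg)) c(1L, 2L) else fg[, mar]
    E <- emissionProbs(design, alleles, errorProb, chromType, sex = sex)
    emis[[t]] <- t(E)[codes + 1L, , drop = FALSE]
  }
  list(init = init, trans = trans, emis = emis, S = S)
}

# split individuals into homogeneous HMM groups for one chromosome
.hmmGroups <- function(cross, chromType) {
  design <- cross@design
  n <- length(cross@ids)
  sex <- if (length(cross@sex)) cross@sex else rep("f", n)
  gen <- if (length(cross@generation)) cross@generation else rep(NA_integer_, n)
  if (design@needsGeneration && anyNA(gen))
    .stopf("design '%s' requires per-individual generation metadata", design@code)
  if (chromType == "X" && anyNA(sex))
    .stopf("X-chromosome analysis requires known sex for every individual")
  key <- if (design@needsGeneration) gen else rep(1L, n)
  if (chromType == "X") key <- paste(sex, key)
  split(seq_len(n), key)
}

.groupMeta <- function(cross, rows, chromType) {
  sexes <- if (length(cross@sex)) unique(cross@sex[rows]) else "f"
  gens <- if (length(cross@generation)) unique(cross@generation[rows]) else NA
  list(sex = if (chromType == "X") c(f = "female", m = "male")[sexes[1L]] else "female",
       generation = if (is.na(gens[1L])) NULL else gens[1L])
}

#' Calculate genotype probabilities by the HMM
#'
#' Posterior probabilities of the design's genotype states at every position,
#' by the scaled forward-backward algorithm run per chromosome and
#' individual.  On the X chromosome of a DO/HS cross, females are computed on
#' the 36 diplotype states and males on the 8 hemizygous states, stored in a
#' combined 44-column array with the other sex's columns at zero.
#'
#' @param cross an [MppCross-class] object
#' @param map positions to compute at, typically
#'   `insertPseudomarkers(genoMap(cross), step)`; defaults to the marker map
#' @param errorProb assumed genotyping error rate (default `1e-4`)
#' @param mapFunction "haldane" (default; the HMM's no-interference
#'   assumption) or "kosambi"
#' @return a [GenotypeProb-class] object
#' @export
calcGenoprob <- function(cross, map = NULL, errorProb = 1e-4,
                         mapFunction = c("haldane", "kosambi")) {
  mapFunction <- match.arg(mapFunction)
  if (errorProb < 0 || errorProb >= 1) .stopf("errorProb must be in [0, 1)")
  if (is.null(map)) map <- cross@map
  if (!all(names(map) %in% names(cross@map)))
    .stopf("map contains chromosomes absent from the cross")
  design <- cross@design
  n <- length(cross@ids)

  probs <- vector("list", length(map))
  names(probs) <- names(map)
  for (chr in names(map)) {
    chromType <- if (.isXchr(chr)) "X" else "autosome"
    if (chromType == "X" && !design@handlesX)
      .stopf("design '%s' has no native X-chromosome support", design@code)
    pos <- map[[chr]]
    mar <- names(pos)
    unknown <- setdiff(colnames(cross@geno[[chr]]), names(cross@map[[chr]]))
    if (length(unknown))
      .stopf("markers in genotypes but not in map: %s", paste(unknown, collapse = ", "))
    stLab <- .stateLabels(design, chromType, "both")
    arr <- array(0, c(n, length(stLab), length(pos)),
                 dimnames = list(cross@ids, stLab, mar))
    groups <- .hmmGroups(cross, chromType)
    for (rows in groups) {
      meta <- .groupMeta(cross, rows, chromType)
      pieces <- .hmmPieces(cross, chr, pos, errorProb, mapFunction, rows,
                           chromType, meta$sex, meta$generation)
      fb <- .fwdbwd(length(rows), pieces$init, pieces$trans, pieces$emis)
      colidx <- match(names(pieces$init), stLab)
      arr[rows, colidx, ] <- fb$post
    }
    probs[[chr]] <- arr
  }
  new("GenotypeProb", probs = probs, map = map, design = design@code,
      alleleProb = FALSE,
      sex = if (length(cross@sex)) cross@sex else rep("f", n),
      errorProb = errorProb, mapFunction = mapFunction)
}

# Viterbi ---------------------------------------------------------------

#' Most probable founder-mosaic path (Viterbi)
#'
#' Joint maximum a posteriori state path per individual and chromosome.
#' Ties are broken toward the lower state index, deterministically.
#'
#' @inheritParams calcGenoprob
#' @return a [ViterbiPath-class] object
#' @export
calcViterbi <- function(cross, map = NULL, errorProb = 1e-4,
                        mapFunction = c("haldane", "kosambi")) {
  mapFunction <- match.arg(mapFunction)
  if (is.null(map)) map <- cross@map
  design <- cross@design
  n <- length(cross@ids)
  paths <- states <- vector("list", length(map))
  names(paths) <- names(states) <- names(map)
  logProb <- matrix(NA_real_, n, length(map),
                    dimnames = list(cross@ids, names(map)))
  for (chr in names(map)) {
    chromType <- if (.isXchr(chr)) "X" else "autosome"
    if (chromType == "X" && !design@handlesX)
      .stopf("design '%s' has no native X-chromosome support", design@code)
    pos <- map[[chr]]
    P <- length(pos)
    stLab <- .stateLabels(design, chromType, "both")
    pmat <- matrix(NA_integer_, n, P, dimnames = list(cross@ids, names(pos)))
    for (rows in .hmmGroups(cross, chromType)) {
      meta <- .groupMeta(cross, rows, chromType)
      pieces <- .hmmPieces(cross, chr, pos, errorProb, mapFunction, rows,
                           chromType, meta$sex, meta$generation)
      lT <- lapply(pieces$trans, function(m) log(m))
      lInit <- log(pieces$init)
      S <- pieces$S
      colidx <- match(names(pieces$init), stLab)
      for (gi in seq_along(rows)) {
        i <- rows[gi]
        d <- lInit
        if (!is.null(pieces$emis[[1L]])) d <- d + log(pieces$emis[[1L]][gi, ])
        psi <- matrix(0L, S, P)
        if (P > 1L) for (t in 2:P) {
          M <- lT[[t - 1L]] + d          # M[s', s] = d[s'] + log T[s', s]
          idx <- max.col(t(M), ties.method = "first")
          d <- M[cbind(idx, seq_len(S))]
          if (!is.null(pieces$emis[[t]])) d <- d + log(pieces$emis[[t]][gi, ])
          psi[, t] <- idx
        }
        path <- integer(P)
        path[P] <- which.max(d)
        logProb[i, chr] <- d[path[P]]
        if (P > 1L) for (t in (P - 1L):1L) path[t] <- psi[path[t + 1L], t + 1L]
        pmat[i, ] <- colidx[path]
      }
    }
    paths[[chr]] <- pmat
    states[[chr]] <- stLab
  }
  new("ViterbiPath", paths = paths, states = states, map = map,
      design = design@code, logProb = logProb)
}

# allele dosages --------------------------------------------------------

#' Collapse genotype probabilities to founder allele dosages
#'
#' Multiplies the raw-state probabilities by the ploidy-normalized founder
#' dosage map, yielding individuals x founders x positions arrays whose
#' (individual, position) slices sum to 1.
#'
#' @param probs a raw-state [GenotypeProb-class]
#' @return a [GenotypeProb-class] with `alleleProb = TRUE`
#' @export
genoprobToAlleleprob <- function(probs) {
  if (probs@alleleProb) .stopf("probabilities are already in allele-dosage form")
  design <- crossDesign(probs@design)
  out <- probs@probs
  for (chr in names(out)) {
    chromType <- if (.isXchr(chr)) "X" else "autosome"
    M <- founderDosageMap(design, chromType, sex = "both")
    M <- M / rowSums(M)                       # per-state ploidy normalization
    p <- out[[chr]]
    dn <- dimnames(p)
    d <- dim(p)
    flat <- matrix(aperm(p, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
    a <- flat %*% M
    arr <- aperm(array(a, c(d[1L], d[3L], ncol(M))), c(1L, 3L, 2L))
    dimnames(arr) <- list(dn[[1L]], colnames(M), dn[[3L]])
    out[[chr]] <- arr
  }
  new("GenotypeProb", probs = out, map = probs@map, design = probs@design,
      alleleProb = TRUE, sex = probs@sex, errorProb = probs@errorProb,
      mapFunction = probs@mapFunction)
}
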