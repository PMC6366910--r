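#' @include io.R
NULL

# mosaic haplotypes: list(brk = segment end positions (cM, ending at L),
#                         fdr = founder label per segment)
.founderHap <- function(f, L) list(brk = L, fdr = as.integer(f))

.mergeHap <- function(brk, fdr) {
  keep <- c(fdr[-1L] != fdr[-length(fdr)], TRUE)
  list(brk = brk[keep], fdr = fdr[keep])
}

# piece of haplotype h over (a, b], shifted boundaries kept absolute
.sliceHap <- function(h, a, b) {
  start <- c(0, h$brk[-length(h$brk)])
  idx <- which(h$brk > a & start < b)
  list(brk = pmin(h$brk[idx], b), fdr = h$fdr[idx])
}

#' Simulate one meiosis (no crossover interference)
#'
#' Crossovers are Poisson with mean equal to the map length in Morgans,
#' placed uniformly; the gamete alternates between the two parental strands
#' at each crossover, starting from a random strand.  This is exactly the
#' Haldane no-interference model assumed by the HMM's transition matrices.
#'
#' @param h1,h2 parental strand mosaics (`list(brk, fdr)`, positions in cM)
#' @param L chromosome length in cM
#' @return a gamete mosaic in the same representation
#' @export
simulateMeiosis <- function(h1, h2, L) {
  nxo <- stats::rpois(1L, L / 100)
  cur <- sample.int(2L, 1L)
  if (nxo == 0L) return(if (cur == 1L) h1 else h2)
  xo <- sort(stats::runif(nxo, 0, L))
  bounds <- c(xo, L)
  strands <- list(h1, h2)
  brk <- numeric(0); fdr <- integer(0)
  a <- 0
  for (b in bounds) {
    if (b > a) {
      piece <- .sliceHap(strands[[cur]], a, b)
      brk <- c(brk, piece$brk)
      fdr <- c(fdr, piece$fdr)
      a <- b
    }
    cur <- 3L - cur
  }
  .mergeHap(brk, fdr)
}

# gamete across all chromosomes; chromosome-specific effective lengths
.gamete <- function(ind, lens) {
  lapply(seq_along(lens), function(k)
    simulateMeiosis(ind[[k]]$mat, ind[[k]]$pat, lens[k]))
}

.mateInd <- function(p1, p2, lens) {
  g1 <- .gamete(p1, lens)
  g2 <- .gamete(p2, lens)
  lapply(seq_along(lens), function(k) list(mat = g1[[k]], pat = g2[[k]]))
}

.pureInd <- function(f, lens) {
  lapply(lens, function(L) list(mat = .founderHap(f, L), pat = .founderHap(f, L)))
}

# funnel: combine 2^k founders (given order) into one individual
.funnel <- function(founders, lens) {
  layer <- lapply(founders, .pureInd, lens = lens)
  while (length(layer) > 1L) {
    layer <- lapply(seq_len(length(layer) / 2L), function(i)
      .mateInd(layer[[2L * i - 1L]], layer[[2L * i]], lens))
  }
  layer[[1L]]
}

.founderAt <- function(h, pos) h$fdr[findInterval(pos - 1e-9, h$brk) + 1L]

#' Simulate an experimental cross with known truth
#'
#' Executes the breeding scheme of the design (backcross/F2: one generation
#' from the F1; doubled haploids: doubled F1 gametes; RILs: founder funnel
#' followed by up to `rilGenerations` generations of selfing or sib mating,
#' with residual heterozygosity reported rather than forced to fixation;
#' DO/HS: per-lineage random funnels into a G3 pool, then `generation`
#' generations of random mating in a population of `popSize`).  SNP
#' genotypes are read off the simulated mosaics and founder alleles, then
#' flipped to one of the other two genotype codes with probability
#' `errorProb` and masked with probability `missingRate`.  The X chromosome
#' (when requested, DO only) is simulated with map distances contracted by
#' 2/3, the same convention as the HMM's X transitions; males carry a single
#' X strand.
#'
#' @param design design code (any natively reconstructable design)
#' @param nInd number of individuals (or lines)
#' @param map optional marker map (list of named cM vectors); by default a
#'   grid of `nChr` chromosomes of length `chrLength` cM with markers every
#'   `markerSpacing` cM
#' @param nChr,chrLength,markerSpacing auto-grid parameters
#' @param includeX also simulate an X chromosome (design `do_hs8` only)
#' @param errorProb genotyping error rate used to corrupt the observed calls
#' @param missingRate fraction of calls masked to missing
#' @param generation DO/HS outbreeding generation (default 5)
#' @param popSize DO/HS breeding population size (default `max(2 nInd, 64)`)
#' @param rilGenerations cap on selfing/sib-mating generations (default 20)
#' @param seed optional integer seed
#' @return list with elements `cross` (an [MppCross-class]) and `truth`
#'   (a [SimTruth-class])
#' @export
simulateCross <- function(design, nInd, map = NULL, nChr = 1L,
                          chrLength = 100, markerSpacing = 1,
                          includeX = FALSE, errorProb = 0.002,
                          missingRate = 0, generation = 5L,
                          popSize = NULL, rilGenerations = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- crossDesign(design)
  entry <- .designEntry(design)
  if (includeX && entry$type != "do")
    .stopf("X-chromosome simulation is supported for design 'do_hs8' only")
  if (is.null(map)) {
    chrs <- as.character(seq_len(nChr))
    map <- lapply(chrs, function(chr) {
      pos <- seq(0, chrLength, by = markerSpacing)
      stats::setNames(pos, sprintf("c%sm%03d", chr, seq_along(pos)))
    })
    names(map) <- chrs
    if (includeX) {
      pos <- seq(0, chrLength, by = markerSpacing)
      map$X <- stats::setNames(pos, sprintf("cXm%03d", seq_along(pos)))
    }
  }
  chrs <- names(map)
  isX <- vapply(chrs, .isXchr, TRUE)
  Ls <- vapply(map, function(m) max(m), 0)
  lens <- ifelse(isX, Ls * 2 / 3, Ls)     # effective (recombination) lengths
  nF <- d@nFounders

  inds <- switch(entry$type,
    backcross = {
      f1 <- .mateInd(.pureInd(1L, lens), .pureInd(2L, lens), lens)
      lapply(seq_len(nInd), function(i) .mateInd(f1, .pureInd(1L, lens), lens))
    },
    f2 = {
      f1 <- .mateInd(.pureInd(1L, lens), .pureInd(2L, lens), lens)
      lapply(seq_len(nInd), function(i) .mateInd(f1, f1, lens))
    },
    inbred = {
      lapply(seq_len(nInd), function(i) {
        ord <- sample.int(nF)
        if (identical(entry$mating, "dh")) {
          f1 <- .funnel(as.list(ord), lens)
          g <- .gamete(f1, lens)
          return(lapply(g, function(h) list(mat = h, pat = h)))
        }
        if (entry$mating == "self") {
          ind <- .funnel(as.list(ord), lens)
          for (g in seq_len(rilGenerations)) ind <- .mateInd(ind, ind, lens)
          ind
        } else {                       # sib mating: two parallel funnels
          half <- length(ord)
          s1 <- .funnel(as.list(ord), lens)
          s2 <- .funnel(as.list(ord), lens)
          for (g in seq_len(rilGenerations)) {
            n1 <- .mateInd(s1, s2, lens)
            n2 <- .mateInd(s1, s2, lens)
            s1 <- n1; s2 <- n2
          }
          s1
        }
      })
    },
    do = {
      if (is.null(popSize)) popSize <- max(2L * nInd, 64L)
      pool <- lapply(seq_len(popSize), function(i)
        .funnel(as.list(sample.int(8L)), lens))
      if (generation > 1L) for (g in seq_len(generation - 1L)) {
        pool <- lapply(seq_len(popSize), function(i) {
          pr <- sample.int(popSize, 2L)
          .mateInd(pool[[pr[1L]]], pool[[pr[2L]]], lens)
        })
      }
      lapply(seq_len(nInd), function(i) {
        pr <- sample.int(popSize, 2L)
        .mateInd(pool[[pr[1L]]], pool[[pr[2L]]], lens)
      })
    })

  sex <- sample(rep_len(c("f", "m"), nInd))
  # males carry a single X strand (the maternally transmitted one)
  if (any(isX)) {
    for (i in which(sex == "m")) {
      k <- which(isX)
      inds[[i]][[k]]$pat <- NULL
    }
  }

  founderAlleles <- lapply(chrs, function(chr) {
    nm <- length(map[[chr]])
    fa <- if (nF == 2L) matrix(rep(c(1L, 2L), nm), 2L, nm)
          else matrix(sample(c(1L, 2L), nF * nm, replace = TRUE), nF, nm)
    dimnames(fa) <- list(LETTERS[seq_len(nF)], names(map[[chr]]))
    fa
  })
  names(founderAlleles) <- chrs

  ids <- sprintf("ind%04d", seq_len(nInd))
  geno <- vector("list", length(chrs)); names(geno) <- chrs
  for (kc in seq_along(chrs)) {
    chr <- chrs[kc]
    pos <- unname(map[[chr]]) * (if (isX[kc]) 2 / 3 else 1)
    fa <- founderAlleles[[chr]]
    nm <- length(pos)
    g <- matrix(0L, nInd, nm, dimnames = list(ids, names(map[[chr]])))
    for (i in seq_len(nInd)) {
      fm <- .founderAt(inds[[i]][[kc]]$mat, pos)
      a1 <- fa[cbind(fm, seq_len(nm))]
      if (isX[kc] && sex[i] == "m") {
        g[i, ] <- ifelse(a1 == 1L, 1L, 3L)
      } else {
        fp <- .founderAt(inds[[i]][[kc]]$pat, pos)
        a2 <- fa[cbind(fp, seq_len(nm))]
        g[i, ] <- 1L + (a1 != a2) + 2L * (a1 == 2L & a2 == 2L)
      }
    }
    if (errorProb > 0) {
      err <- matrix(stats::runif(length(g)) < errorProb, nInd, nm)
      shift <- matrix(sample(1:2, length(g), replace = TRUE), nInd, nm)
      g[err] <- 1L + (g[err] - 1L + shift[err]) %% 3L
    }
    if (missingRate > 0)
      g[matrix(stats::runif(length(g)) < missingRate, nInd, nm)] <- 0L
    geno[[chr]] <- g
  }

  fg <- if (nF == 2L) stats::setNames(vector("list", length(chrs)), chrs)
        else founderAlleles
  cross <- new("MppCross", design = d, geno = geno, founderGeno = fg,
               map = map, pmap = list(),
               pheno = matrix(numeric(0), nInd, 0L, dimnames = list(ids, NULL)),
               covar = data.frame(row.names = ids), sex = sex,
               generation = if (d@needsGeneration)
                 rep(as.integer(generation), nInd) else integer(0),
               ids = ids)
  mosaics <- inds
  names(mosaics) <- ids
  for (i in seq_len(nInd)) names(mosaics[[i]]) <- chrs
  # realized kinship of the true mosaics at the autosomal marker grid
  K <- matrix(0, nInd, nInd, dimnames = list(ids, ids))
  nmar <- 0L
  for (kc in which(!isX)) {
    chr <- chrs[kc]
    pos <- unname(map[[chr]])
    dos <- vapply(mosaics, function(m)
      cbind(.founderAt(m[[chr]]$mat, pos), .founderAt(m[[chr]]$pat, pos)),
      matrix(0L, length(pos), 2L))
    for (t in seq_along(pos)) {
      Pd <- t(apply(dos[t, , ], 2L, tabulate, nbins = nF)) / 2
      K <- K + tcrossprod(Pd)
    }
    nmar <- nmar + length(pos)
  }
  truth <- new("SimTruth", mosaics = mosaics, map = map,
               founderAlleles = founderAlleles, pheno = list(),
               kinship = K / nmar)
  list(cross = cross, truth = truth)
}

# founder dosage matrix (n x nF) at one position of one chromosome
.truthDosage <- function(truth, chr, pos, nF, isXpos = FALSE) {
  p <- pos * (if (isXpos) 2 / 3 else 1)
  t(vapply(truth@mosaics, function(m) {
    fm <- .founderAt(m[[chr]]$mat, p)
    dose <- tabulate(fm, nF)
    if (!is.null(m[[chr]]$pat)) dose <- dose + tabulate(.founderAt(m[[chr]]$pat, p), nF)
    as.numeric(dose)
  }, numeric(nF)))
}

#' Simulate a phenotype on a simulated cross
#'
#' Builds `y` as the sum of QTL terms (from the true founder dosages at each
#' QTL), a polygenic term drawn from N(0, K) with K the realized kinship of
#' the true mosaics at the marker grid, and a Gaussian residual.  Each QTL
#' term is scaled to its requested variance fraction (in sample variance);
#' the residual takes up the remainder, so the realized fractions are
#' recorded alongside.
#'
#' @param cross,truth output of [simulateCross()]
#' @param qtl list of QTL specifications, each a list with `chr`, `pos` and
#'   either `effects` (per-founder additive haplotype effects) or `sdp`
#'   (biallelic strain-distribution mask), plus `varExplained`
#' @param h2 polygenic variance fraction
#' @param seed optional integer seed
#' @return list with `pheno` (named numeric), `components` (matrix of the
#'   generating terms) and `varFractions`
#' @export
simulatePhenotype <- function(cross, truth, qtl = list(), h2 = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(cross@ids)
  nF <- cross@design@nFounders
  scaleTo <- function(x, v) {
    s <- stats::sd(x)
    if (s < 1e-12 || v <= 0) return(rep(0, n))
    x / s * sqrt(v)
  }
  qtlTerm <- rep(0, n)
  vq <- 0
  for (q in qtl) {
    D <- .truthDosage(truth, q$chr, q$pos, nF, .isXchr(q$chr))
    term <- if (!is.null(q$effects)) drop(D %*% q$effects)
            else drop(D %*% .sdpBits(q$sdp, nF))
    qtlTerm <- qtlTerm + scaleTo(term, q$varExplained)
    vq <- vq + q$varExplained
  }
  poly <- rep(0, n)
  if (h2 > 0) {
    L <- chol(truth@kinship + diag(1e-8, n))
    poly <- scaleTo(drop(crossprod(L, stats::rnorm(n))), h2)
  }
  resid <- stats::rnorm(n, sd = sqrt(max(1 - vq - h2, 0)))
  y <- stats::setNames(qtlTerm + poly + resid, cross@ids)
  comp <- cbind(qtl = qtlTerm, polygenic = poly, residual = resid)
  vf <- apply(comp, 2L, stats::var) / stats::var(y)
  list(pheno = y, components = comp, varFractions = vf)
}

# fast two-locus simulation of the DO breeding scheme (independent
# lineages, exact under the no-interference model): returns an n x 2
# matrix of (left, right) founder origins of generation-`gen` haplotypes
# separated by recombination fraction r.  Used as the Monte-Carlo oracle
# for the DO transition matrix.
.simDoTwoLocus <- function(n, r, gen) {
  gamete <- function(hA, hB) {
    s1 <- stats::runif(n) < 0.5
    s2 <- xor(s1, stats::runif(n) < r)
    cbind(ifelse(s1, hA[, 1L], hB[, 1L]), ifelse(s2, hA[, 2L], hB[, 2L]))
  }
  g3hap <- function(cols) {             # cols: n x 4 founder assignment
    i1 <- cbind(cols[, 1L], cols[, 1L]); i2 <- cbind(cols[, 2L], cols[, 2L])
    i3 <- cbind(cols[, 3L], cols[, 3L]); i4 <- cbind(cols[, 4L], cols[, 4L])
    g2 <- gamete(gamete(i1, i2), gamete(i3, i4))
    g2
  }
  perm <- t(vapply(seq_len(n), function(i) sample.int(8L), integer(8L)))
  g3 <- function(half) g3hap(perm[, half])   # half: columns 1:4 or 5:8
  hap <- function(k) {
    if (k == 1L) return(gamete(g3(1:4), g3(5:8)))
    gamete(hap(k - 1L), hap(k - 1L))
  }
  hap(gen)
}
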