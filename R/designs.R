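#' @include AllClasses.R utils.R
NULL

# design registry -------------------------------------------------------

# type determines the state-space machinery:
#   backcross : states AA, AB (one segregating gamete)
#   f2        : unordered pairs of 2 founders (AA, AB, BB)
#   inbred    : fully inbred lines, states = founder labels (DH and RILs)
#   do        : 8-founder outbred diplotypes, generation-dependent transitions
.DESIGNS <- list(
  backcross        = list(type = "backcross", nFounders = 2L),
  intercross_F2    = list(type = "f2",        nFounders = 2L),
  doubled_haploids = list(type = "inbred",    nFounders = 2L, mating = "dh"),
  riself2  = list(type = "inbred", nFounders = 2L,  mating = "self"),
  risib2   = list(type = "inbred", nFounders = 2L,  mating = "sib"),
  riself4  = list(type = "inbred", nFounders = 4L,  mating = "self"),
  riself8  = list(type = "inbred", nFounders = 8L,  mating = "self"),
  riself16 = list(type = "inbred", nFounders = 16L, mating = "self"),
  risib4   = list(type = "inbred", nFounders = 4L,  mating = "sib"),
  risib8   = list(type = "inbred", nFounders = 8L,  mating = "sib"),
  do_hs8   = list(type = "do",     nFounders = 8L)
)

.designEntry <- function(code) {
  if (is(code, "CrossDesign")) code <- code@code
  entry <- .DESIGNS[[code]]
  if (is.null(entry)) .stopf("unknown cross design code: '%s'", code)
  entry
}

#' Look up a built-in cross design
#'
#' Built-in designs: `backcross`, `intercross_F2`, `doubled_haploids`,
#' 2-/4-/8-/16-way recombinant inbred lines by selfing (`riself2`, `riself4`,
#' `riself8`, `riself16`), 2-/4-/8-way RILs by sibling mating (`risib2`,
#' `risib4`, `risib8`), and 8-founder Diversity Outbred / heterogeneous stock
#' (`do_hs8`).  Designs outside this list (e.g. 19-way MAGIC) are supported
#' through the custom probability import path ([importGenoprob()]) rather
#' than native transition code.
#'
#' @param code design code string
#' @return a [CrossDesign-class] object
#' @examples
#' crossDesign("do_hs8")
#' @export
crossDesign <- function(code) {
  entry <- .designEntry(code)
  new("CrossDesign", code = code, nFounders = entry$nFounders,
      phaseKnown = FALSE,
      handlesX = identical(entry$type, "do"),
      needsGeneration = identical(entry$type, "do"))
}

# state spaces ----------------------------------------------------------

# founder composition of each state: list of integer vectors
# (length 2 = diplotype, length 1 = hemizygous male X)
.stateFounderList <- function(design, chromType = c("autosome", "X"),
                              sex = c("female", "male", "both")) {
  chromType <- match.arg(chromType)
  sex <- match.arg(sex)
  entry <- .designEntry(design)
  n <- entry$nFounders
  if (chromType == "X" && entry$type != "do")
    .stopf("design '%s' has no native X-chromosome support",
           if (is(design, "CrossDesign")) design@code else design)
  fem <- switch(entry$type,
    backcross = list(c(1L, 1L), c(1L, 2L)),
    f2        = ,
    do        = { p <- .founderPairs(n); lapply(seq_len(ncol(p)), function(k) p[, k]) },
    inbred    = lapply(seq_len(n), function(f) c(f, f)))
  if (chromType == "autosome") return(fem)
  male <- lapply(seq_len(n), function(f) f)
  switch(sex, female = fem, male = male, both = c(fem, male))
}

.stateLabels <- function(design, chromType = "autosome", sex = "both") {
  entry <- .designEntry(design)
  n <- entry$nFounders
  fem <- switch(entry$type,
    backcross = c("AA", "AB"),
    f2        = c("AA", "AB", "BB"),
    do        = .pairLabels(n),
    inbred    = LETTERS[seq_len(n)])
  if (chromType == "autosome") return(fem)
  male <- paste0(LETTERS[seq_len(n)], "Y")
  switch(sex, female = fem, male = male, both = c(fem, male))
}

#' Number of genotype states for a design
#'
#' For an n-founder outbred design the autosomal states are the n(n+1)/2
#' unordered founder pairs (diplotypes); on the X chromosome a combined-sex
#' probability array additionally carries the n hemizygous male states, so an
#' 8-founder DO autosome has 36 states and the combined-sex X has 44.
#'
#' @param design a [CrossDesign-class] or design code
#' @param chromType "autosome" or "X"
#' @param bothSexes on the X, count female diplotype states plus male
#'   hemizygous states (the combined probability-array layout)?
#' @return integer state count
#' @examples
#' nGenotypeStates("do_hs8")                        # 36
#' nGenotypeStates("do_hs8", "X", bothSexes = TRUE) # 44
#' @export
nGenotypeStates <- function(design, chromType = c("autosome", "X"),
                            bothSexes = FALSE) {
  chromType <- match.arg(chromType)
  sex <- if (chromType == "X" && bothSexes) "both" else "female"
  length(.stateFounderList(design, chromType, sex))
}

#' State labels for a design
#'
#' @inheritParams nGenotypeStates
#' @param sex "female", "male", or "both" (X chromosome only)
#' @return character vector of state labels, in the package's fixed
#'   founder-pair lexicographic order
#' @export
genoStates <- function(design, chromType = c("autosome", "X"), sex = "both") {
  chromType <- match.arg(chromType)
  .stateLabels(design, chromType, if (chromType == "autosome") "both" else sex)
}

# initial distributions -------------------------------------------------

# diplotype distribution implied by independent haplotypes with marginal pi
.dipInit <- function(pi) {
  n <- length(pi)
  p <- .founderPairs(n)
  ifelse(p[1L, ] == p[2L, ], pi[p[1L, ]]^2, 2 * pi[p[1L, ]] * pi[p[2L, ]])
}

#' HMM initial state distribution
#'
#' Uniform over founder lines for inbred designs, Mendelian for backcross/F2,
#' and Hardy-Weinberg on equally frequent founder haplotypes for DO/HS
#' (heterozygous diplotypes 2/64, homozygous 1/64 on an 8-founder autosome).
#'
#' @inheritParams nGenotypeStates
#' @param sex "female" or "male" (X chromosome only)
#' @param generation outbreeding generation (required for `do_hs8`)
#' @return probability vector over the design's states (sums to 1)
#' @export
initProbs <- function(design, chromType = c("autosome", "X"),
                      sex = "female", generation = NULL) {
  chromType <- match.arg(chromType)
  entry <- .designEntry(design)
  if (entry$type == "do" && is.null(generation))
    .stopf("design 'do_hs8' requires a generation")
  n <- entry$nFounders
  pr <- switch(entry$type,
    backcross = c(0.5, 0.5),
    f2        = c(0.25, 0.5, 0.25),
    inbred    = rep(1 / n, n),
    do        = if (chromType == "X" && sex == "male") rep(1 / n, n)
                else .dipInit(rep(1 / n, n)))
  names(pr) <- .stateLabels(design, chromType,
                            if (chromType == "X") sex else "both")
  pr
}

# transition matrices ---------------------------------------------------

# haplotype-level transition matrix for a single meiosis (2 founders)
.meiosisH <- function(r) matrix(c(1 - r, r, r, 1 - r), 2L, 2L)

# collapse an independent-haplotype-pair process to unordered diplotypes
.dipCollapse <- function(H) {
  n <- nrow(H)
  p <- .founderPairs(n)
  np <- ncol(p)
  out <- matrix(0, np, np)
  for (from in seq_len(np)) {
    a <- p[1L, from]; b <- p[2L, from]
    for (to in seq_len(np)) {
      cc <- p[1L, to]; dd <- p[2L, to]
      out[from, to] <- if (cc == dd) H[a, cc] * H[b, cc]
                       else H[a, cc] * H[b, dd] + H[a, dd] * H[b, cc]
    }
  }
  out
}

# two-locus same-founder haplotype probability at fixation for 2^k-way RILs;
# each funnel generation beyond the base design contributes a factor (1-r)
.rilSameProb <- function(r, nFounders, mating) {
  k <- log2(nFounders)
  switch(mating,
         dh   = 1 - r,
         self = (1 - r)^(k - 1) / (1 + 2 * r),
         sib  = if (nFounders == 2L) (1 + 2 * r) / (1 + 6 * r)
                else (1 - r)^(k - 2) / (1 + 6 * r))
}

# DO/HS haplotype same-founder probability: idealized 8-way funnel
# (3 generations) followed by `gen` generations of random outbreeding
.doSameProb <- function(r, gen) {
  1 / 8 + ((1 - r)^3 - 1 / 8) * (1 - r)^(gen - 1)
}

.symmetricH <- function(psame, n) {
  H <- matrix((1 - psame) / (n - 1), n, n)
  diag(H) <- psame
  H
}

#' HMM transition ("step") matrix between adjacent positions
#'
#' Row-stochastic matrix of state-transition probabilities across an interval
#' with recombination fraction `r`, specific to the cross design.  Two-way
#' RILs use the classical fixation formulas (off-diagonal `2r/(1+2r)` for
#' selfing, `4r/(1+6r)` for sibling mating); multi-way RILs extend them with
#' one factor of `(1-r)` per additional funnel generation.  DO/HS transitions
#' follow the generation-dependent recurrence of the package's breeding model
#' (see the methods vignette), applied independently to the two haplotypes
#' and collapsed to unordered diplotypes.  On the X the female map is
#' contracted by the factor 2/3 (recombination only in female meioses).
#'
#' @inheritParams initProbs
#' @param r recombination fraction in `[0, 0.5]`
#' @return states x states row-stochastic matrix; the identity when `r = 0`
#' @examples
#' transitionProbs("riself2", 0.01)[1, 2]   # 2r/(1+2r)
#' @export
transitionProbs <- function(design, r, chromType = c("autosome", "X"),
                            generation = NULL, sex = "female") {
  chromType <- match.arg(chromType)
  if (r < 0 || r > 0.5) .stopf("r must be in [0, 0.5], got %g", r)
  entry <- .designEntry(design)
  out <- switch(entry$type,
    backcross = .meiosisH(r),
    f2        = .dipCollapse(.meiosisH(r)),
    inbred    = .symmetricH(.rilSameProb(r, entry$nFounders, entry$mating),
                            entry$nFounders),
    do = {
      if (is.null(generation) || generation < 1)
        .stopf("design 'do_hs8' requires generation >= 1")
      reff <- if (chromType == "X") 2 * r / 3 else r
      H <- .symmetricH(.doSameProb(reff, generation), entry$nFounders)
      if (chromType == "X" && sex == "male") H else .dipCollapse(H)
    })
  lab <- .stateLabels(design, chromType, if (chromType == "X") sex else "both")
  dimnames(out) <- list(lab, lab)
  out
}

# emissions -------------------------------------------------------------

# genotype distribution (AA, AB, BB) implied by a state's founder content;
# alleles: integer vector over founders, 0 = missing, 1 = A, 2 = B.
# Missing founder alleles marginalize with probability 1/2 each; the two
# chromosomes of a founder-homozygous state carry the *same* (inbred) allele.
.stateGenoDist <- function(founders, alleles) {
  pA <- c(`0` = 0.5, `1` = 1, `2` = 0)[as.character(alleles[founders])]
  if (length(founders) == 1L || founders[1L] == founders[2L]) {
    pA <- pA[1L]
    c(AA = pA, AB = 0, BB = 1 - pA)
  } else {
    c(AA = pA[1L] * pA[2L],
      AB = pA[1L] * (1 - pA[2L]) + (1 - pA[1L]) * pA[2L],
      BB = (1 - pA[1L]) * (1 - pA[2L]))
  }
}

# S x 3 matrix of implied-genotype distributions for all states at one marker
.stateGenoMatrix <- function(stateFounders, alleles) {
  t(vapply(stateFounders, .stateGenoDist, numeric(3L), alleles = alleles))
}

#' Emission probabilities at one marker
#'
#' Probability of each observable genotype code given the true state, under
#' the symmetric error model: the true genotype is observed with probability
#' `1 - errorProb`, and errors are split evenly between the other two full
#' genotype codes.  Partial codes (`notAA`, `notBB`) aggregate the consistent
#' full codes; a missing observation has emission probability 1 everywhere;
#' a missing founder allele is marginalized with probability 1/2 per allele.
#'
#' @inheritParams initProbs
#' @param founderAlleles integer vector over founders: 0 missing, 1 A, 2 B
#' @param errorProb genotyping error rate epsilon
#' @return states x 6 matrix with columns
#'   `missing`, `AA`, `AB`, `BB`, `notAA`, `notBB`
#' @export
emissionProbs <- function(design, founderAlleles, errorProb,
                          chromType = c("autosome", "X"), sex = "female") {
  chromType <- match.arg(chromType)
  sf <- .stateFounderList(design, chromType,
                          if (chromType == "X") sex else "female")
  G <- .stateGenoMatrix(sf, founderAlleles)        # S x 3, rows sum to 1
  full <- G * (1 - errorProb) + (1 - G) * (errorProb / 2)
  out <- cbind(missing = 1, full,
               notAA = full[, 2L] + full[, 3L],
               notBB = full[, 1L] + full[, 2L])
  colnames(out) <- c("missing", "AA", "AB", "BB", "notAA", "notBB")
  rownames(out) <- .stateLabels(design, chromType,
                                if (chromType == "X") sex else "both")
  out
}

# dosage map ------------------------------------------------------------

#' Founder dosage of each genotype state
#'
#' The matrix that collapses raw states to founder "dosages": entry (s, f)
#' counts the copies of founder f's haplotype in state s.  Rows sum to the
#' state's ploidy (2 for diplotypes, 1 for hemizygous male X states).
#'
#' @inheritParams nGenotypeStates
#' @param sex "female", "male", or "both" (X chromosome only)
#' @return states x founders integer matrix
#' @export
founderDosageMap <- function(design, chromType = c("autosome", "X"),
                             sex = "both") {
  chromType <- match.arg(chromType)
  entry <- .designEntry(design)
  sf <- .stateFounderList(design, chromType,
                          if (chromType == "X") sex else "female")
  n <- entry$nFounders
  out <- t(vapply(sf, function(f) tabulate(f, nbins = n), integer(n)))
  dimnames(out) <- list(.stateLabels(design, chromType,
                                     if (chromType == "X") sex else "both"),
                        LETTERS[seq_len(n)])
  out
}
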