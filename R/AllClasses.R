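#' @import methods
NULL

#' Cross-design descriptor
#'
#' Describes one supported breeding design: its founder count, whether
#' heterozygous states are phase-known, whether the design has native
#' X-chromosome support, and whether per-individual outbreeding generation
#' metadata is required (Diversity Outbred / heterogeneous stock).
#'
#' @slot code design code, one of the built-in codes (see [crossDesign()])
#' @slot nFounders number of founder strains
#' @slot phaseKnown are heterozygous diplotypes phase-known? (always `FALSE`
#'   for the built-in designs; states are unordered founder pairs)
#' @slot handlesX does the design have native X-chromosome state handling?
#' @slot needsGeneration does the HMM need an outbreeding generation?
#'
#' @exportClass CrossDesign
setClass("CrossDesign",
         representation(code = "character",
                        nFounders = "integer",
                        phaseKnown = "logical",
                        handlesX = "logical",
                        needsGeneration = "logical"))

setValidity("CrossDesign", function(object) {
  if (length(object@code) != 1L) return("code must be a single string")
  if (!object@nFounders %in% c(2L, 4L, 8L, 16L))
    return("nFounders must be one of 2, 4, 8, 16 for built-in designs")
  TRUE
})

#' Experimental-cross data container
#'
#' Holds the observed SNP genotypes, founder genotypes, genetic (and optional
#' physical) map, phenotypes, covariates and individual metadata for one
#' population, aligned by individual ID.  Genotypes are stored per chromosome
#' as individuals x markers integer matrices using codes
#' 0 = missing, 1 = AA, 2 = AB, 3 = BB, 4 = notAA, 5 = notBB; founder
#' genotypes use allele codes 0 = missing, 1 = A, 2 = B.
#'
#' @slot design a [CrossDesign-class] object
#' @slot geno list (one per chromosome) of individuals x markers integer
#'   matrices of observed genotype codes
#' @slot founderGeno list (one per chromosome) of founders x markers integer
#'   allele matrices (may be empty for biparental designs, where founder 1
#'   carries A and founder 2 carries B at every marker)
#' @slot map list of named numeric vectors of marker positions in cM
#' @slot pmap optional physical map (bp), same shape as `map`
#' @slot pheno individuals x traits numeric matrix
#' @slot covar individuals x columns data.frame of covariates
#' @slot sex character vector, "f"/"m" per individual
#' @slot generation integer outbreeding generation per individual (DO/HS)
#' @slot ids individual identifiers
#'
#' @exportClass MppCross
setClass("MppCross",
         representation(design = "CrossDesign",
                        geno = "list",
                        founderGeno = "list",
                        map = "list",
                        pmap = "list",
                        pheno = "matrix",
                        covar = "data.frame",
                        sex = "character",
                        generation = "integer",
                        ids = "character"))

setValidity("MppCross", function(object) {
  msg <- character(0)
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "individual IDs must be unique")
  if (!identical(names(object@geno), names(object@map)))
    msg <- c(msg, "geno and map must cover the same chromosomes, in order")
  for (chr in names(object@geno)) {
    g <- object@geno[[chr]]
    if (nrow(g) != n) msg <- c(msg, sprintf("chr %s: genotype rows != #individuals", chr))
    if (!identical(colnames(g), names(object@map[[chr]])))
      msg <- c(msg, sprintf("chr %s: genotype columns must match map markers", chr))
    if (is.unsorted(object@map[[chr]]))
      msg <- c(msg, sprintf("chr %s: map positions must be nondecreasing", chr))
  }
  if (length(object@sex) && length(object@sex) != n)
    msg <- c(msg, "sex must have one entry per individual")
  if (nrow(object@pheno) && nrow(object@pheno) != n)
    msg <- c(msg, "phenotype rows must match individuals")
  if (length(msg)) msg else TRUE
})

#' Genotype (or founder allele dosage) probabilities
#'
#' The HMM output contract: one 3-d array per chromosome with dimensions
#' individuals x states x positions.  Every (individual, position) slice sums
#' to 1.  `alleleProb = TRUE` marks the collapsed founder-dosage form in which
#' the state dimension indexes founders rather than diplotypes.
#'
#' @slot probs list of 3-d arrays, one per chromosome, dimnames set to
#'   (individual IDs, state labels, position labels)
#' @slot map positions (cM) of each array's third dimension, named
#' @slot design design code used for the computation
#' @slot alleleProb `TRUE` when the arrays are founder-dosage probabilities
#' @slot sex per-individual sex, used for combined-sex X arrays
#' @slot errorProb genotyping error rate used
#' @slot mapFunction map function used ("haldane" or "kosambi")
#'
#' @exportClass GenotypeProb
setClass("GenotypeProb",
         representation(probs = "list",
                        map = "list",
                        design = "character",
                        alleleProb = "logical",
                        sex = "character",
                        errorProb = "numeric",
                        mapFunction = "character"))

setValidity("GenotypeProb", function(object) {
  msg <- character(0)
  if (!identical(names(object@probs), names(object@map)))
    msg <- c(msg, "probs and map must cover the same chromosomes")
  for (chr in names(object@probs)) {
    p <- object@probs[[chr]]
    if (length(dim(p)) != 3L) { msg <- c(msg, "each probs entry must be a 3-d array"); next }
    if (dim(p)[3L] != length(object@map[[chr]]))
      msg <- c(msg, sprintf("chr %s: positions do not match map", chr))
    if (any(p < -1e-12 | p > 1 + 1e-12)) msg <- c(msg, sprintf("chr %s: entries outside [0,1]", chr))
    ss <- apply(p, c(1L, 3L), sum)
    if (any(abs(ss - 1) > 1e-6)) msg <- c(msg, sprintf("chr %s: slices do not sum to 1", chr))
  }
  if (length(msg)) msg else TRUE
})

#' Viterbi haplotype reconstruction
#'
#' Maximum a posteriori state paths per chromosome, individuals x positions,
#' with the joint log probability of each individual's path.
#'
#' @slot paths list of individuals x positions integer matrices (state indices)
#' @slot states list of state-label vectors per chromosome
#' @slot map positions per chromosome (cM)
#' @slot design design code
#' @slot logProb individuals x chromosomes matrix of path log probabilities
#'
#' @exportClass ViterbiPath
setClass("ViterbiPath",
         representation(paths = "list",
                        states = "list",
                        map = "list",
                        design = "character",
                        logProb = "matrix"))

#' Genome-scan result
#'
#' LOD scores at every scanned position for one or more phenotypes, with the
#' position map and the model degrees of freedom.
#'
#' @slot lod positions x phenotypes matrix of LOD scores
#' @slot chr chromosome of each position
#' @slot pos cM position of each scanned position
#' @slot model model tag ("full", "additive", or "snp")
#' @slot df model degrees of freedom (autosomal model)
#' @slot n number of individuals used per phenotype
#' @slot method "hk" or "lmm"
#'
#' @exportClass ScanResult
setClass("ScanResult",
         representation(lod = "matrix",
                        chr = "character",
                        pos = "numeric",
                        model = "character",
                        df = "integer",
                        n = "integer",
                        method = "character"))

setValidity("ScanResult", function(object) {
  if (length(object@chr) != nrow(object@lod) || length(object@pos) != nrow(object@lod))
    return("chr/pos must annotate every scan row")
  if (any(!is.finite(object@lod))) return("LOD scores must be finite")
  TRUE
})

#' Permutation-test null maxima
#'
#' Genome-wide maximum LOD scores under permutation of the haplotype
#' probability rows, stored separately for autosomes and (optionally) the X
#' chromosome, plus the summed map lengths used for the length-apportioned
#' significance levels.
#'
#' @slot maxLod replicates x phenotypes matrix of autosomal maxima
#' @slot maxLodX replicates x phenotypes matrix of X maxima (0 columns if X
#'   was not scanned separately)
#' @slot lengthA summed autosomal map length (cM)
#' @slot lengthX summed X map length (cM)
#'
#' @exportClass ScanPerm
setClass("ScanPerm",
         representation(maxLod = "matrix",
                        maxLodX = "matrix",
                        lengthA = "numeric",
                        lengthX = "numeric"))

#' Per-position effect estimates
#'
#' Fixed-effect (least squares) or BLUP estimates of the state/founder
#' effects along one chromosome.
#'
#' @slot coef positions x effects matrix (state or founder effects, then any
#'   covariate columns; BLUP mode stores the random founder effects plus an
#'   intercept column)
#' @slot se matching standard errors (fixed-effect mode; 0-row otherwise)
#' @slot pos scanned positions (cM)
#' @slot chr chromosome
#' @slot mode "ols" or "blup"
#'
#' @exportClass EffectEstimates
setClass("EffectEstimates",
         representation(coef = "matrix",
                        se = "matrix",
                        pos = "numeric",
                        chr = "character",
                        mode = "character"))

#' Simulation ground truth
#'
#' The generating truth for a simulated cross: the founder mosaic of each
#' individual (two strands per autosome; males carry one X strand), the map,
#' founder SNP alleles, and (once a phenotype has been simulated) the
#' phenotype decomposition.
#'
#' @slot mosaics list (per individual) of lists (per chromosome) with
#'   elements `mat` and `pat`, each a list with numeric `brk` (segment end
#'   positions in cM, ending at the chromosome length) and integer `fdr`
#'   (founder label per segment)
#' @slot map the marker map used (cM)
#' @slot founderAlleles list per chromosome of founders x markers allele codes
#' @slot pheno list with the phenotype decomposition (qtl/polygenic/residual
#'   components and realized variance fractions); empty until a phenotype is
#'   simulated
#' @slot kinship realized kinship of the true mosaics at the autosomal
#'   marker grid (used as the polygenic covariance by [simulatePhenotype()])
#'
#' @exportClass SimTruth
setClass("SimTruth",
         representation(mosaics = "list",
                        map = "list",
                        founderAlleles = "list",
                        pheno = "list",
                        kinship = "matrix"))
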