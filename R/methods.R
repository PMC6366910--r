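#' @include AllGenerics.R designs.R
NULL

#' @export
setMethod("designCode", "CrossDesign", function(x) x@code)
#' @export
setMethod("designCode", "MppCross", function(x) x@design@code)
#' @export
setMethod("designCode", "GenotypeProb", function(x) x@design)

#' @export
setMethod("nFounders", "CrossDesign", function(x) x@nFounders)
#' @export
setMethod("nFounders", "MppCross", function(x) x@design@nFounders)

#' @export
setMethod("nInd", "MppCross", function(x) length(x@ids))
#' @export
setMethod("nInd", "GenotypeProb", function(x) dim(x@probs[[1L]])[1L])

#' @export
setMethod("chrNames", "MppCross", function(x) names(x@map))
#' @export
setMethod("chrNames", "GenotypeProb", function(x) names(x@probs))
#' @export
setMethod("chrNames", "ScanResult", function(x) unique(x@chr))

#' @export
setMethod("genoMap", "MppCross", function(x) x@map)
#' @export
setMethod("genoMap", "GenotypeProb", function(x) x@map)

#' @export
setMethod("probArray", "GenotypeProb", function(x, chr) x@probs[[chr]])
#' @export
setMethod("stateNames", "GenotypeProb",
          function(x, chr) dimnames(x@probs[[chr]])[[2L]])

#' @export
setMethod("lodMatrix", "ScanResult", function(x) x@lod)
#' @export
setMethod("phenoMatrix", "MppCross", function(x) x@pheno)

setMethod("show", "CrossDesign", function(object) {
  cat(sprintf("CrossDesign '%s': %d founders, %d autosomal states%s%s\n",
              object@code, object@nFounders,
              nGenotypeStates(object),
              if (object@handlesX) ", native X handling" else "",
              if (object@needsGeneration) ", needs generation" else ""))
})

setMethod("show", "MppCross", function(object) {
  nm <- sum(lengths(object@map))
  cat(sprintf("MppCross: design '%s', %d individuals, %d chromosomes, %d markers\n",
              object@design@code, length(object@ids),
              length(object@map), nm))
  cat(sprintf("  phenotypes: %d; covariates: %d; sex recorded: %s\n",
              ncol(object@pheno), ncol(object@covar),
              if (length(object@sex)) "yes" else "no"))
})

setMethod("show", "GenotypeProb", function(object) {
  cat(sprintf("GenotypeProb (%s): design '%s', %d individuals, %d chromosomes\n",
              if (object@alleleProb) "founder dosages" else "genotype states",
              object@design, dim(object@probs[[1L]])[1L], length(object@probs)))
  for (chr in names(object@probs))
    cat(sprintf("  chr %s: %d states x %d positions\n", chr,
                dim(object@probs[[chr]])[2L], dim(object@probs[[chr]])[3L]))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s, %s model, %d df): %d positions x %d phenotypes; max LOD %.2f\n",
              object@method, object@model, object@df, nrow(object@lod),
              ncol(object@lod), max(object@lod)))
})

setMethod("show", "ScanPerm", function(object) {
  cat(sprintf("ScanPerm: %d replicates x %d phenotypes%s\n",
              nrow(object@maxLod), ncol(object@maxLod),
              if (nrow(object@maxLodX)) " (X recorded separately)" else ""))
})

setMethod("show", "EffectEstimates", function(object) {
  cat(sprintf("EffectEstimates (%s): chr %s, %d positions x %d effects\n",
              object@mode, object@chr, nrow(object@coef), ncol(object@coef)))
})

setMethod("show", "ViterbiPath", function(object) {
  cat(sprintf("ViterbiPath: design '%s', %d individuals, %d chromosomes\n",
              object@design, nrow(object@paths[[1L]]), length(object@paths)))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d individuals, %d chromosomes%s\n",
              length(object@mosaics), length(object@map),
              if (length(object@pheno)) ", phenotype decomposition attached" else ""))
})
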