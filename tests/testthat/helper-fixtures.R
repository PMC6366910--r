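# construct a toy cross directly (integer genotype codes: 0 missing, 1 AA,
# 2 AB, 3 BB, 4 notAA, 5 notBB; founder alleles 0 missing, 1 A, 2 B)
makeToyCross <- function(design, geno, posCm, founderAlleles = NULL,
                         chr = "1", sex = NULL, generation = NULL) {
  d <- crossDesign(design)
  n <- nrow(geno)
  ids <- sprintf("i%02d", seq_len(n))
  mar <- sprintf("m%02d", seq_along(posCm))
  dimnames(geno) <- list(ids, mar)
  map <- list(stats::setNames(posCm, mar))
  names(map) <- chr
  fg <- list(NULL)
  names(fg) <- chr
  if (!is.null(founderAlleles)) {
    colnames(founderAlleles) <- mar
    fg[[chr]] <- founderAlleles
  }
  g <- list(geno)
  names(g) <- chr
  new("MppCross", design = d, geno = g, founderGeno = fg, map = map,
      pmap = list(),
      pheno = matrix(numeric(0), n, 0L, dimnames = list(ids, NULL)),
      covar = data.frame(row.names = ids),
      sex = if (is.null(sex)) rep("f", n) else sex,
      generation = if (d@needsGeneration) {
        if (is.null(generation)) rep(5L, n) else rep(as.integer(generation), n)
      } else integer(0),
      ids = ids)
}

# wrap a list of n x S x P arrays as a GenotypeProb (for synthetic inputs)
makeProbObject <- function(arrs, posLists, design = "do_hs8",
                           alleleProb = TRUE, sex = NULL) {
  for (chr in names(arrs)) {
    if (is.null(dimnames(arrs[[chr]])[[1L]]))
      dimnames(arrs[[chr]])[[1L]] <- sprintf("i%03d", seq_len(dim(arrs[[chr]])[1L]))
    if (is.null(dimnames(arrs[[chr]])[[3L]]))
      dimnames(arrs[[chr]])[[3L]] <- names(posLists[[chr]])
  }
  new("GenotypeProb", probs = arrs, map = posLists, design = design,
      alleleProb = alleleProb,
      sex = if (is.null(sex)) rep("f", dim(arrs[[1L]])[1L]) else sex,
      errorProb = 1e-4, mapFunction = "haldane")
}

# shared medium-sized DO fixture, built once per test run
.fixtureEnv <- new.env(parent = emptyenv())
doFixture <- function() {
  if (is.null(.fixtureEnv$do)) {
    sim <- simulateCross("do_hs8", nInd = 150, nChr = 2, chrLength = 50,
                         markerSpacing = 2, errorProb = 0.002, seed = 777)
    pr <- calcGenoprob(sim$cross, errorProb = 0.002)
    ap <- genoprobToAlleleprob(pr)
    .fixtureEnv$do <- list(sim = sim, pr = pr, ap = ap)
  }
  .fixtureEnv$do
}
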