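# mppqtl

QTL mapping for classical two-way crosses and multiparent populations
(MPPs) in R.  In an experimental cross each genome is a mosaic of segments
inherited from a small set of founder strains; `mppqtl` reconstructs those
mosaics from incompletely informative SNP genotypes with a hidden Markov
model, then scans the genome for quantitative trait loci by Haley-Knott
regression or a linear mixed model, with permutation-based significance
thresholds, founder-effect BLUPs, founder-SNP imputation/association, and
genotype diagnostics.  A bundled simulator generates complete input
bundles with known truth, so every component is testable end to end
without external data.

## The model in brief

* **Haplotype reconstruction.** The latent state at a locus is the
  diplotype -- the unordered pair of founder haplotypes (36 states for an
  8-founder Diversity Outbred autosome, 44 on the combined-sex X).  The
  HMM's initial, transition ("step"), and emission laws are
  design-specific: e.g. 2-way RILs by selfing have off-diagonal step
  probability `2r/(1+2r)`, sib-mated RILs `4r/(1+6r)`, and DO/HS
  transitions follow a generation-dependent recurrence
  `q_s(r) = 1/8 + ((1-r)^3 - 1/8)(1-r)^(s-1)`.  Emissions allow genotyping
  error `eps` split evenly across the other genotype codes.  Posteriors
  come from scaled forward-backward; joint reconstructions from Viterbi.
* **Genome scans.** At every position,
  `LOD = (n/2) log10(RSS0/RSS1)` from a regression of phenotype on the
  state (35 df full model), founder-dosage (7 df additive), or imputed-SNP
  (1-2 df) probability columns.  A residual polygenic effect with
  leave-one-chromosome-out (LOCO) kinship
  `K[i,j] = mean_t sum_f p_ift p_jft` handles population structure via the
  eigendecomposition trick; heritability is profiled by REML at the null.
* **Inference.** Significance comes from permuting the haplotype
  probability rows against the (phenotype, covariate, kinship) tuples,
  with length-apportioned autosome/X thresholds; founder effects are
  reported either as fixed estimates or as BLUPs shrunk toward zero.

Supported designs: backcross, F2 intercross, doubled haploids, 2-/4-/8-/16-way
RILs by selfing, 2-/4-/8-way RILs by sib mating, and 8-founder DO/HS;
other populations can enter through the documented custom-probability
text format (`importGenoprob()`).

## Worked example

Simulate a 300-mouse DO-style population (generation 5, genotyping error
0.2%) with a 12%-variance QTL at 24 cM on chromosome 2 whose
non-reference allele is carried by founders A, B, C and E (SDP mask 23),
plus a 15% polygenic background; then reconstruct, scan, and test.

```r
library(mppqtl)

sim <- simulateCross("do_hs8", nInd = 300, nChr = 4, chrLength = 60,
                     markerSpacing = 1, errorProb = 0.002, seed = 41)
ph  <- simulatePhenotype(sim$cross, sim$truth,
                         qtl = list(list(chr = "2", pos = 24, sdp = 23L,
                                         varExplained = 0.12)),
                         h2 = 0.15, seed = 42)

pr <- calcGenoprob(sim$cross, errorProb = 0.002)
pr
#> GenotypeProb (genotype states): design 'do_hs8', 300 individuals, 4 chromosomes
#>   chr 1: 36 states x 61 positions
#>   ...

ap   <- genoprobToAlleleprob(pr)      # founder dosages (additive model)
K    <- calcKinship(ap, "loco")       # LOCO kinship matrices
scan <- scanQtl(ap, ph$pheno, kinship = K)
scan
#> ScanResult (lmm, additive model, 7 df): 244 positions x 1 phenotypes; max LOD 13.62

perm <- scanPerm(ap, ph$pheno, nPerm = 100, xSeparate = FALSE, seed = 43)
thr  <- permThreshold(perm, 0.05)$autosome[1, 1]   # 5.67
findPeaks(scan, threshold = thr)
#>        pheno chr pos      lod ci_lo ci_hi
#> c2m026 pheno   2  25 13.62119    23    27
```

The peak lands at 25 cM on chromosome 2 -- within 1 cM of the true locus --
with LOD 13.6 against a 5% genome-wide permutation threshold of 5.7, and
a 1.5-LOD support interval of 23-27 cM.  The BLUP founder effects at the
peak separate the simulated carrier strains (A, B, C, E positive) from the
non-carriers:

```r
blup <- scanBlup(ap, ph$pheno, chr = "2")
round(blup@coef[which.min(abs(blup@pos - 24)), 1:8], 3)
#>      A      B      C      D      E      F      G      H
#>  0.623  0.750  0.563 -0.687  0.254 -0.101 -0.830 -0.571
```

SNP association on imputed founder SNPs (`indexSnps()`, `scanSnps()`,
`topSnps()`) and genotype diagnostics (`calcErrorLod()`,
`countCrossovers()`, `validateCross()`) follow the same pattern; see the
methods vignette (`vignettes/mppqtl-methods.Rmd`) for the models,
assumptions, and numerical choices.

## Acceptance script

`scripts/acceptance.R` recomputes the package's structural acceptance
targets from scratch against the installed package -- it enumerates the
DO/HS genotype state spaces (autosome, and combined-sex X) and verifies
them against a freshly computed probability array before reporting:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON output maps each target id to its recomputed value and the
problem size used.
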