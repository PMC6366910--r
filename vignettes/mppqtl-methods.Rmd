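---
title: "Models and methods in mppqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mppqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mppqtl)
```

# The problem

In an experimental cross -- a backcross, an F2 intercross, a recombinant
inbred panel, or a multiparent population such as Diversity Outbred (DO)
mice -- each individual's genome is a mosaic of segments inherited from a
small set of known founder strains.  Quantitative trait locus (QTL) mapping
proceeds in two steps: reconstruct the founder mosaic from incompletely
informative SNP genotypes, then regress phenotypes on the reconstruction,
position by position, while accounting for genetic relatedness.  `mppqtl`
implements both steps, together with permutation-based significance,
founder-effect estimation, SNP imputation/association, diagnostics, and a
simulator that generates full input bundles with known truth.

# Hidden Markov model

For each chromosome and individual, the latent state at a position is the
*diplotype*: the unordered pair of founder haplotypes (36 states for 8
founders; single founder labels for inbred-line designs; 8 hemizygous
states for the male DO X, giving the 44-column combined-sex X array).
The chain is assumed Markov along the chromosome, with:

* **Initial distribution.**  Uniform over lines for inbred designs,
  Mendelian for backcross/F2, and Hardy-Weinberg over equally frequent
  founder haplotypes for DO/HS (heterozygotes 2/64, homozygotes 1/64).
* **Transition matrices.**  Design-specific functions of the recombination
  fraction *r* across each interval.  Distances in cM are converted to *r*
  by the Haldane map function by default (Kosambi is available); Haldane
  matches the chain's no-interference assumption, and the simulator uses
  the same model so that oracle comparisons are exact.
* **Emissions.**  The observed SNP codes are AA/AB/BB plus the partial
  codes notAA/notBB and missing.  A state implies a genotype through the
  founder SNP alleles; the call is observed correctly with probability
  `1 - errorProb` and errors are split evenly between the two other full
  codes.  Missing observations emit probability 1; a missing founder
  allele is marginalized with probability 1/2 per allele, with the two
  chromosomes of a founder-homozygous state sharing a single (inbred)
  allele draw.  The default `errorProb = 1e-4` reflects common array
  genotyping error rates; simulations in the test suite use `2e-3`.

Posteriors come from the scaled forward-backward algorithm (per-position
rescaling, so 10^4-marker chromosomes cannot underflow); joint
reconstructions from Viterbi with ties broken toward the lower state index.
Pseudomarkers (positions without data) emit 1 everywhere.

## Transition models

* Backcross / doubled haploids: the single segregating gamete switches
  with probability *r*.
* F2 and DO/HS: the two haplotypes are treated as independent chains and
  collapsed to unordered pairs.
* RILs at fixation: the probability that adjacent loci carry the same
  founder is `1/(1+2r)` (2-way selfing) and `(1+2r)/(1+6r)` (2-way sib
  mating), with each additional funnel generation in multi-way panels
  contributing one factor of `(1-r)`: `(1-r)^(k-1)/(1+2r)` for 2^k-way
  selfing and `(1-r)^(k-2)/(1+6r)` for 2^k-way sib mating.  These forms
  are validated in the tests against exact two-locus breeding chains
  (2-way) and against Monte-Carlo simulation of the breeding schemes
  (multi-way).
* DO/HS: the package models an idealized scheme -- an 8-way funnel taking
  three generations, followed by `s` generations of random outbreeding in
  a large population.  The same-founder probability of a haplotype across
  an interval is then

  `q_s(r) = 1/8 + ((1-r)^3 - 1/8) (1-r)^(s-1)`,

  with the remaining mass spread evenly over the other founders.  This is
  the exact two-locus law of the scheme the bundled simulator executes, so
  transition matrices and simulations agree by construction; it does not
  attempt to reproduce the pre-Collaborative-Cross generation mixture of
  the real DO founders.  Different individuals may carry different
  generations; each group gets its own matrices.
* X chromosome (DO only): recombination happens only in females, so the
  female map is contracted by the factor 2/3; males carry a single
  haplotype.  The simulator applies the same convention.

Designs not covered natively (e.g. 19-way MAGIC) are supported through the
custom probability import path (`importGenoprob()`), which accepts any
state labels.

# Genome scans

Haley-Knott regression fits, at every position, the phenotype on the state
(or founder-dosage) probability columns plus covariates;
`LOD = (n/2) log10(RSS0/RSS1)` against the covariates-only null.  Because
probability columns sum to 1 the intercept is dropped from the alternative
-- effects are per-state means, the parameterization in which one effect is
plotted per founder.  The full (36-state) model has 35 df for the DO, the
additive dosage model 7, and imputed-SNP models 1 (additive) or 2
(general).

The mixed model adds a polygenic random effect with covariance
proportional to a kinship matrix: `K[i,j]` is the average probability that
haplotypes drawn from individuals i and j carry the same founder,
optionally leave-one-chromosome-out (LOCO).  The null heritability is
estimated once per chromosome by REML after rotating by K's
eigendecomposition, then held fixed across positions (re-estimating at
every position changes LODs negligibly at much higher cost); the scan is
ordinary Haley-Knott in the rotated, variance-weighted space.  With `K = cI`
the mixed-model scan reduces exactly to Haley-Knott, which the tests
assert at 1e-8.

Note on the *h2* scale: with the probability-cross-product definition, DO
self-kinship averages about 0.56 rather than 1, so the raw variance ratio
is not directly the phenotypic polygenic fraction.  Analyses that interpret
*h2* on the phenotypic scale should rescale, e.g. `K / mean(diag(K))`, as
the parameter-recovery tests do.  Even then the estimates carry a mild
downward bias (a few hundredths) because the baseline founder-sharing
common to all pairs is absorbed by the intercept.

## Effect estimates and BLUPs

`scanCoef()` returns per-position least-squares state effects and standard
errors (minimum-norm pseudo-inverse when columns are collinear).
`scanBlup()` instead treats the founder effects as i.i.d. random effects,
estimates the variance ratio per position by REML (Woodbury identities on
the founder-column SVD keep this O(n) per evaluation), and returns
posterior means: estimates shrunk toward zero, exactly zero when the
estimated effect variance is zero, and converging to the centered fixed
estimates as the variance ratio grows.

## Permutations and thresholds

Each permutation replicate applies one shared permutation to the rows of
the genome-wide probability arrays, leaving phenotype, covariates, and
kinship rows aligned with each other, and records the genome-wide maximum
LOD.  Internally the package permutes the phenotype side by the inverse
permutation, which is algebraically identical and avoids copying the
arrays; under the mixed model the kinship is permuted symmetrically with
the phenotype, and the null variance components are re-estimated per
replicate.  Thresholds are empirical quantiles; when the X is scanned, the
autosome and X use the length-apportioned significance levels
`1-(1-a)^(L_A/L_G)` and `1-(1-a)^(L_X/L_G)` (lengths in cM), which recover
`a` itself when either part vanishes.  X scans add sex to both null and
alternative models whenever both sexes are present, so sex differences in
the phenotype cannot masquerade as X linkage.

In the end-to-end recovery tests the genome-wide threshold is computed
from Haley-Knott permutations even when the reported scan is the mixed
model: rotating every permuted design would multiply the cost ~60-fold,
and in these simulated populations the two thresholds are close.  This is
a documented approximation of the test harness, not of `scanPerm()` itself,
which supports kinship.

# SNP imputation and association

Founder SNPs are encoded as strain-distribution patterns (SDPs): bit i set
when founder i carries the non-reference allele.  SNPs falling in the same
inter-position interval with the same SDP get identical imputed
probabilities, so only one representative per (interval, SDP) class is
scanned and results are expanded back to members -- the tests verify this
equals scanning every SNP individually.  Haplotype probabilities are
interpolated linearly in cM to the SNP position (linear interpolation is
the simplest monotone choice and its error vanishes with dense grids),
then collapsed by the SDP
into allele-dosage (additive) or genotype-category (general) columns.

# Diagnostics

The genotyping-error LOD of an observed call is the log10 likelihood ratio
of "this call is an error" versus "this call is correct" under the state
posterior computed from all *other* markers (the forward-backward pass
with the marker's own emission removed).  The exact formula is this
package's fixed choice; the error channel is the same "split evenly over
the other two codes" model as the HMM emission, without the epsilon prior
odds, so scores are positive exactly when the flanking information argues
against the call.  Crossover counts weight each adjacent state change by
its minimum number of strand exchanges (shared-founder diplotype changes
count 1, homozygote-to-homozygote switches 2; inbred-line and backcross
designs count 1 per change, as only one strand segregates).

# The simulator as a stated world

`simulateCross()` executes the actual breeding schemes: one generation for
backcross/F2, doubled F1 gametes, funnels plus up to 20 generations of
selfing/sib mating for RILs (residual heterozygosity is reported, not
forced away), and per-lineage random funnels into a G3 pool followed by
random mating for DO/HS (population size `max(2 nInd, 64)` by default, so
realistic sibling/cousin relatedness arises).  Meioses are Poisson with no
interference, matching the HMM.  Phenotypes decompose into QTL terms from
the true founder dosages, a polygenic draw from the realized mosaic
kinship, and Gaussian noise, each scaled to its requested variance
fraction (fractions are exact in sample variance up to cross-component
covariance).  Defaults mirror the DO application: generation 5 (published DO mapping populations typically span
outbreeding generations three to five), genotyping error
2e-3, founder SNP alleles i.i.d. equally frequent.

What a green test does and does not establish: the generator shares the
HMM's Markov/no-interference model, so agreement between the two validates
the implementation, not the biological realism of Haldane's model; real
genotyping arrays also have informative-marker selection, linkage-disequilibrium
structure among founders, and non-random missingness that the generator
does not emulate.  Mosaic reconstruction accuracy depends on the
outbreeding generation: with markers every 0.5 cM and error 2e-3, the
maximal-marginal diplotype reconstruction matches the simulated truth at
about 95% of positions at generation 3, dropping roughly one point per
additional generation as segments shorten -- breakpoint-adjacent positions
account for almost all mismatches.

# Numerical choices

* Forward/backward vectors are rescaled at every position; no log-space
  arithmetic is needed.
* The h2 profile is maximized by a 0.01-grid pre-search plus Brent
  refinement (tolerance 1e-8) on [0, 1-1e-8], guarding against the rare
  multimodal profile; the tests check agreement with a 1e-4 grid argmax.
* Viterbi ties resolve to the lower state index; `which.max`/`max.col`
  with "first" make this deterministic.
* Collinear design columns fall back to the minimum-norm pseudo-inverse.
* Probability exports print 17 significant digits, so text round trips are
  bit-exact; imports reject arrays whose slices miss sum 1 by more than
  1e-6.
* Chromosomes and individuals are independent HMM work units; results are
  identical regardless of evaluation order.

# Known limitations

* The DO/HS transition law is the idealized funnel-plus-outbreeding
  recurrence above, not the pre-CC mixture of the real DO founders.
* Native X support is limited to the DO design; other designs analyze
  autosomes (classical two-way X handling is a planned extension).
* Interval mapping, multiple imputation, multiple-QTL models, and
  genotyping-by-sequencing allele-count emissions are out of scope.
* Residual heterozygosity in partially inbred RILs is reported by the
  simulator but ignored by the reconstruction (inbred-line state spaces).
* The control-file reader accepts JSON (not YAML) control files.
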