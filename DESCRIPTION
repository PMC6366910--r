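Package: mppqtl
Title: QTL Mapping in Multiparent and Classical Experimental Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hidden Markov model reconstruction of founder-haplotype mosaics
    in classical two-way crosses and multiparent populations (recombinant
    inbred panels, Diversity Outbred / heterogeneous stock), genome scans by
    Haley-Knott regression and by a linear mixed model with leave-one-
    chromosome-out kinship, permutation-based genome-wide significance
    thresholds with separate autosome and X handling, fixed-effect and BLUP
    estimates of founder allele effects, founder-SNP imputation and
    association scans, genotyping diagnostics, and a cross simulator that
    generates complete input bundles with known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'designs.R'
    'hmm.R'
    'kinship.R'
    'lmm.R'
    'scan.R'
    'coef.R'
    'diagnostics.R'
    'io.R'
    'methods.R'
    'mppqtl-package.R'
    'perm.R'
    'simulate.R'
    'snps.R'
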