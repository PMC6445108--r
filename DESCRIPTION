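Package: sumraa
Title: Region-Based Association Tests from Individual-Level Data or GWAS
    Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-based association analysis of a continuous trait with a
    set of genetic variants, carried out either on individual-level
    genotype/phenotype data or on SNP-level GWAS summary statistics
    (Z scores, beta standard errors) together with a SNP-by-SNP correlation
    (LD) matrix.  Implements six method families -- multiple linear
    regression, principal-component regression, functional linear models,
    burden, SKAT and SKAT-O -- in both formulations, built so that the two
    data levels give identical test results when the summary statistics and
    LD are computed from the same genotypes.  Includes weighted chi-square
    mixture tail probabilities, a lasso estimator of variant effects from
    LD and Z scores, a generic combiner for dependent Z scores of any
    level, a genotype/phenotype simulator with tunable LD, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
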