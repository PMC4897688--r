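Package: hetmap
Title: Trans-Ancestry Association-Heterogeneity Mapping for GWAS Summary
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genetic variants whose disease associations differ
    between ancestry groups. Implements fixed-effect inverse-variance
    meta-analysis of per-cohort GWAS summary statistics, decomposition of
    Cochran's Q into within-ancestry and between-ancestry heterogeneity
    components (chi-square with groups minus one degrees of freedom under
    the null), genomic-control calibration of the heterogeneity scan,
    analytic power for the heterogeneity and single-population association
    tests, and the follow-up analyses (allele frequencies, linkage
    disequilibrium from phased haplotypes, Hardy-Weinberg tests,
    conditional logistic association, dosage eQTL regression) that
    localize a population-specific risk allele. Ships synthetic-data
    generators reproducing the statistical structure the pipeline assumes
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    vcfR,
    limma
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
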