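Package: pleiocfdr
Title: Pleiotropy-Informed Conditional False Discovery Rate Analysis of
    GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-trait conditional false discovery rate (cFDR) analysis
    of genome-wide association study summary statistics. Provides
    genomic-control correction estimated from intergenic SNPs, stratified
    conditional Q-Q curves for assessing pleiotropic enrichment,
    two-dimensional conditional FDR lookup tables with bilinear
    interpolation on the -log10 scale, greedy LD clumping of significant
    SNPs into independent loci with novelty classification against a
    reference locus list, nearest-gene annotation, covariate-adjusted
    expression validation of candidate genes, and a seeded synthetic-data
    generator with known truth labels for end-to-end calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
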