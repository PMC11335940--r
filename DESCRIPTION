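Package: hapanchor
Title: Sliding-Window Haplotype Association and Joint-SNP Anchored Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Haplotype-block association testing for phased case-control
    cohorts. Enumerates sliding windows of phased SNPs, derives haplotype
    alleles and recodes them as pseudo-biallelic NN/NH/HH markers, fits
    per-population logistic regression with a sex covariate, combines
    populations whose haplotypes are not identical through a joint-SNP
    anchored DerSimonian-Laird random-effects inverse-variance meta-analysis
    with Cochran's Q and I2 heterogeneity statistics, and reports
    genome-wide-significant risk regions. Includes a mosaic founder-copy
    simulator of phased multi-population case-control panels, SHAPEIT
    haps/sample and PLINK ped/map readers and writers, and BED/forest-plot
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    knitr,
    rmarkdown
Config/testthat/edition: 3
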