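Package: origwas
Title: Subspecies-Origin-Aware Genome-Wide Association Analysis for Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association studies in populations admixed
    between two deeply diverged source subspecies (for example Bos taurus and
    Bos indicus cattle). Phased chromosome segments are classified by
    subspecies origin from reference-panel haplotype frequencies, SNP alleles
    are recoded into four origin-by-allele classes, and three association
    models are fitted under a polygenic mixed model: a conventional allele
    test, an allele-by-origin interaction test, and a best-single-variable
    scan. Includes false discovery rate estimation, QTL segregation-pattern
    classification, and a synthetic-data generator that emulates diverged
    founder pools, recent admixture, and polygenic phenotypes with known
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
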