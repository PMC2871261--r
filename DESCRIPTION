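Package: trioase
Title: Allele-Specific Expression and Imprinting Analysis for Family Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detection of allele-specific expression (ASE) and genomic
    imprinting in family trios assayed on two-channel allelic intensity
    bead arrays. Implements bead-level preprocessing (between-channel
    quantile normalisation, MAD outlier removal, per-array median
    centring), an empirical-Bayes moderated-t ASE test with a
    three-criterion call rule, parent-of-origin classification of
    ASE-positive SNPs into imprinting and related allelic-expression
    modes, a paired allelic-ratio test for mass-spectrometry allelotyping
    data, ROC calibration from genomic-DNA mixture titration series, and
    a synthetic-data generator that emulates the full trio study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
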