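Package: reciprocross
Title: Homoeolog Bias, Genomic Imprinting and Differential Splicing in
    Reciprocal Interploidy Wheat Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcriptomes of grain development in
    reciprocal crosses between tetraploid and hexaploid wheats. Classifies
    homoeolog triads into expression-bias categories by nearest-centroid
    assignment on the within-triad composition simplex and tracks category
    switches between crosses; calls maternally and paternally expressed genes
    (MEGs/PEGs) from allele-specific read counts with parental-dosage-aware
    chi-square testing, Benjamini-Hochberg correction, ratio thresholds and
    reciprocal-direction concordance; computes isoform-level percent
    spliced-in (PSI), group differences in PSI and empirical differential
    splicing significance. A negative-binomial/binomial synthetic-data
    generator with planted ground truth emulates the data structure of such
    a study so every stage is testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
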