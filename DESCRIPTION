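Package: smascreen
Title: Newborn Screening for Spinal Muscular Atrophy from Targeted
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls homozygous SMN1 exon 7 deletions, the variant responsible
    for most spinal muscular atrophy (SMA), from aligned short reads produced
    by a targeted capture panel. Reads co-mapped over the SMN1/SMN2 locus are
    assigned to a paralog using paralog-specific variant (PSV) bases, SMN1
    exon 7 copy support is expressed as a coverage score normalised against
    diploid control genes, and each sample receives a qualitative screen call
    (POSITIVE, NEGATIVE or FAIL) after depth and uniformity quality control.
    Includes an aligned-read simulator with known SMN1/SMN2 copy numbers so
    sensitivity and specificity experiments can be reproduced at desk scale,
    plus batch evaluation against a truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
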