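Package: readthrough
Title: Readthrough Propensity Prediction for Stop-Codon Contexts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts basal translational readthrough (BTR) from the 15-nt
    stop-codon context (SCC) using ridge regression on indicator-encoded
    nucleotide positions, derives high-readthrough consensus motifs by
    stepwise feature elimination, classifies C-terminal peroxisomal
    targeting signals (PTS1) with a regularized least-squares classifier,
    scans transcript sets for readthrough extensions ranked by the product
    of scaled readthrough propensity and PTS1 posterior probability, and
    computes readthrough percentages from dual-reporter plate data with
    first-order error propagation. Ships the published LINiter and LINfs3
    model weights plus synthetic-data generators with planted structure so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
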