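Package: pluriexit
Title: Hit Calling, Chromatin Binding Association and Image Quantification
    for an Exit-from-Pluripotency RNAi Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementation of the analysis pipeline behind a
    genome-scale siRNA screen for genes required to exit naive pluripotency and
    the accompanying chromatin and imaging analyses. Covers per-plate
    percent-of-control normalization and dual-replicate Z-score hit calling
    with its analytic false-positive bound, the hit exclusion ledger and
    multi-siRNA validation rule; ChIP-seq downstream steps (PCR-duplicate
    removal, equal-depth subsampling, IgG fold-enrichment peak filtering,
    per-peak read densities, binary bin matrices over gene windows, an
    exponential distance-decay TSS association score, Pearson-correlation
    hierarchical clustering, nearest-factor distances and rank-based
    enrichment); and per-cell nuclear/cytoplasmic ratio quantification from
    multi-channel images. Synthetic-data generators with known ground truth
    make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
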