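Package: centrofish
Title: Quantifying Pericentrosomal RNA and Protein Localization from
    smFISH Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring where an mRNA and its encoded protein sit
    relative to the mitotic centrosome in single-molecule RNA FISH (smFISH)
    images.  Provides a ground-truthed synthetic microscopy-scene generator
    for metaphase cells (two centrosomes defining a spindle axis, an
    astral-biased pericentrosomal RNA ring, a spindle-side protein signal,
    Poisson shot noise and Gaussian read noise), centrosome and
    diffraction-limited spot detection, disk-ROI enrichment with in-cell
    background subtraction, a signed spindle-to-astral line-profile
    peak-position statistic, washout time-course recovery-onset testing,
    and smiFISH probe tiling under length and GC constraints.  All
    user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
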