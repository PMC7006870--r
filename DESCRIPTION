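Package: langcore
Title: Core Language Network Analysis for Task fMRI Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for reconstructing the core language
    network from task-based fMRI BOLD time series. Builds per-subject
    voxel-level functional networks by thresholding pairwise Pearson
    correlations among task-activated voxels, aggregates them into weighted
    functional-region-of-interest (fROI) networks, extracts the cross-subject
    common network of persistent areas and links, analyses k-core/k-shell
    occupancy against a label-permutation null, and computes normalized
    rich-club curves with degree-preserving rewiring nulls. Ships a synthetic
    block-design cohort generator with planted ground truth so the whole
    pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
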