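Package: cellmil
Title: Multiple-Instance Learning of Single-Cell Gene Expression from Spot-Level Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns an instance-level regressor that predicts single-cell gene
    expression scores from per-cell image embeddings, using only spot-level
    Visium-style transcript counts as (weak) supervision. Each spot is treated
    as a bag of cells; a feed-forward network scores every cell and the mean
    over the bag is matched to the measured spot profile under either a mean
    squared error loss on log-normalized data or a negative binomial count
    likelihood with gene-wise learned dispersion. Includes spot/gene quality
    filters, highly and spatially variable gene selection, cell-to-spot bag
    construction, a fully synthetic simulation framework (random, centroid and
    cell scenarios), evaluation metrics with bootstrap confidence intervals,
    and marker-gene cell scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr
Config/testthat/edition: 3
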