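Package: homoeoscan
Title: Detection and Visualization of Homoeologous Genome Exchanges in
    Allopolyploid Crops from mRNAseq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects homoeologous exchanges (HEs), duplications, deletions
    and aneuploidies in allopolyploid crops from replicated mRNAseq (or
    low-pass DNA coverage) data. Homoeologous gene pairs and triplets are
    built by reciprocal-best-hit pairing of subgenome CDS alignments,
    transcript abundance is normalized as RPKM, each homoeologue set is
    classified per accession into nine genome-dosage categories by
    replicate t-tests against the panel mean, contiguous exchange blocks
    are segmented and their panel-wide frequency summarized, and relative
    subgenome abundance is rendered as Transcriptome Display Tile Plots
    in CMYK colour space. A seeded simulator generates complete synthetic
    panels with planted events for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    grDevices,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
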