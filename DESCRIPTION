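Package: fragcnv
Title: Fetal Copy-Number Detection from Read Counts and cfDNA Fragment Sizes
Version: 0.1.0
Authors@R:
    person("fragcnv", "maintainers", email = "fragcnv@example.org", role = c("aut", "cre"))
Description: Within-sample normalization pipeline for detecting fetal copy-number
    variants from shallow paired-end whole-genome sequencing of maternal plasma.
    Paired alignments are reduced to fragment midpoints and sizes, aggregated on a
    fixed genomic bin grid, and scored against a two-datatype reference (read counts
    and per-bin mean fragment sizes) built from negative-control samples. Technical
    bias is removed with per-datatype principal-component models, each bin is judged
    against its most similar bins on other chromosomes of the same sample, the two
    Z-score tracks are combined (Fisher or Stouffer), and events are called with
    circular binary segmentation. A bin-level cohort simulator with a maternal/fetal
    fragment-size mixture and known copy-number truth supports testing without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
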