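Package: nanotax
Title: Full-Length 16S rRNA Long-Read Profiling and Cross-Platform
    Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Taxonomy-supervised profiling of microbial communities from
    noisy long-read full-length 16S rRNA amplicons, alongside a short-read
    (V3-V4) OTU-based arm and the statistics to compare the two platforms:
    best-hit classification with affine-gap local alignment, spike-in
    error-rate estimation, greedy 97 percent OTU clustering with
    rarefaction, detection-group and rank-correlation concordance, and
    hypervariable-region variant analysis. Ships a synthetic-data
    generator (reference databases with V1-V9 structure, in-silico PCR,
    per-aligned-column long-read error simulation, paired short reads) so
    every stage runs against sequences with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
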