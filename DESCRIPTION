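Package: avimark
Title: Avian Microbial Source Tracking Marker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discovering and evaluating host-associated fecal
    16S rRNA gene markers for microbial source tracking (MST), with a focus
    on avian hosts. Builds a host-annotated fecal 16S reference database
    from GenBank flat files, selects sample-group-exclusive OTUs from
    grouped amplicon read sets, locates host-unique subsequences by k-mer
    seeded local alignment search, greedy identity clustering,
    query-anchored alignment and sliding-window difference scanning, and
    evaluates the resulting qPCR assays (standard curves, amplification
    efficiency, limit of detection, sensitivity and specificity, and
    marker quantity profiles). Includes seeded synthetic-data generators
    that emulate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
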