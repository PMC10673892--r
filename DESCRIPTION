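Package: miaminer
Title: Candidate Gene Discovery for Monoterpene Indole Alkaloid Biosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating biosynthetic gene candidates in plant
    specialized metabolism from a multi-tissue expression atlas. Builds joint
    gene-metabolite co-expression networks ranked by highest reciprocal rank
    (HRR), trains a feed-forward neural classifier separating pathway-like
    from conserved housekeeping expression profiles, scans genome annotations
    for physically co-localized clusters of pathway-associated protein
    domains around ortholog anchors, filters latex proteome proteins by
    oxidoreductase annotation, and intersects the four evidence routes into a
    prioritized candidate shortlist. Includes a seeded synthetic-study
    generator that plants recoverable co-expression modules, gene clusters
    and decoys for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
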