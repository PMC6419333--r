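Package: otushift
Title: Differential-Abundance Shift Vectors for Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-condition differential-abundance ("shift") vectors
    from OTU count tables and numeric sample metadata using a univariate
    negative-binomial GLM with likelihood-ratio testing, assembles them into
    per-rank shift matrices, and compares shifts between conditions, against
    user queries, against microbial trait annotations, and against alpha
    diversity. Includes TMM normalization, taxonomy collapsing over
    Greengenes-style lineages, the ACE richness estimator, Mantel permutation
    tests, a within-taxon coherence check against a permuted-table null, and
    a fully specified synthetic cohort generator with planted effects so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
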