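Package: prairienet
Title: Bee Community Diversity and Bee-Plant Co-Occurrence Networks for
    In-Field Prairie Strips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for assessing how strips of reconstructed
    native prairie vegetation sown within row-crop fields affect wild bee
    communities.  Provides Hill-number diversity with sample-size-based
    rarefaction/extrapolation and bootstrap intervals, Bray-Curtis
    community comparison via the multi-response permutation procedure
    (MRPP) and PCoA-based multivariate dispersion, Shannon landscape
    diversity with a non-crop transform, and a correlation-based bee-plant
    co-occurrence network (pairwise Pearson screening with
    Benjamini-Hochberg control, validation against observed visitation,
    family-level proportion tables, native/exotic affinity ratios, and
    monthly bipartite edge lists).  A synthetic community generator with
    known ground truth makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
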