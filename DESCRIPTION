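Package: flywalkr
Title: Quantification of Odor-Guided Walking Behavior in Circular Arenas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how walking flies change their locomotion
    when an odor fills a central zone of a circular arena. Includes an
    agent-based simulator of run/stop walking with ground-truth labels, a
    centroid tracker for single-fly videos, Schmidt-trigger run/stop
    segmentation with smooth/sharp turn classification, extraction of a
    17-parameter motor description per fly, and group-level statistics:
    rank-sum panels with Bonferroni correction, a pairwise correlation
    screen, principal component analysis, and canonical variate analysis
    with a label-shuffle permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    rlang,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
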