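Package: vertvar
Title: Vertebral Formula Variation and Phylogenetic Comparative Analysis in Newts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing meristic variation in the vertebral column of
    Triturus newts and similar salamanders. Scores specimens for homeotic
    transformations including transitional thoraco-sacral vertebrae (half
    scores), summarises per-species thoracic-count distributions into the
    modal count (T_n), the percentage of non-modal individuals (T_var), the
    count range (T_range) and the transitional-sacrum prevalence (S_tr),
    and compares species with tie-corrected Spearman rank correlations and
    G-tests of independence. Phylogenetic structure is handled with
    Felsenstein independent contrasts, through-origin contrast regression,
    squared-change parsimony and a tip-permutation phylogenetic signal test.
    A seeded synthetic-data module generates record sets and Brownian-motion
    trait vectors with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
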