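Package: ventbeta
Title: Incidence-Based Beta-Diversity Partitioning and Null-Model
    Inference for Insular Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing site-by-species presence/absence
    matrices from insular habitat systems such as deep-sea hydrothermal
    vents. Implements the pairwise decomposition of Jaccard
    beta-diversity into overlap, replacement and richness-difference
    components together with relativized nestedness and its
    intersection/complement partition, Raup-Crick null-model
    dissimilarities with frequency-weighted fixed-richness
    randomization, local contributions to beta diversity (LCBD) with
    permutation tests, Chao1 and individual-based rarefaction richness
    estimation, permutation ANOVA and t-tests for comparing groups of
    pairwise values, exact minimum-set site coverage, UPGMA site
    clustering with Newick export, and a synthetic community generator
    with controlled nested, turnover and random assembly structure for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr
Config/testthat/edition: 3
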