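Package: lineacom
Title: Lineage-Specific Phylogenetic Community Structure
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decomposing the phylogenetic structure of ecological
    communities lineage by lineage. Computes a pairwise species co-occurrence
    index and its permutation test against phylogenetic distance, the net
    relatedness index (NRI, the negative standardized effect size of mean
    pairwise phylogenetic distance) evaluated separately at every internal
    node of a dated phylogeny with a richness- and prevalence-preserving null
    model restricted to each clade's species pool, and per-node regressions of
    NRI against elevation and node age. Includes a synthetic-data module
    (Yule trees, Brownian elevation-optimum traits, community assembly under
    environmental filtering, limiting similarity, or neutrality) so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
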