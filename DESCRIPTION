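Package: shrubphylo
Title: Community Phylogenetic Structure of Dryland Shrub Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for community phylogenetics of shrub
    communities in arid and semiarid regions: maximum-likelihood
    estimation of Pagel's lambda phylogenetic signal for continuous
    traits, abundance-weighted mean pairwise phylogenetic distance and
    the net relatedness index (NRI) against a richness- and
    abundance-preserving randomization null, Faith's phylogenetic
    diversity, climate-based habitat grouping by PCA and UPGMA
    clustering, and association of NRI with current climate and
    paleoclimate anomalies (Spearman, Wilcoxon, partial least squares).
    Includes a synthetic-data generator that emulates the statistical
    structure of dryland shrub survey data (birth-death phylogenies,
    Brownian-motion traits with tunable lambda, neutral / habitat
    filtering / limiting-similarity community assembly, and correlated
    bioclimatic covariates with latent habitat groups) so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
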