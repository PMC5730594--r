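Package: fdextinct
Title: Functional Redundancy and Sensitivity of Assemblages Under
    Species-Extinction Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dendrogram-based functional diversity analysis for ecological
    assemblages described by mixed categorical and ordered traits. Builds a
    functional dendrogram from Gower dissimilarities by UPGMA clustering,
    measures functional richness as total branch length, simulates
    directional and random species-extinction trajectories, and quantifies
    functional sensitivity by the area under the loss curve (AUC) and
    standardized effect sizes against 999-replicate random nulls. Includes a
    synthetic assemblage generator emulating fish communities of lakes,
    rivers and estuaries, saturation regression of functional on taxonomic
    richness, and non-parametric group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
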