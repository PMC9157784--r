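Package: plantsurv
Title: Adaptive Survey Design and Incidence-Based Richness Estimation for
    Early Detection of Aquatic Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and evaluating probabilistic
    boat-based surveys for early detection of rare and invasive aquatic
    plants in large coastal areas. Provides incidence-matrix data
    structures and readers, Chao2 species-richness estimation (classic and
    bias-corrected, with the ICE heterogeneity rule for choosing between
    them), sample-based rarefaction with confidence intervals, projection
    of the additional sampling effort needed to detect a target fraction
    of the estimated species pool, simplified Morisita (Morisita-Horn)
    design similarity, spatially balanced (GRTS) sample selection over
    gridded sample frames with zone- and richness-percentile inclusion
    weights, inverse-distance and ordinary-kriging richness surfaces,
    forest-based regression of richness on habitat variables with
    Gini-importance screening, and a synthetic coastal-landscape and
    rake-toss survey simulator for desk-scale evaluation of whole designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
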