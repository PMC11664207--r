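Package: antniche
Title: Abundance-Weighted Isotopic Niche and Community Change Metrics for
    Canopy Ant Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing trophic and community change in canopy ant
    assemblages sampled by plot-based canopy fogging across a land-use
    gradient. Provides leaf-calibrated, abundance-weighted stable-isotope
    niche metrics (Average, Maximum, Minimum and Range of d13C and d15N
    relative to a per-plot leaf baseline), per-plot community metrics
    (density, richness, inverse-occupancy rarity), incidence-based Chao2
    species-pool estimation, rank-abundance and sample-based rarefaction
    curves, land-use overlap and nestedness partitions, and fixed-effects
    Gaussian and negative-binomial land-use contrasts with AICc model
    simplification. A hierarchical synthetic-data generator emulating the
    nested plot/subplot/trap sampling design makes the full pipeline
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
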