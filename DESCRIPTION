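Package: cardioTPC
Title: Cardiac Thermal Performance Curves and Phylogenetic Trait Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns raw cardiac (heartbeat) sensor traces recorded during
    controlled heating ramps into per-individual thermal performance traits:
    the Sharpe-Schoolfield activation energy (slope gradient), the upslope
    quadratic curvature, maximum heart rate (HRmax), the optimal temperature
    (Topt) and the upper lethal temperature (ULT) called from heartbeat
    flatlining.  Species-mean traits are compared across habitats with
    phylogenetic generalized least squares under star, Brownian and Pagel
    lambda covariance models ranked by AICc weights; within-habitat species
    contrasts use Gaussian linear models with likelihood-ratio tests and
    Tukey HSD; trait variability is summarised as coefficients of variation
    computed on the Kelvin scale for temperature traits.  A synthetic-data
    module simulates diurnal shore temperature regimes, ramped heartbeat
    traces and phylogenies with Brownian trait evolution, all with known
    ground truth, so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
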