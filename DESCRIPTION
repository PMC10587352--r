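Package: mycodd
Title: Mycorrhizal Mediation of Density Dependence in Forest Census Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial analysis of conspecific density dependence (CDD) and
    conmycorrhizal density dependence (CMDD) in stem-mapped forest census
    plots. Provides census normalisation and size-class delineation,
    arbuscular/ectomycorrhizal (AM/EM) trait assignment with genus-level
    fallback, Clark 2Dt distance-weighted neighbourhood adult densities,
    Ricker-form negative-binomial recruitment models (per species-by-site
    and a global integrated model with species-by-site random intercepts
    and slopes), per-capita sapling-density effect estimation over an
    optimised adult-density window, mycorrhizal-type hypothesis tests, a
    dispersal-kernel null model, and a synthetic forest-plot generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mgcv,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
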