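# mycodd

Spatial analysis of **conspecific density dependence (CDD)** and
**conmycorrhizal density dependence (CMDD)** in stem-mapped forest
census plots, for forest and community ecologists working with
large-plot census data (or synthetic stand simulations).

The Janzen–Connell mechanism predicts fewer recruits per adult where
conspecific adults are dense (negative CDD); mycorrhizal mutualists may
counteract it, and differently for the two major guilds — arbuscular
mycorrhizal (AM) and ectomycorrhizal (EM) trees. `mycodd` implements
the full estimation pipeline for testing whether EM species experience
weaker negative CDD than AM species, and whether species benefit from
heterospecific neighbours of their own mycorrhizal type (positive
CMDD).

## The model

The unit of replication is the 20 × 20 m quadrat. For each species and
quadrat, sapling counts *S* are modelled by a Ricker-form negative
binomial regression with log link and offset log *A*:

    S = A · exp(r + c·A + d·H)            (CDD form)
    S = A · exp(r + c·A + d·M + f·HMH)    (CMDD form)

where *A*, *H*, *M*, *HMH* are distance-weighted adult densities —
conspecific, all-heterospecific, conmycorrhizal-heterospecific and
heteromycorrhizal-heterospecific (*H* = *M* + *HMH*). Adults in the
focal quadrat get weight 1; adults outside are down-weighted by a
Clark 2Dt dispersal kernel, `w(d) = (1 + d²/u)^-(p+1)`, of their
distance to the quadrat edge.

Models are fitted per species-by-site, and jointly as a **global
integrated model** with mycorrhizal-type-specific fixed effects and
species-by-site random intercepts and conspecific slopes (mgcv, NB
family, REML variance components). Effects are summarised as the
change in log per-capita sapling density for a standard +1-adult
increment over a data-supported density window, relative to the same
increment of heterospecific adults — which reduces to `c − d` (CDD)
and `d − f` (CMDD) under the parametric model. A dispersal-kernel
null model (adults fixed, saplings re-dispersed from partly-dead
parents) quantifies how much of the observed mycorrhizal signal is
attributable to dispersal limitation, adult clumping and mortality
alone. A synthetic-forest generator (Thomas-process adults, log-series
abundances, known recruitment parameters, latitudinal AM→EM gradient)
provides ground truth for every stage.

## Worked example

```r
library(mycodd)

# three synthetic plots with known truth: c_AM = -0.3, c_EM = -0.1,
# d = -0.02, theta = 2
cfg <- synthetic_config(seed = 42)
study <- generate_study(cfg, n_plots = 3)

species <- unique(unlist(lapply(study$censuses, function(x) x$stems$species)))
traits <- assign_mycorrhizal_type(species, study$traits)
tab <- prepare_quadrat_data(study$censuses, traits, cfg$kernel, "CDD")

eff <- estimate_effects(tab, "CDD")     # global integrated model
attr(eff, "fit")
#> global_fit (CDD, gam): 26 species-by-site groups, theta = 1.88
#>  type         r           c           d  f
#>    AM 0.5927478 -0.30048095 -0.02386055 NA
#>    EM 0.5846671 -0.09580725 -0.02638826 NA
attr(eff, "window")
#> density window [0.098, 1.098] (+1 adults), retains 26 group(s)
type_contrast(eff, "site_random")
#> AM - EM [site_random, n = 26]: estimate = -0.2072 (se 3.71e-06), ...
```

The fitted type-specific conspecific effects recover the generating
values (−0.30 and −0.096 against true −0.3 and −0.1), the retention
window starts at a fractional adult density (0.098) because densities
are distance-weighted, and the AM − EM contrast of the per-capita
sapling-density deltas is −0.207 (true gap −0.2): AM species lose
about 0.2 more log per-capita sapling density per added conspecific
adult than EM species, the signature of stronger negative CDD in AM
trees.

## Analysis workflow

The `analysis/` directory holds the end-to-end study as numbered
drivers over the package functions, writing tables under `results/`:

1. `01_simulate_study.R` — six-plot synthetic study along an AM→EM
   latitudinal gradient, written as delimited census/trait files;
2. `02_build_neighborhoods.R` — read censuses back, assign types,
   build CDD/CMDD quadrat tables;
3. `03_fit_models.R` — global integrated and species-by-site NB
   Ricker fits, compared with the generating truth;
4. `04_effects_inference.R` — windows, effect estimates, type
   contrasts, abundance-weighted site medians, site-level models,
   prediction curves;
5. `05_null_model.R` — dispersal-kernel null experiment for the AM−EM
   CDD difference.

Run them in order from the repository root after installing the
package.

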