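---
title: "Estimating mycorrhizal mediation of density dependence in forest plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mycorrhizal mediation of density dependence in forest plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Negative conspecific density dependence (CDD) — reduced recruitment of
juveniles near conspecific adults, classically attributed to a local
build-up of species-specific enemies — is a leading candidate mechanism
for the maintenance of tree diversity. Trees, however, also form
mutualisms with mycorrhizal fungi, and the two major guilds differ:
ectomycorrhizal (EM) associations tend to be more host-specific and
more protective than arbuscular mycorrhizal (AM) ones. That motivates
two spatial hypotheses testable in stem-mapped census plots:

1. EM tree species experience weaker negative CDD than AM species
   (their per-capita sapling density declines less with conspecific
   adult density);
2. tree species benefit from heterospecific neighbours of their *own*
   mycorrhizal type — positive conmycorrhizal density dependence
   (CMDD), expected to be strongest in AM species because of their low
   host specificity.

`mycodd` implements the full estimation pipeline for these hypotheses
— census normalisation, neighbourhood density computation, recruitment
modelling, effect extraction, hypothesis tests and a dispersal-kernel
null model — together with a synthetic-forest generator with known
ground truth, so that every stage is testable without restricted census
data.

## Data model and filtering

A census is a table of stems (`stem_id`, `tree_id`, `species`, `x`,
`y`, `dbh`, `status`, `main_stem`) on a rectangular plot; quadrats are
20 m squares by default, with membership on half-open intervals
`[kq, (k+1)q)` so boundary stems are assigned unambiguously. Dead
stems are excluded from all analyses; site metadata (richness,
mycorrhizal composition, basal area, abundances) uses all living
stems, while model tables use only main stems — the largest living
stem of each tree, ties broken deterministically by smallest stem id.
Unrecognised status strings are conservatively treated as dead and
logged.

Mycorrhizal types come from a trait table with species- and
genus-level rows: species labels take precedence, genus labels are the
fallback, and anything not strictly AM or EM (mixed or non-mycorrhizal
categories, unmatched names) is excluded from every model, with the
excluded fraction logged.

Saplings are separated from adults by a species-specific DBH cutoff
cascade: 10 cm if at least 20% of the species' stems are ≥ 10 cm,
else 5 cm under the same rule, else 2 cm, which is terminal because
1 cm is the smallest measured stem. The 20% thresholds are inclusive
(a species with exactly 20% adults keeps the higher cutoff), and the
cascade depends only on the species' DBH multiset.

## Neighbourhood densities

The unit of replication is the quadrat. For each retained species and
quadrat we compute the sapling count `S` and four distance-weighted
adult densities: conspecific `A`, all-heterospecific `H`,
conmycorrhizal-heterospecific `M` and heteromycorrhizal-heterospecific
`HMH`, with `H = M + HMH` by construction. Adults inside the focal
quadrat count with weight 1; adults outside are down-weighted by a
Clark 2Dt kernel of their distance to the nearest point of the quadrat
boundary,

$$w(d) = \left(1 + d^2/u\right)^{-(p+1)},$$

normalised to 1 at distance zero so interior and exterior weights join
continuously. The 2Dt family is the standard heavy-tailed seed-shadow
kernel; its parameterisation here is a package choice, with shape
`p = 1` by default and the scale `u` set from a mean dispersal distance
via the closed-form mean $\sqrt{u}\,p\,B(3/2, p - 1/2)$ (finite for
`p > 1/2`). No maximum radius is imposed and no toroidal edge
correction is applied: adults beyond the mapped plot simply do not
exist, so edge quadrats have truncated neighbourhoods, as in the
observational setting. Densities are floored at $10^{-12}$ so the
`log(A)` model offset is always defined.

A species enters the model tables only if its saplings and its adults
each occupy at least ten quadrats. For the CMDD dataset, plots whose
retained species are all of one mycorrhizal type are dropped entirely,
since conmycorrhizal effects are not estimable there.

## Recruitment models

Recruitment follows a Ricker form with negative-binomial errors and a
log link. For the CDD dataset,

$$S = A\,e^{\,r + cA + dH},$$

i.e. a NB regression of `S` on `A` and `H` with offset `log(A)`:
`r` is log per-capita sapling density with no conspecific adults, `c`
the conspecific effect, `d` the heterospecific effect. The CMDD form
splits the heterospecifics by mycorrhizal type:

$$S = A\,e^{\,r + cA + dM + f\,H_{\mathrm{hmh}}}.$$

Species-by-site models (`fit_species_model()`) are NB GLMs with
dispersion estimated by maximum likelihood; non-convergence is flagged
on the result, never silently dropped, an all-zero response yields an
explicit uninformative fit, and constant or collinear density columns
raise a singular-design error. The core model is deliberately the
printed parametric form — every headline quantity (the deltas below)
depends only on it — and the penalised-spline generalisation of the
same regression is available through the mgcv backend for users who
want smooth terms.

The global integrated model (`fit_global_model()`) pools all
species-by-site groups: type-specific fixed intercepts and density
slopes (mycorrhizal type interacting with each density term) plus
independent Gaussian random intercepts and random conspecific slopes
for every species-by-site group, fitted as ridge penalties whose
variance components are selected by Laplace-approximate restricted
marginal likelihood (mgcv `bam`/`gam` with `re` smooths; `fREML` with
`discrete = TRUE` for large tables). The random-effects covariance is
diagonal — intercepts and slopes shrink independently — since nothing
in the design identifies their correlation well at typical group
sizes. Two limiting behaviours anchor the implementation and are kept
as tests: with penalties forced to zero and shared dispersion fixed,
the per-group effective coefficients reproduce separate species fits;
with infinite penalties, all group slopes collapse onto the
type-level effects.

## Effect estimates

The quantity of interest is the change in log per-capita sapling
density (PCS = predicted `S`/`A`) for a standard increment of one
adult, relative to the same increment of heterospecific adults:

$$\Delta = \left[\log \mathrm{PCS}(x_0 + 1) - \log \mathrm{PCS}(x_0)\right]_{\text{focal}}
         - \left[\log \mathrm{PCS}(x_0 + 1) - \log \mathrm{PCS}(x_0)\right]_{\text{heterospecific}}.$$

Under the log-linear model this is window-invariant and reduces to
`c − d` for CDD and `d − f` for CMDD (the CMDD reference is the
heteromycorrhizal pool; an alternative reference that splits one
generic heterospecific adult into the observed CMH/HMH proportions is
also implemented for the CDD-mode contrast on CMDD-form fits). The
"relative to heterospecific" wording admits a ratio-of-ratios reading,
which is identical on the log scale. Standard errors follow from the
delta method on the coefficient covariance; for global-model groups
the contrast covers the type slope, the group's random slope and the
heterospecific slope jointly.

The window start is chosen by `select_window()`: over a 0.001-step
grid, maximise the number of species-by-site groups whose observed
density range contains the whole `[a, a+1]` window, ties to the
smallest start. Fractional optima (windows like 0.067–1.067 adults)
arise naturally because densities are distance-weighted. Because the
parametric delta is window-invariant, the window matters only for
which groups are considered supported — and robustness of the deltas
to the increment (1 vs 0.75 vs 0.5) is verified in the tests. Held
densities during prediction default to observed means (they cancel
under the log-linear model); this is configurable.

## Hypothesis tests

Species-by-site deltas feed four test families: (1) the AM−EM type
contrast, with site either a random intercept (REML linear mixed
model) or an interacting fixed effect (marginal contrast with equal
site weights) — with a single site both reduce to ordinary regression,
which is logged; (2) one-sample t tests of each type's mean delta
against zero (used for CMDD, where the type contrast is expected
null); exactly constant inputs are reported as degenerate rather than
producing undefined statistics; (3) site-level summaries — the
weighted median of deltas with natural-log abundance weights, lower
weighted-median convention on ties; and (4) single-predictor OLS
models of site-level responses on latitude, climate or EM proportion.
Predictors are fit strictly one at a time: those covariates are
collinear across any realistic site set, and the package deliberately
refuses to combine them. Species-by-site estimates enter these models
unweighted by default; SE-weighting is available.

## The dispersal-kernel null model

Spatial sapling–adult association arises from dispersal limitation,
habitat affinity and adult mortality even without density dependence.
The null model keeps every adult exactly where it was observed
(preserving clumping), then re-disperses the observed saplings of each
species from a parent pool consisting of its adults plus
`ceiling(m · n_adults)` ghost parents (default mortality `m = 0.1`),
placed by resampling observed adult coordinates with a uniform jitter
of half a quadrat width — a rule that preserves the observed clumping
the null is meant to retain; the mortality proportion and ghost
placement are configuration, as no canonical values exist. Each
sapling picks a parent uniformly, a distance by inverse-CDF sampling
of the species' 2Dt kernel (mean dispersal from a height allometry,
$10^{a + b\log_{10}h}$, defaults `a = 0.5`, `b = 0.5` — package
defaults giving plausible tree dispersal distances, not values from a
specific compilation), and a uniform angle; draws landing outside the
plot are redrawn rather than wrapped. Sapling counts and DBHs are
conserved exactly; only coordinates change.

Each iteration re-runs the whole estimation and recomputes the
statistic — the AM−EM difference in mean CDD, or the AM mean CMDD
(used because CMDD shows no significant type difference while AM CMDD
is the hypothesised positive effect). The full global refit is the
default; a reduced refit (pooled type-specific NB GLM, no random
effects) is provided for tight iteration budgets and used in the
scaled calibration tests. The two-sided exceedance is the fraction of
null draws at least as far from the null median as the observed value,
with resolution bounded by 1/iterations (100 by default).

One structural point deserves emphasis. Even when saplings carry no
spatial association with adults at all (the infinite-dispersal limit,
where null saplings are uniform), refitting the Ricker form does
*not* return `c = 0`: a spatially constant expected count forces the
linear term `cA` to cancel the `log(A)` offset, so null fits produce
systematically negative conspecific coefficients whose magnitude
depends on each species' density distribution. This is precisely why
observed statistics are judged against the null *distribution* of the
same statistic — which inherits the artifact — and never against
zero. The tests verify the limit at the level where it genuinely
holds: per-quadrat null sapling counts are uncorrelated with
conspecific adult density, and null sapling positions are uniform.

## The synthetic generator

The generator emulates the features of stem-mapped censuses the
pipeline depends on: clustered adults (per-species Thomas processes —
Poisson parents, Poisson-Gaussian offspring, wrapped toroidally so the
expected count is exactly `kappa * area * mu`), a log-series rank
abundance distribution so rare species exercise the ten-quadrat rule,
species-level AM/EM labels with an AM proportion that declines with
latitude across plots, and saplings drawn either from the generating
count model (per-quadrat NB counts with the exact Ricker mean;
guarantees that correctly-specified fits are unbiased) or
mechanistically (kernel-dispersed recruits thinned by
`exp(c_type * A)`; used for null-model realism). DBH values are
cosmetic — adults lognormal above 10 cm, saplings below 2 cm — because
only class membership matters downstream; the sub-2 cm saplings ensure
the cutoff cascade always separates generated classes correctly.

Default conditions (a 9 ha plot, 20 species, ~1200 adults, `r = 0.5`,
`c_AM = -0.3`, `c_EM = -0.1`, `d = -0.02`, `theta = 2`) give
distance-weighted conspecific densities of order 0.1–10 per quadrat
and realistic zero-inflated sapling counts. What the generator does
*not* emulate: habitat covariate surfaces, demographic time series,
phylogenetic structure among species, and measurement error in
coordinates or DBH — so passing tests demonstrate correctness of the
estimators under the stated generating process, not robustness to
those real-data complications.

## Numerical choices and problem sizes

Convergence of the NB GLMs uses a relative-deviance tolerance of
1e-12 (up to 200 iterations); the global model inherits mgcv's REML
convergence control. Window search uses a 0.001 grid step. Density
floors are 1e-12. Ties: smallest window start, smallest stem id,
lower weighted median. The test suite runs the heavier experiments at
sizes chosen to balance statistical resolution against a desk-scale
run: parameter recovery for the global model at 40 species × 2 sites
× 1000 quadrats over 20 replicates; species-fit recovery at 200
replicates of 1000 quadrats; null-model calibration over 20 scaled
replicates of 10 iterations with the reduced refit; increment
robustness across 200 simulated fits. The analysis scripts under
`analysis/` run the same pipeline end to end on a six-plot study and
write their tables under `results/`.

## Known limitations

Kernel parameters (`u`, `p`) are assumed, not estimated from seed-trap
data; edge quadrats have truncated neighbourhoods; the random-effects
covariance is diagonal; CMDD group-level estimates from the global
model vary only through the type-level slopes (the random slope is on
conspecific density, following the model specification), so
species-level CMDD heterogeneity is better examined with the
species-by-site route; and single-census spatial signatures are an
indirect proxy for the demographic rates that dynamic data would
measure.
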