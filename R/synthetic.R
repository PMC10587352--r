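#' Configuration for the synthetic forest-plot generator
#'
#' Defines the generating conditions for synthetic censuses: plot
#' geometry, a log-series species-abundance distribution, Thomas
#' cluster processes for adult spatial pattern, Ricker-form
#' negative-binomial recruitment, an AM/EM composition that can follow a
#' latitudinal gradient, and the height-dispersal allometry. Defaults
#' are desk-scale analogues of a stem-mapped forest census: a 9 ha plot
#' of 20 m quadrats, a strongly skewed abundance distribution so rare
#' species exercise the inclusion rule, negative CDD that is stronger
#' for AM than EM species, and mild heterospecific effects.
#'
#' @param x_extent,y_extent Plot extents (m).
#' @param quadrat_size Quadrat side (m).
#' @param n_species Species per plot.
#' @param logseries_theta Log-series parameter in (0, 1); relative
#'   abundance of rank-k species is proportional to `theta^k / k`.
#' @param n_adults Expected adult stems per plot.
#' @param prop_am Proportion of AM species (single-plot default).
#' @param thomas_mu Mean offspring (adults) per Thomas-process parent.
#' @param thomas_sigma Gaussian offspring spread (m).
#' @param r,c_am,c_em,d,f,theta Recruitment parameters of the Ricker NB
#'   model: log baseline per-capita sapling density, type-specific
#'   conspecific effects, heterospecific effect `d` (conmycorrhizal
#'   effect in the CMDD form), heteromycorrhizal effect `f`, NB
#'   dispersion `theta`.
#' @param recruitment `"cdd"` (Eq.-1 form, `d*H`) or `"cmdd"` (Eq.-2
#'   form, `d*M + f*HMH`).
#' @param allometry Height-dispersal allometry (see
#'   [dispersal_from_height()]).
#' @param kernel Neighbourhood kernel used when computing the adult
#'   densities that drive recruitment; defaults to a Clark 2Dt with
#'   15 m mean dispersal.
#' @param seed Integer seed for full determinism.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(x_extent = 300, y_extent = 300,
                             quadrat_size = 20, n_species = 20,
                             logseries_theta = 0.85, n_adults = 1200,
                             prop_am = 0.6, thomas_mu = 20,
                             thomas_sigma = 15, r = 0.5, c_am = -0.3,
                             c_em = -0.1, d = -0.02, f = 0.01,
                             theta = 2,
                             recruitment = c("cdd", "cmdd"),
                             allometry = c(intercept = 0.5, slope = 0.5),
                             kernel = clark2dt(mean_distance = 15, p = 1),
                             seed = NULL) {
  recruitment <- match.arg(recruitment)
  stopifnot(x_extent > 0, y_extent > 0, quadrat_size > 0,
            n_species >= 2, logseries_theta > 0, logseries_theta < 1,
            n_adults > 0, prop_am >= 0, prop_am <= 1,
            thomas_mu > 0, thomas_sigma > 0, theta > 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# log-series relative abundances for ranks 1..n
logseries_abundance <- function(n, theta) {
  p <- theta^seq_len(n) / seq_len(n)
  p / sum(p)
}

# species pool: binomials, AM/EM labels, max heights, per-species
# Thomas parent intensity implied by the target abundance
synthetic_species_pool <- function(config, prop_am = config$prop_am) {
  n <- config$n_species
  n_am <- round(prop_am * n)
  type <- sample(c(rep("AM", n_am), rep("EM", n - n_am)))
  relab <- logseries_abundance(n, config$logseries_theta)
  area <- config$x_extent * config$y_extent
  data.frame(
    species = sprintf("Genus%02d species%02d",
                      (seq_len(n) - 1L) %/% 3 + 1L, seq_len(n)),
    mycorrhizal_type = type,
    max_height = round(rlnorm(n, log(22), 0.35), 1),
    rel_abundance = relab,
    kappa = relab * config$n_adults / (config$thomas_mu * area))
}

#' Generate clustered adult stems (Thomas process)
#'
#' One Thomas cluster process per species: Poisson parents with
#' intensity `kappa` (per m^2), Poisson(`thomas_mu`) offspring per
#' parent displaced by an isotropic Gaussian of sd `thomas_sigma`, so
#' the expected adult count is `kappa * area * thomas_mu`. Offspring are
#' wrapped toroidally into the plot, preserving both the expectation and
#' the clustered pattern; with many parents and a spread on the plot
#' scale the pattern approaches complete spatial randomness. Adult DBH
#' is cosmetic (lognormal above the 10 cm adult cutoff).
#'
#' @param config A [synthetic_config()].
#' @param species Optional species pool (data.frame with `species` and
#'   `kappa`); generated from the config when omitted.
#' @return data.frame of adult stems: `species`, `x`, `y`, `dbh`.
#' @export
generate_adults <- function(config, species = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(species)) species <- synthetic_species_pool(config)
  area <- config$x_extent * config$y_extent
  out <- lapply(seq_len(nrow(species)), function(i) {
    n_par <- rpois(1, species$kappa[i] * area)
    if (n_par == 0L) return(NULL)
    pxx <- runif(n_par, 0, config$x_extent)
    pyy <- runif(n_par, 0, config$y_extent)
    n_off <- rpois(n_par, config$thomas_mu)
    if (sum(n_off) == 0L) return(NULL)
    x <- rep(pxx, n_off) + rnorm(sum(n_off), 0, config$thomas_sigma)
    y <- rep(pyy, n_off) + rnorm(sum(n_off), 0, config$thomas_sigma)
    data.frame(species = species$species[i],
               x = x %% config$x_extent, y = y %% config$y_extent,
               dbh = round(10 * exp(abs(rnorm(sum(n_off), 0, 0.45))), 1))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(species = character(),
                                      x = numeric(), y = numeric(),
                                      dbh = numeric())
  rownames(out) <- NULL
  out
}

# wrap adult stems into a plot_census (adults only)
adults_as_census <- function(adults, config, plot_id = "synthetic",
                             latitude = NA_real_) {
  n <- nrow(adults)
  plot_census(data.frame(stem_id = sprintf("a%06d", seq_len(n)),
                         tree_id = sprintf("a%06d", seq_len(n)),
                         species = adults$species, x = adults$x,
                         y = adults$y, dbh = adults$dbh,
                         status = "alive", main_stem = TRUE),
              plot_id = plot_id, x_extent = config$x_extent,
              y_extent = config$y_extent,
              quadrat_size = config$quadrat_size, latitude = latitude)
}

#' Generate saplings around adults under known recruitment rules
#'
#' `mode = "count_model"` draws per-quadrat sapling counts for each
#' species from the generating Ricker NB model — mean
#' `A * exp(r + c_type*A + d*H)` (or the CMDD form with `M` and `HMH`)
#' with the distance-weighted densities computed from the adults — and
#' places them uniformly within their quadrat. This matches the fitted
#' model exactly, so correctly-specified fits are unbiased.
#' `mode = "mechanistic"` disperses Poisson recruits from each adult via
#' the species' 2Dt dispersal kernel (mean from the height allometry)
#' and thins them with survival `exp(c_type * A)` (clamped to 1), a
#' spatially explicit process used for null-model realism checks.
#'
#' @param adults Adult stems from [generate_adults()].
#' @param config A [synthetic_config()].
#' @param species Species pool (must cover the adults' species;
#'   regenerated from the config when omitted — pass the pool for
#'   consistent mycorrhizal labels).
#' @param mode `"count_model"` or `"mechanistic"`.
#' @param fecundity Mean recruits per adult in mechanistic mode.
#' @return data.frame of sapling stems: `species`, `x`, `y`, `dbh`.
#' @export
generate_saplings <- function(adults, config, species = NULL,
                              mode = c("count_model", "mechanistic"),
                              fecundity = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(species)) species <- synthetic_species_pool(config)
  if (nrow(adults) == 0L)
    return(data.frame(species = character(), x = numeric(),
                      y = numeric(), dbh = numeric()))
  census <- adults_as_census(adults, config)
  sizes <- data.frame(species = species$species, sapling_cutoff = 10)
  tab <- build_quadrat_table(census, sizes, species, config$kernel,
                             dataset = "CDD", min_quadrats = 0)
  ctype <- ifelse(tab$mycorrhizal_type == "AM", config$c_am, config$c_em)
  eta <- config$r + ctype * tab$A +
    if (config$recruitment == "cmdd")
      config$d * tab$M + config$f * tab$HMH
    else config$d * tab$H
  if (mode == "count_model") {
    mu <- tab$A * exp(eta)
    n <- rnbinom(nrow(tab), size = config$theta, mu = mu)
    keep <- which(n > 0)
    q <- config$quadrat_size
    out <- lapply(keep, function(i) {
      data.frame(species = tab$species[i],
                 x = pmin(runif(n[i], tab$qcol[i] * q,
                                min((tab$qcol[i] + 1) * q, config$x_extent)),
                          config$x_extent - 1e-9),
                 y = pmin(runif(n[i], tab$qrow[i] * q,
                                min((tab$qrow[i] + 1) * q, config$y_extent)),
                          config$y_extent - 1e-9))
    })
    out <- do.call(rbind, out)
  } else {
    # per-quadrat survival field from the generating exponent
    q <- config$quadrat_size
    surv <- pmin(exp(ctype * tab$A), 1)
    key <- paste(tab$species, tab$qrow, tab$qcol)
    out <- lapply(unique(adults$species), function(sp) {
      ad <- adults[adults$species == sp, , drop = FALSE]
      h <- species$max_height[match(sp, species$species)]
      kern <- clark2dt(mean_distance =
                         dispersal_from_height(h, config$allometry),
                       p = config$kernel$p)
      n_rec <- rpois(nrow(ad), fecundity)
      tot <- sum(n_rec)
      if (tot == 0L) return(NULL)
      px <- rep(ad$x, n_rec)
      py <- rep(ad$y, n_rec)
      rr <- sample_kernel_distance(tot, kern)
      aa <- runif(tot, 0, 2 * pi)
      x <- px + rr * cos(aa)
      y <- py + rr * sin(aa)
      ok <- x >= 0 & x < config$x_extent & y >= 0 & y < config$y_extent
      x <- x[ok]
      y <- y[ok]
      if (!length(x)) return(NULL)
      ki <- match(paste(sp, floor(y / q), floor(x / q)), key)
      alive <- runif(length(x)) < surv[ki]
      if (!any(alive)) return(NULL)
      data.frame(species = sp, x = x[alive], y = y[alive])
    })
    out <- do.call(rbind, out)
  }
  if (is.null(out))
    return(data.frame(species = character(), x = numeric(),
                      y = numeric(), dbh = numeric()))
  # sapling DBH below 2 cm so the size-class cascade always separates
  # generated saplings (< 2) from adults (>= 10) whatever cutoff it picks
  out$dbh <- round(runif(nrow(out), 1, 1.99), 2)
  rownames(out) <- NULL
  out
}

#' Generate a multi-plot synthetic study with known ground truth
#'
#' Generates `n_plots` censuses along a latitudinal gradient in AM/EM
#' composition (proportion of AM species declining with latitude,
#' mirroring the shift from AM-dominated tropical to EM-dominated
#' temperate forests), writes censuses and a species-level trait table
#' in the exact formats consumed by [read_census()] and [read_traits()],
#' and records the generating truth.
#'
#' @param config A [synthetic_config()]; `config$seed` drives all
#'   randomness.
#' @param n_plots Number of plots.
#' @param latitudes Plot latitudes (degrees); default evenly spaced
#'   5–55.
#' @param prop_am_fun Function latitude -> proportion of AM species;
#'   default a linear decline from ~0.9 at the equator clamped to
#'   [0.1, 0.9].
#' @param mode Sapling generation mode (see [generate_saplings()]).
#' @param out_dir Optional directory: writes `census_<plot>.csv`,
#'   `traits.csv` and `ground_truth.json`.
#' @return List of class `synthetic_study`: `censuses` (named list of
#'   [plot_census()]), `traits` (trait table, species-level rows),
#'   `truth` (generating parameters, per-species types and dispersal
#'   distances, per-plot latitude and AM proportion).
#' @export
generate_study <- function(config, n_plots = 6,
                           latitudes = seq(5, 55, length.out = n_plots),
                           prop_am_fun = function(lat)
                             pmin(pmax(0.92 - 0.013 * lat, 0.1), 0.9),
                           mode = "count_model", out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  censuses <- list()
  pools <- list()
  for (k in seq_len(n_plots)) {
    pid <- sprintf("plot%02d", k)
    pool <- synthetic_species_pool(config, prop_am = prop_am_fun(latitudes[k]))
    pool$species <- sprintf("Genus%02d species%02d",
                            (k - 1L) * config$n_species +
                              (seq_len(config$n_species) - 1L) %/% 3 + 1L,
                            (k - 1L) * config$n_species +
                              seq_len(config$n_species))
    cfg <- config
    cfg$seed <- NULL                 # RNG stream already seeded
    adults <- generate_adults(cfg, pool)
    saplings <- generate_saplings(adults, cfg, pool, mode = mode)
    stems <- rbind(
      data.frame(species = adults$species, x = adults$x, y = adults$y,
                 dbh = adults$dbh),
      data.frame(species = saplings$species, x = saplings$x,
                 y = saplings$y, dbh = saplings$dbh))
    n <- nrow(stems)
    censuses[[pid]] <- plot_census(
      data.frame(stem_id = sprintf("%s_s%06d", pid, seq_len(n)),
                 tree_id = sprintf("%s_t%06d", pid, seq_len(n)),
                 species = stems$species, x = stems$x, y = stems$y,
                 dbh = stems$dbh, status = "alive", main_stem = TRUE),
      plot_id = pid, x_extent = config$x_extent,
      y_extent = config$y_extent, quadrat_size = config$quadrat_size,
      latitude = latitudes[k])
    pools[[pid]] <- pool
  }
  pool_all <- do.call(rbind, pools)
  traits <- data.frame(
    species = pool_all$species,
    genus = vapply(strsplit(pool_all$species, "\\s+"), `[`, "", 1L),
    mycorrhizal_type = pool_all$mycorrhizal_type,
    max_height = pool_all$max_height,
    level = "species", row.names = NULL)
  truth <- list(
    params = list(r = config$r, c_am = config$c_am, c_em = config$c_em,
                  d = config$d, f = config$f, theta = config$theta,
                  recruitment = config$recruitment),
    kernel = list(u = config$kernel$u, p = config$kernel$p),
    allometry = as.list(config$allometry),
    species = data.frame(
      species = pool_all$species,
      mycorrhizal_type = pool_all$mycorrhizal_type,
      max_height = pool_all$max_height,
      mean_dispersal = dispersal_from_height(pool_all$max_height,
                                             config$allometry),
      row.names = NULL),
    plots = data.frame(plot_id = names(censuses), latitude = latitudes,
                       prop_am_target = prop_am_fun(latitudes),
                       row.names = NULL),
    seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(censuses))
      write_census(censuses[[pid]],
                   file.path(out_dir, paste0("census_", pid, ".csv")))
    write.csv(traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(list(censuses = censuses, traits = traits, truth = truth),
            class = "synthetic_study")
}

#' Simulate a quadrat table directly from the Ricker NB model
#'
#' Bypasses spatial generation: draws distance-weighted densities from
#' lognormal distributions and sapling counts from the generating
#' Ricker NB model with species-by-site random intercepts and
#' conspecific slopes. This is the generator used for model-recovery
#' experiments where the sampling distribution of the estimator matters
#' and the spatial machinery does not.
#'
#' @param n_species Species per site.
#' @param n_sites Sites.
#' @param n_quadrats Quadrats per site.
#' @param r,c_am,c_em,d,f,theta Generating parameters ([synthetic_config()]
#'   meanings; `f = NULL` generates the CDD form).
#' @param prop_am Proportion of AM species.
#' @param sd_r,sd_c SDs of the species-by-site random intercepts and
#'   conspecific slopes.
#' @param meanlog_A,sdlog_A,meanlog_H,sdlog_H Lognormal density
#'   parameters.
#' @return Quadrat-table data.frame compatible with
#'   [fit_global_model()] (columns `plot_id`, `species`, `S`, `A`, `H`,
#'   `M`, `HMH`, `mycorrhizal_type`, `group`), with the per-group truth
#'   attached as attribute `"truth"`.
#' @export
simulate_quadrat_table <- function(n_species = 40, n_sites = 2,
                                   n_quadrats = 1000, r = 1,
                                   c_am = -0.4, c_em = -0.1, d = -0.05,
                                   f = NULL, theta = 2, prop_am = 0.5,
                                   sd_r = 0.3, sd_c = 0.05,
                                   meanlog_A = 0, sdlog_A = 0.6,
                                   meanlog_H = log(5), sdlog_H = 0.4) {
  cmdd <- !is.null(f)
  n_am <- round(prop_am * n_species)
  types <- sample(c(rep("AM", n_am), rep("EM", n_species - n_am)))
  out <- vector("list", n_species * n_sites)
  truth <- vector("list", n_species * n_sites)
  k <- 0L
  for (s in seq_len(n_sites)) {
    for (j in seq_len(n_species)) {
      k <- k + 1L
      sp <- sprintf("sp%03d", j)
      pid <- sprintf("site%02d", s)
      ctype <- if (types[j] == "AM") c_am else c_em
      b0 <- rnorm(1, 0, sd_r)
      b1 <- rnorm(1, 0, sd_c)
      A <- rlnorm(n_quadrats, meanlog_A, sdlog_A)
      # independent conmycorrhizal / heteromycorrhizal components so the
      # CMDD design is full rank within a single group
      M <- rlnorm(n_quadrats, meanlog_H - log(2), sdlog_H)
      HMH <- rlnorm(n_quadrats, meanlog_H - log(2), sdlog_H)
      H <- M + HMH
      eta <- r + b0 + (ctype + b1) * A +
        if (cmdd) d * M + f * HMH else d * H
      S <- rnbinom(n_quadrats, size = theta, mu = A * exp(eta))
      out[[k]] <- data.frame(
        plot_id = pid, qrow = 0L, qcol = seq_len(n_quadrats) - 1L,
        species = sp, S = S, A = A, H = H, M = M, HMH = HMH,
        mycorrhizal_type = types[j], group = paste0(pid, ":", sp))
      truth[[k]] <- data.frame(group = paste0(pid, ":", sp),
                               mycorrhizal_type = types[j],
                               r = r + b0, c = ctype + b1,
                               d = d, f = if (cmdd) f else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- do.call(rbind, truth)
  res
}
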