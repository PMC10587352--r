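#' Configuration of the dispersal-kernel null model
#'
#' @param iterations Number of null realisations (default 100).
#' @param adult_mortality Proportion `m` of "ghost" parents added per
#'   species (`ceiling(m * n_adults)` adults that may have spawned
#'   recruits and since died), `0 <= m < 1`. Default 0.1.
#' @param allometry Height-to-dispersal allometry passed to
#'   [dispersal_from_height()].
#' @param kernel_p Shape of the species dispersal kernels.
#' @param default_height Maximum height (m) assumed for species without
#'   a height trait.
#' @param seed Integer seed; per-iteration seeds are derived from it so
#'   a given seed yields bit-identical null censuses.
#' @return A list of class `null_config`.
#' @export
null_config <- function(iterations = 100, adult_mortality = 0.1,
                        allometry = c(intercept = 0.5, slope = 0.5),
                        kernel_p = 1, default_height = 20, seed = NULL) {
  if (adult_mortality < 0 || adult_mortality >= 1)
    stop("adult_mortality must be in [0, 1)")
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 adult_mortality = adult_mortality,
                 allometry = allometry, kernel_p = kernel_p,
                 default_height = default_height, seed = seed),
            class = "null_config")
}

#' Simulate one dispersal-kernel null census
#'
#' Keeps every adult stem exactly where it was observed (so clumping
#' from habitat affinity and other adult-level processes is retained)
#' and re-disperses the observed saplings of each species from a parent
#' pool: the species' adults plus `ceiling(m * n_adults)` ghost parents
#' (adult mortality), placed by resampling observed adult coordinates
#' with a uniform jitter of half a quadrat width. Each sapling picks a
#' parent uniformly, then a dispersal distance from the species' Clark
#' 2Dt kernel (mean from the height allometry) and a uniform angle;
#' draws landing outside the plot are redrawn. Sapling identities,
#' DBHs and counts are conserved; only coordinates change. Species with
#' no adults and no ghosts get uniformly placed saplings (logged).
#'
#' @param census A [plot_census()] of living analysis stems.
#' @param assignments Size classes from [assign_size_classes()] for this
#'   census.
#' @param traits Assignment from [assign_mycorrhizal_type()] including
#'   `max_height`.
#' @param config A [null_config()]; its `seed`, when non-NULL, makes the
#'   realisation deterministic.
#' @return A [plot_census()] with re-dispersed saplings.
#' @export
simulate_null_census <- function(census, assignments, traits, config) {
  stopifnot(inherits(census, "plot_census"), inherits(config, "null_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  stems <- census$stems
  cutoff <- assignments$sapling_cutoff[match(stems$species,
                                             assignments$species)]
  q <- census$quadrat_size
  xe <- census$x_extent
  ye <- census$y_extent
  eps <- 1e-9
  for (sp in unique(stems$species)) {
    co <- cutoff[match(sp, stems$species)]
    if (is.na(co)) next
    sel <- stems$species == sp
    is_sap <- sel & stems$dbh < co
    n_sap <- sum(is_sap)
    if (n_sap == 0L) next
    ad <- stems[sel & stems$dbh >= co, c("x", "y"), drop = FALSE]
    n_ad <- nrow(ad)
    n_ghost <- ceiling(config$adult_mortality * n_ad)
    if (n_ghost > 0) {
      gi <- sample.int(n_ad, n_ghost, replace = TRUE)
      gx <- pmin(pmax(ad$x[gi] + runif(n_ghost, -q / 2, q / 2), 0), xe - eps)
      gy <- pmin(pmax(ad$y[gi] + runif(n_ghost, -q / 2, q / 2), 0), ye - eps)
      pool <- rbind(ad, data.frame(x = gx, y = gy))
    } else pool <- ad
    if (nrow(pool) == 0L) {
      mycodd_log("species ", sp, ": no parents; saplings placed uniformly")
      stems$x[is_sap] <- runif(n_sap, 0, xe - eps)
      stems$y[is_sap] <- runif(n_sap, 0, ye - eps)
      next
    }
    h <- traits$max_height[match(sp, traits$species)]
    if (is.na(h)) h <- config$default_height
    kern <- clark2dt(mean_distance =
                       dispersal_from_height(h, config$allometry),
                     p = config$kernel_p)
    pid <- sample.int(nrow(pool), n_sap, replace = TRUE)
    px <- pool$x[pid]
    py <- pool$y[pid]
    newx <- newy <- rep(NA_real_, n_sap)
    pending <- seq_len(n_sap)
    for (round in 1:500) {
      n <- length(pending)
      if (n == 0L) break
      r <- sample_kernel_distance(n, kern)
      ang <- runif(n, 0, 2 * pi)
      cx <- px[pending] + r * cos(ang)
      cy <- py[pending] + r * sin(ang)
      ok <- cx >= 0 & cx < xe & cy >= 0 & cy < ye
      newx[pending[ok]] <- cx[ok]
      newy[pending[ok]] <- cy[ok]
      pending <- pending[!ok]
    }
    if (length(pending)) {          # pathological kernel/plot geometry
      mycodd_log("species ", sp, ": ", length(pending),
                 " sapling(s) placed uniformly after rejection limit")
      newx[pending] <- runif(length(pending), 0, xe - eps)
      newy[pending] <- runif(length(pending), 0, ye - eps)
    }
    stems$x[is_sap] <- newx
    stems$y[is_sap] <- newy
  }
  out <- census
  out$stems <- stems
  out
}

# pooled NB GLM with type-specific fixed effects only: the fast reduced
# refit used inside null iterations
fit_reduced_model <- function(records, dataset = c("CDD", "CMDD"),
                              theta = NULL) {
  dataset <- match.arg(dataset)
  x <- as.data.frame(records)
  x$myco <- droplevels(factor(x$mycorrhizal_type, levels = c("AM", "EM")))
  if (nlevels(x$myco) < 2L) stop("both mycorrhizal types required")
  x$log_A <- log(x$A)
  form <- if (dataset == "CDD")
    S ~ 0 + myco + A:myco + H:myco + offset(log_A)
  else
    S ~ 0 + myco + A:myco + M:myco + HMH:myco + offset(log_A)
  fit <- suppressWarnings(
    if (is.null(theta)) MASS::glm.nb(form, data = x)
    else stats::glm(form, data = x, family = MASS::negative.binomial(theta)))
  cf <- coef(fit)
  nms <- names(cf)
  out <- do.call(rbind, lapply(levels(x$myco), function(tp) {
    data.frame(type = tp,
               r = unname(cf[global_fixed_name(nms, NULL, tp)]),
               c = unname(cf[global_fixed_name(nms, "A", tp)]),
               d = unname(cf[global_fixed_name(
                 nms, if (dataset == "CDD") "H" else "M", tp)]),
               f = if (dataset == "CMDD")
                 unname(cf[global_fixed_name(nms, "HMH", tp)])
               else NA_real_)
  }))
  out
}

# two-sided exceedance of the observed statistic in the null
# distribution: the fraction of draws at least as far from the null
# median as the observed value (resolution bounded by 1/iterations)
two_sided_exceedance <- function(observed, draws) {
  med <- median(draws)
  mean(abs(draws - med) >= abs(observed - med) - 1e-12)
}

# the scalar statistics compared against their null distributions
null_statistic <- function(records, dataset, statistic, refit,
                           theta = NULL) {
  if (refit == "reduced") {
    fx <- fit_reduced_model(records, dataset, theta = theta)
    am <- fx[fx$type == "AM", ]
    em <- fx[fx$type == "EM", ]
    return(switch(statistic,
      cdd_am_em_difference = (am$c - am$d) - (em$c - em$d),
      cmdd_am_mean = am$d - am$f))
  }
  gfit <- fit_global_model(records, dataset, theta = theta)
  win <- structure(list(start = 0, end = 1, increment = 1,
                        n_retained = NA_integer_),
                   class = "density_window")
  eff <- global_group_effects(gfit, win)
  switch(statistic,
         cdd_am_em_difference =
           type_contrast(eff, mode = "site_random")$estimate,
         cmdd_am_mean = mean(eff$delta[eff$mycorrhizal_type == "AM"]))
}

#' Run the dispersal-kernel null experiment
#'
#' Computes an observed mycorrhizal statistic from the census data, then
#' re-estimates it on `config$iterations` null censuses in which
#' saplings are re-dispersed from (partly dead) parents while adults
#' stay fixed. Statistics: `"cdd_am_em_difference"` — the AM minus EM
#' difference in mean CDD from the type-contrast model; `"cmdd_am_mean"`
#' — the mean CMDD of AM species (used because CMDD does not differ
#' significantly between types, while AM CMDD is the hypothesised
#' positive effect). The two-sided exceedance is the fraction of null
#' draws at least as far from the null median as the observed value.
#'
#' @param censuses A [plot_census()] or list of them (raw censuses; they
#'   are filtered to living main stems internally).
#' @param traits Assignment from [assign_mycorrhizal_type()].
#' @param kernel Neighbourhood [clark2dt()] kernel for the quadrat
#'   tables.
#' @param config A [null_config()].
#' @param dataset `"CDD"` or `"CMDD"`.
#' @param statistic See above.
#' @param refit `"full"` (global integrated model each iteration) or
#'   `"reduced"` (pooled type-specific NB GLM; much faster, same fixed
#'   effects).
#' @param min_quadrats Occupancy threshold for species retention.
#' @param theta Optional fixed NB dispersion for the refits.
#' @return A list of class `null_result`: `statistic`, `observed`,
#'   `draws`, `exceedance`, `n_iterations` (effective), `config`.
#' @export
run_null_experiment <- function(censuses, traits, kernel, config,
                                dataset = c("CDD", "CMDD"),
                                statistic = c("cdd_am_em_difference",
                                              "cmdd_am_mean"),
                                refit = c("full", "reduced"),
                                min_quadrats = 10, theta = NULL) {
  dataset <- match.arg(dataset)
  statistic <- match.arg(statistic)
  refit <- match.arg(refit)
  if (inherits(censuses, "plot_census")) censuses <- list(censuses)
  stopifnot(inherits(config, "null_config"))

  filtered <- lapply(censuses, filter_stems)
  assignments <- lapply(filtered, assign_size_classes)
  tables <- mapply(build_quadrat_table, filtered, assignments,
                   MoreArgs = list(traits = traits, kernel = kernel,
                                   dataset = dataset,
                                   min_quadrats = min_quadrats),
                   SIMPLIFY = FALSE)
  observed_table <- do.call(rbind, tables)
  if (is.null(observed_table) || nrow(observed_table) == 0L)
    stop("no retained species in any plot")
  observed <- null_statistic(observed_table, dataset, statistic, refit,
                             theta = theta)

  draws <- rep(NA_real_, config$iterations)
  for (i in seq_len(config$iterations)) {
    cfg_i <- config
    cfg_i$seed <- if (is.null(config$seed)) NULL else config$seed + i
    draws[i] <- tryCatch({
      null_tabs <- mapply(function(cen, asg) {
        ncen <- simulate_null_census(cen, asg, traits, cfg_i)
        build_quadrat_table(ncen, asg, traits, kernel,
                            dataset = dataset, min_quadrats = min_quadrats)
      }, filtered, assignments, SIMPLIFY = FALSE)
      null_statistic(do.call(rbind, null_tabs), dataset, statistic,
                     refit, theta = theta)
    }, error = function(e) {
      warning("null iteration ", i, " dropped: ", conditionMessage(e))
      NA_real_
    })
  }
  draws <- draws[!is.na(draws)]
  exceedance <- two_sided_exceedance(observed, draws)
  structure(list(statistic = statistic, observed = observed,
                 draws = draws, exceedance = exceedance,
                 n_iterations = length(draws),
                 n_requested = config$iterations,
                 dataset = dataset, refit = refit, config = config),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("null_result [%s, %s, %s]: observed = %.4g, %d draws in [%.4g, %.4g], exceedance = %.3g\n",
              x$statistic, x$dataset, x$refit, x$observed,
              x$n_iterations, min(x$draws), max(x$draws), x$exceedance))
  invisible(x)
}

#' Write null-model draws and summary to disk
#'
#' @param result A `null_result`.
#' @param draws_path Delimited-text path for (iteration, value) rows.
#' @param summary_path JSON path for the observed value, exceedance and
#'   configuration echo.
#' @return `result`, invisibly.
#' @export
write_null_result <- function(result, draws_path, summary_path) {
  stopifnot(inherits(result, "null_result"))
  write.csv(data.frame(iteration = seq_along(result$draws),
                       value = result$draws),
            draws_path, row.names = FALSE)
  jsonlite::write_json(
    list(statistic = result$statistic, observed = result$observed,
         exceedance = result$exceedance,
         n_iterations = result$n_iterations, dataset = result$dataset,
         refit = result$refit,
         config = result$config[c("iterations", "adult_mortality",
                                  "kernel_p", "default_height")]),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(result)
}
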