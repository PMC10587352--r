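#' Build the combined quadrat table for a set of censuses
#'
#' Filters each census to living main stems, delineates size classes,
#' and stacks the per-plot quadrat tables ([build_quadrat_table()]).
#'
#' @param censuses A [plot_census()] or list of them.
#' @param traits Assignment from [assign_mycorrhizal_type()].
#' @param kernel A [clark2dt()] kernel.
#' @param dataset `"CDD"` or `"CMDD"`.
#' @param min_quadrats Occupancy threshold for species retention.
#' @return Combined quadrat-table data.frame.
#' @export
prepare_quadrat_data <- function(censuses, traits, kernel,
                                 dataset = c("CDD", "CMDD"),
                                 min_quadrats = 10) {
  dataset <- match.arg(dataset)
  if (inherits(censuses, "plot_census")) censuses <- list(censuses)
  tabs <- lapply(censuses, function(cen) {
    f <- filter_stems(cen)
    build_quadrat_table(f, assign_size_classes(f), traits, kernel,
                        dataset = dataset, min_quadrats = min_quadrats)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Estimate species-by-site density-dependence effects
#'
#' Runs the estimation stage on a quadrat table: fits either the global
#' integrated model (default; retains every group through partial
#' pooling) or independent species-by-site models, selects the
#' standard-increment density window by the retention-maximising search,
#' and returns the per-species-by-site effect estimates.
#'
#' @param records Quadrat table from [prepare_quadrat_data()].
#' @param dataset `"CDD"` or `"CMDD"`.
#' @param method `"global"` or `"species"`.
#' @param increment Standard adult increment (default 1).
#' @param window Optional [select_window()] result; selected from the
#'   data when `NULL`. For the global model every group is retained and
#'   the window only anchors the (window-invariant) contrast.
#' @param engine,theta Passed to [fit_global_model()] /
#'   [fit_species_model()].
#' @return data.frame of effect estimates (`species`, `plot_id`,
#'   `kind`, `delta`, `se`, `mycorrhizal_type`, `window_start`), with
#'   the fitted model in attribute `"fit"` (global method) and the
#'   window in attribute `"window"`.
#' @export
estimate_effects <- function(records, dataset = c("CDD", "CMDD"),
                             method = c("global", "species"),
                             increment = 1, window = NULL,
                             engine = "auto", theta = NULL) {
  dataset <- match.arg(dataset)
  method <- match.arg(method)
  mode <- if (dataset == "CDD") "conspecific" else "conmycorrhizal"
  var <- if (dataset == "CDD") "A" else "M"
  if (is.null(window))
    window <- select_window(density_ranges(records, var), increment)
  if (method == "global") {
    gfit <- fit_global_model(records, dataset, theta = theta,
                             engine = engine)
    eff <- global_group_effects(gfit, window)
    attr(eff, "fit") <- gfit
  } else {
    groups <- split(records, records$group)
    rows <- lapply(names(groups), function(g) {
      rec <- groups[[g]]
      fit <- tryCatch(fit_species_model(rec, dataset, theta = theta),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$informative) return(NULL)
      dl <- tryCatch(percapita_delta(fit, window, mode = mode),
                     error = function(e) NULL)
      if (is.null(dl)) return(NULL)
      data.frame(species = rec$species[1L], plot_id = rec$plot_id[1L],
                 group = g, kind = dl$kind, delta = dl$delta,
                 se = dl$se, mycorrhizal_type = rec$mycorrhizal_type[1L],
                 window_start = dl$window_start,
                 converged = fit$converged)
    })
    eff <- do.call(rbind, rows)
    if (is.null(eff)) stop("no species-by-site model could be fitted")
    rownames(eff) <- NULL
  }
  attr(eff, "window") <- window
  eff
}

#' Attach site abundances to effect estimates
#'
#' @param effects Effect table from [estimate_effects()].
#' @param summaries List of [summarize_site()] results (one per plot).
#' @return `effects` with an `abundance` column (stems of the species at
#'   the site; NA when the species is absent from the summary).
#' @export
join_abundance <- function(effects, summaries) {
  ab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(plot_id = s$plot_id, species = s$abundance$species,
               abundance = s$abundance$n_stems)))
  i <- match(paste(effects$plot_id, effects$species),
             paste(ab$plot_id, ab$species))
  effects$abundance <- ab$abundance[i]
  effects
}

#' Site-level summary table for cross-site models
#'
#' One row per site: richness, EM proportions, coordinates and climate,
#' plus the abundance-weighted median CDD/CMDD when effects are given.
#'
#' @param censuses List of [plot_census()].
#' @param traits Assignment from [assign_mycorrhizal_type()].
#' @param effects Optional effect table (with `abundance`; see
#'   [join_abundance()]).
#' @return data.frame with one row per plot.
#' @export
build_site_table <- function(censuses, traits, effects = NULL) {
  if (inherits(censuses, "plot_census")) censuses <- list(censuses)
  summaries <- lapply(censuses, function(cen)
    summarize_site(filter_stems(cen, main_stems_only = FALSE), traits))
  out <- do.call(rbind, lapply(summaries, function(s)
    data.frame(plot_id = s$plot_id, latitude = s$latitude,
               mat = s$mat, map = s$map,
               species_richness = s$species_richness,
               proportion_EM_species = s$proportion_EM_species,
               proportion_EM_basal_area = s$proportion_EM_basal_area)))
  if (!is.null(effects)) {
    wm <- vapply(out$plot_id, function(p) {
      e <- effects[effects$plot_id == p & is.finite(effects$abundance), ]
      if (nrow(e) == 0L) return(NA_real_)
      weighted_median_cdd(e)
    }, 0)
    out$weighted_median_delta <- wm
  }
  rownames(out) <- NULL
  out
}
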