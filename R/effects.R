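#' Observed adult-density ranges per species-by-site
#'
#' @param records Quadrat table from [build_quadrat_table()].
#' @param var Density column whose range is wanted (`"A"` for the
#'   conspecific window, `"M"` for the conmycorrhizal window).
#' @return data.frame with `group`, `min`, `max`.
#' @export
density_ranges <- function(records, var = "A") {
  sp <- split(records[[var]], records$group)
  data.frame(group = names(sp),
             min = vapply(sp, min, 0),
             max = vapply(sp, max, 0), row.names = NULL)
}

#' Select the standard-increment density window retaining most species
#'
#' The effect of a standard increment (+1 adult by default) is evaluated
#' over a window `[a, a + increment]` of adult density. To predict only
#' where the data support it, the start `a` is chosen, over a fine grid,
#' to maximise the number of species-by-site groups whose observed
#' density range contains the whole window; ties go to the smallest
#' start. Fractional optima (e.g. a window like 0.067–1.067 conspecific
#' adults) arise naturally because densities are distance-weighted.
#'
#' @param ranges data.frame from [density_ranges()] (columns `min`,
#'   `max`, one row per group), or a list of length-2 ranges.
#' @param increment Window width in adults (default 1).
#' @param step Grid step in density units (default 0.001).
#' @return A list of class `density_window`: `start`, `end`,
#'   `increment`, `n_retained`.
#' @export
select_window <- function(ranges, increment = 1, step = 0.001) {
  if (!is.data.frame(ranges))
    ranges <- data.frame(min = vapply(ranges, `[`, 0, 1L),
                         max = vapply(ranges, `[`, 0, 2L))
  if (increment <= 0) stop("increment must be positive")
  lo <- min(ranges$min)
  hi <- max(ranges$max) - increment
  if (hi < lo) stop("no window of width ", increment,
                    " fits inside any observed density range")
  grid <- seq(lo, hi, by = step)
  # retained(a) = #(min <= a) - #(max < a + increment), via sorted ECDFs
  smin <- sort(ranges$min)
  smax <- sort(ranges$max)
  n_lo <- findInterval(grid, smin)                       # min_i <= a
  n_hi <- findInterval(grid + increment, smax, left.open = TRUE)
  retained <- n_lo - n_hi
  if (max(retained) <= 0)
    stop("no window of width ", increment,
         " is contained in any species' observed density range")
  best <- which.max(retained)                            # first max = smallest a
  structure(list(start = grid[best], end = grid[best] + increment,
                 increment = increment,
                 n_retained = retained[best]),
            class = "density_window")
}

#' @export
print.density_window <- function(x, ...) {
  cat(sprintf("density window [%.3f, %.3f] (+%g adults), retains %d group(s)\n",
              x$start, x$end, x$increment, x$n_retained))
  invisible(x)
}

#' Change in per-capita sapling density for a standard adult increment
#'
#' Computes the log-ratio change in per-capita sapling density (PCS,
#' predicted saplings divided by conspecific adult density) when the
#' focal density increases by the window increment, relative to the same
#' increment applied to the reference heterospecific density, all other
#' densities held fixed:
#' \deqn{\Delta = [\log PCS(x_0 + i) - \log PCS(x_0)]_{focal}
#'              - [\log PCS(x_0 + i) - \log PCS(x_0)]_{reference}}
#' For `mode = "conspecific"` (CDD) the focal density is the conspecific
#' `A` and the reference is the heterospecific density (`H`, or `M` and
#' `HMH` jointly in species-specific proportions for a CMDD-form fit).
#' For `mode = "conmycorrhizal"` (CMDD) the focal density is the
#' conmycorrhizal heterospecific `M` and the reference the
#' heteromycorrhizal `HMH`. Under the log-linear Ricker form the
#' contrast is independent of the window start and of the held
#' densities, and reduces to `increment * (c - d)` for CDD and
#' `increment * (d - f)` for CMDD; it is nevertheless evaluated through
#' model predictions so that the same contract extends to non-parametric
#' fits. The standard error follows from the delta method on the
#' coefficient covariance.
#'
#' @param fit A converged `ricker_fit`.
#' @param window A `density_window` from [select_window()].
#' @param held Optional named list of held densities (`A`, `H`, `M`,
#'   `HMH`); defaults to zero — irrelevant under the log-linear model.
#' @param mode `"conspecific"` or `"conmycorrhizal"`.
#' @return One-row data.frame: `kind`, `delta`, `se`, `window_start`,
#'   `increment`.
#' @export
percapita_delta <- function(fit, window,
                            held = NULL,
                            mode = c("conspecific", "conmycorrhizal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "ricker_fit"), inherits(window, "density_window"))
  if (!fit$informative) stop("fit is uninformative; no effect estimate")
  cmdd <- !is.null(fit$f)
  if (mode == "conmycorrhizal" && !cmdd)
    stop("conmycorrhizal mode requires a CMDD-form fit (with M and HMH)")
  h <- list(A = 0, H = 0, M = 0, HMH = 0)
  h[names(held)] <- held
  a0 <- window$start
  inc <- window$increment
  lpcs <- function(A, H, M, HMH) {
    if (A <= 0) stop("per-capita density undefined at A = 0")
    log(predict_saplings(fit, A = A, H = H, M = M, HMH = HMH) / A)
  }
  base_A <- max(h$A, a0)
  if (mode == "conspecific") {
    lr_focal <- lpcs(a0 + inc, h$H, h$M, h$HMH) - lpcs(a0, h$H, h$M, h$HMH)
    if (!cmdd) {
      lr_ref <- lpcs(base_A, h$H + inc, h$M, h$HMH) -
        lpcs(base_A, h$H, h$M, h$HMH)
      grad <- c(r = 0, c = inc, d = -inc)
    } else {
      # +increment of generic heterospecific adults split into the
      # observed conmycorrhizal/heteromycorrhizal proportions
      tot <- h$M + h$HMH
      pm <- if (tot > 0) h$M / tot else 0.5
      lr_ref <- lpcs(base_A, 0, h$M + inc * pm, h$HMH + inc * (1 - pm)) -
        lpcs(base_A, 0, h$M, h$HMH)
      grad <- c(r = 0, c = inc, d = -inc * pm, f = -inc * (1 - pm))
    }
  } else {
    lr_focal <- lpcs(base_A, 0, a0 + inc, h$HMH) - lpcs(base_A, 0, a0, h$HMH)
    lr_ref <- lpcs(base_A, 0, a0, h$HMH + inc) - lpcs(base_A, 0, a0, h$HMH)
    grad <- c(r = 0, c = 0, d = inc, f = -inc)
  }
  delta <- lr_focal - lr_ref
  if (!is.finite(delta)) stop("non-finite per-capita contrast (window [",
                              a0, ", ", a0 + inc, "])")
  vc <- fit$vcov
  g <- grad[colnames(vc)]
  se <- sqrt(drop(t(g) %*% vc %*% g))
  data.frame(kind = if (mode == "conspecific") "CDD" else "CMDD",
             delta = delta, se = se, window_start = a0, increment = inc)
}

#' Species-by-site effect estimates from the global integrated model
#'
#' Extracts, for every species-by-site group, the change in per-capita
#' sapling density for the window increment: for a CDD fit the group's
#' effective conspecific slope (`c_type` + random slope) against the
#' type's heterospecific slope, `increment * (c_g - d_type)`; for a CMDD
#' fit the type-level conmycorrhizal against heteromycorrhizal slope,
#' `increment * (d_type - f_type)`. Standard errors come from the
#' model's coefficient covariance (delta method on the contrast).
#'
#' @param gfit A `global_fit`.
#' @param window A `density_window`.
#' @return data.frame with `species`, `plot_id`, `group`, `kind`,
#'   `delta`, `se`, `mycorrhizal_type`, `window_start`.
#' @export
global_group_effects <- function(gfit, window) {
  stopifnot(inherits(gfit, "global_fit"), inherits(window, "density_window"))
  V <- vcov(gfit$model)
  nms <- colnames(V)
  inc <- window$increment
  g <- gfit$groups
  kind <- if (gfit$dataset == "CDD") "CDD" else "CMDD"
  delta <- se <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    tp <- g$mycorrhizal_type[i]
    if (gfit$dataset == "CDD") {
      iA <- match(global_fixed_name(nms, "A", tp), nms)
      iH <- match(global_fixed_name(nms, "H", tp), nms)
      ib <- g$coef_b1[i]
      delta[i] <- inc * (g$c[i] - g$d[i])
      v <- V[iA, iA] + V[ib, ib] + V[iH, iH] +
        2 * V[iA, ib] - 2 * V[iA, iH] - 2 * V[ib, iH]
    } else {
      iM <- match(global_fixed_name(nms, "M", tp), nms)
      iF <- match(global_fixed_name(nms, "HMH", tp), nms)
      delta[i] <- inc * (g$d[i] - g$f[i])
      v <- V[iM, iM] + V[iF, iF] - 2 * V[iM, iF]
    }
    se[i] <- inc * sqrt(max(v, 0))
  }
  data.frame(species = g$species, plot_id = g$plot_id, group = g$group,
             kind = kind, delta = delta, se = se,
             mycorrhizal_type = g$mycorrhizal_type,
             window_start = window$start, row.names = NULL)
}

#' Mycorrhizal-type prediction curves from the global model
#'
#' Per-capita sapling density as a function of conspecific (CDD) or
#' conmycorrhizal (CMDD) adult density for each mycorrhizal type, with
#' other fixed effects held at their observed means and the
#' species-by-site random intercepts and slopes excluded. Pointwise
#' intervals are normal on the log scale (fixed-effect covariance only).
#'
#' @param gfit A `global_fit`.
#' @param grid Density grid; defaults to 100 points over the observed
#'   conspecific range. A grid beyond the observed support triggers a
#'   warning.
#' @param scale_to_max Scale each type's curve to its maximum (so the
#'   maximum is 1), easing cross-type comparison of shapes.
#' @param level Interval level, default 0.95.
#' @return data.frame with `type`, `density`, `pcs`, `lower`, `upper`.
#' @export
global_prediction_curves <- function(gfit, grid = NULL,
                                     scale_to_max = FALSE, level = 0.95) {
  stopifnot(inherits(gfit, "global_fit"))
  if (is.null(grid)) grid <- seq(0, gfit$max_A, length.out = 100)
  if (max(grid) > gfit$max_A + 1e-9)
    warning("prediction grid extends beyond the observed density support")
  V <- vcov(gfit$model)
  nms <- colnames(V)
  z <- qnorm(1 - (1 - level) / 2)
  cmdd <- gfit$dataset == "CMDD"
  out <- do.call(rbind, lapply(seq_len(nrow(gfit$fixed)), function(k) {
    fx <- gfit$fixed[k, ]
    if (!cmdd) {
      lp <- fx$r + fx$c * grid + fx$d * gfit$mean_H
      ii <- match(c(global_fixed_name(nms, NULL, fx$type),
                    global_fixed_name(nms, "A", fx$type),
                    global_fixed_name(nms, "H", fx$type)), nms)
      X <- cbind(1, grid, gfit$mean_H)
    } else {
      # CMDD curves vary the conmycorrhizal density M
      lp <- fx$r + fx$c * gfit$mean_A + fx$d * grid + fx$f * gfit$mean_HMH
      ii <- match(c(global_fixed_name(nms, NULL, fx$type),
                    global_fixed_name(nms, "A", fx$type),
                    global_fixed_name(nms, "M", fx$type),
                    global_fixed_name(nms, "HMH", fx$type)), nms)
      X <- cbind(1, gfit$mean_A, grid, gfit$mean_HMH)
    }
    se <- sqrt(pmax(rowSums((X %*% V[ii, ii]) * X), 0))
    data.frame(type = fx$type, density = grid, pcs = exp(lp),
               lower = exp(lp - z * se), upper = exp(lp + z * se))
  }))
  if (scale_to_max) {
    for (tp in unique(out$type)) {
      sel <- out$type == tp
      m <- max(out$pcs[sel])
      out$pcs[sel] <- out$pcs[sel] / m
      out$lower[sel] <- out$lower[sel] / m
      out$upper[sel] <- out$upper[sel] / m
    }
  }
  rownames(out) <- NULL
  out
}
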