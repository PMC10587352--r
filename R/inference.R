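#' Weighted median (lower-median convention)
#'
#' Smallest value whose cumulative weight reaches half the total weight.
#' With equal weights this reproduces the lower sample median (and the
#' ordinary sample median for odd sample sizes).
#'
#' @param x Numeric values.
#' @param w Positive weights, same length as `x`.
#' @return A single value from `x`.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  if (length(x) == 0L) stop("empty input")
  if (length(w) != length(x)) stop("weights must match values in length")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  o <- order(x)
  x <- x[o]
  w <- w[o]
  x[which(cumsum(w) >= sum(w) / 2)[1L]]
}

#' Abundance-weighted median effect for one site
#'
#' Site-level summary of species-by-site effect estimates: the weighted
#' median of the deltas, weighting each species by the natural log of
#' its abundance at the site.
#'
#' @param effects Effect estimates for one site (data.frame with
#'   `delta`; `abundance` column used unless `abundances` is given).
#' @param abundances Optional abundance vector aligned with `effects`
#'   rows; all values must be >= 1 so log-weights are positive (a
#'   species present once would get zero weight under ln, so abundance 1
#'   is weighted as ln(2)).
#' @return The weighted median delta.
#' @export
weighted_median_cdd <- function(effects, abundances = NULL) {
  if (is.null(abundances)) abundances <- effects$abundance
  if (is.null(abundances)) stop("no abundances available")
  if (nrow(effects) == 0L) stop("empty input")
  if (any(!is.finite(abundances)) || any(abundances < 1))
    stop("abundances must be >= 1")
  weighted_median(effects$delta, log(pmax(abundances, 2)))
}

new_contrast_result <- function(name, estimate, se, statistic, p_value,
                                mode, n, degenerate = FALSE) {
  structure(list(name = name, estimate = estimate, se = se,
                 statistic = statistic, p_value = p_value,
                 mode = mode, n = n, degenerate = degenerate),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s [%s, n = %d]: estimate = %.4g (se %.3g), stat = %.3g, p = %.3g%s\n",
              x$name, x$mode, x$n, x$estimate, x$se, x$statistic,
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Mycorrhizal-type contrast on effect estimates
#'
#' Tests whether species-by-site CDD (or CMDD) estimates differ between
#' AM and EM tree species. `mode = "site_random"` fits a linear mixed
#' model of delta on type with a site-level random intercept (REML);
#' with a single site this degenerates to ordinary regression (logged).
#' `mode = "site_interaction"` fits type-by-site fixed effects and
#' reports the AM-EM contrast marginal over sites (equal site weights).
#'
#' @param effects data.frame with `delta`, `mycorrhizal_type`, `plot_id`.
#' @param mode `"site_random"` or `"site_interaction"`.
#' @return A `contrast_result` with the AM minus EM estimate.
#' @export
type_contrast <- function(effects,
                          mode = c("site_random", "site_interaction")) {
  mode <- match.arg(mode)
  eff <- as.data.frame(effects)
  eff$myco <- factor(eff$mycorrhizal_type, levels = c("AM", "EM"))
  if (any(is.na(eff$myco))) stop("mycorrhizal_type must be AM or EM")
  if (nlevels(droplevels(eff$myco)) < 2L)
    stop("both mycorrhizal types are required for a type contrast")
  eff$site <- factor(eff$plot_id)
  one_site <- nlevels(eff$site) < 2L
  if (one_site)
    mycodd_log("single site: ", mode, " reduces to ordinary regression")
  if (mode == "site_random" && !one_site) {
    fit <- suppressMessages(
      lmerTest::lmer(delta ~ myco + (1 | site), data = eff))
    sm <- summary(fit)$coefficients
    est <- -sm["mycoEM", "Estimate"]        # AM - EM
    se <- sm["mycoEM", "Std. Error"]
    tv <- -sm["mycoEM", "t value"]
    pv <- sm["mycoEM", "Pr(>|t|)"]
  } else if (mode == "site_interaction" && !one_site) {
    fit <- lm(delta ~ myco * site, data = eff)
    em <- suppressMessages(emmeans::emmeans(fit, ~myco))
    # marginal AM - EM contrast with equal site weights
    ct <- as.data.frame(suppressMessages(
      emmeans::contrast(em, method = list("AM - EM" = c(1, -1)))))
    est <- ct$estimate[1L]
    se <- ct$SE[1L]
    tv <- ct$t.ratio[1L]
    pv <- ct$p.value[1L]
  } else {
    fit <- lm(delta ~ myco, data = eff)
    sm <- summary(fit)$coefficients
    est <- -sm["mycoEM", "Estimate"]
    se <- sm["mycoEM", "Std. Error"]
    tv <- -sm["mycoEM", "t value"]
    pv <- sm["mycoEM", "Pr(>|t|)"]
  }
  new_contrast_result("AM - EM", est, se, tv, pv, mode, nrow(eff))
}

#' One-sample test of effect estimates against zero
#'
#' Student t test of the deltas for one mycorrhizal type against zero.
#' An exactly constant input has no sampling variance and is reported as
#' degenerate (p = 1 at zero, p = 0 otherwise) rather than producing an
#' undefined statistic.
#'
#' @param effects data.frame with `delta` (>= 2 rows).
#' @return A `contrast_result`.
#' @export
mean_vs_zero <- function(effects) {
  d <- if (is.data.frame(effects)) effects$delta else effects
  if (length(d) < 2L) stop("at least two estimates are required")
  if (sd(d) == 0) {
    return(new_contrast_result("mean vs 0", mean(d), 0,
                               if (mean(d) == 0) 0 else Inf,
                               if (mean(d) == 0) 1 else 0,
                               "t_test", length(d), degenerate = TRUE))
  }
  tt <- t.test(d, mu = 0)
  new_contrast_result("mean vs 0", unname(tt$estimate),
                      unname(tt$stderr), unname(tt$statistic),
                      tt$p.value, "t_test", length(d))
}

#' Single-predictor site-level model
#'
#' Ordinary least squares of a site-level response (e.g. the
#' abundance-weighted median CDD, species richness, or the proportion of
#' EM species) on exactly one predictor. Predictors are deliberately fit
#' one at a time: typical site covariates (latitude, temperature,
#' precipitation, EM proportion) are strongly collinear.
#'
#' @param sites data.frame with one row per site.
#' @param response Name of the response column.
#' @param predictor Name of the predictor column (e.g. `"latitude"`,
#'   `"mat"`, `"map"`, `"proportion_EM_species"`).
#' @return A `contrast_result` holding the slope.
#' @export
site_level_model <- function(sites, response, predictor) {
  x <- as.data.frame(sites)
  if (!response %in% names(x)) stop("unknown response: ", response)
  if (!predictor %in% names(x)) stop("unknown predictor: ", predictor)
  x <- x[is.finite(x[[response]]) & is.finite(x[[predictor]]), ]
  if (nrow(x) < 3L) stop("at least three sites are required")
  if (sd(x[[predictor]]) == 0) stop("constant predictor: ", predictor)
  fit <- lm(as.formula(paste(response, "~", predictor)), data = x)
  sm <- summary(fit)$coefficients
  new_contrast_result(paste0(response, " ~ ", predictor),
                      sm[2L, "Estimate"], sm[2L, "Std. Error"],
                      sm[2L, "t value"], sm[2L, "Pr(>|t|)"],
                      "ols", nrow(x))
}
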