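#' Predicted sapling density under the Ricker recruitment model
#'
#' Evaluates the Ricker-form mean: for the conspecific/heterospecific
#' (CDD) parameterisation `S = A * exp(r + c*A + d*H)`, and for the
#' mycorrhizal (CMDD) split `S = A * exp(r + c*A + d*M + f*HMH)`, where
#' `A` is distance-weighted conspecific adult density, `H` all
#' heterospecific, `M` conmycorrhizal heterospecific and `HMH`
#' heteromycorrhizal heterospecific adult density. The prediction is
#' exactly 0 at `A = 0` (no conspecific adults, no per-capita basis).
#'
#' @param coefs A `ricker_fit` (from [fit_species_model()]) or any list
#'   with elements `r`, `c`, `d` and, for the CMDD form, `f`.
#' @param A,H,M,HMH Adult densities (vectorised).
#' @return Expected sapling density per quadrat.
#' @export
predict_saplings <- function(coefs, A, H = 0, M = 0, HMH = 0) {
  cmdd <- !is.null(coefs$f) && !is.na(coefs$f)
  eta <- coefs$r + coefs$c * A +
    if (cmdd) coefs$d * M + coefs$f * HMH else coefs$d * H
  out <- A * exp(eta)
  out[A == 0] <- 0
  out
}

# NB log-likelihood of a parameter vector on a quadrat table; shared
# definition used by fits and by the brute-force oracle in the tests
#' Negative-binomial Ricker log-likelihood
#'
#' Sum of NB log-densities of the sapling counts `S` with mean
#' `A * exp(r + c*A + d*H)` (or the CMDD form) and dispersion `theta`.
#'
#' @param params List or named vector with `r`, `c`, `d` (`f` for CMDD)
#'   and `theta`.
#' @param records Quadrat table rows (needs `S`, `A`, `H` or `M`/`HMH`).
#' @param dataset `"CDD"` or `"CMDD"`.
#' @return Log-likelihood (scalar).
#' @export
ricker_loglik <- function(params, records, dataset = c("CDD", "CMDD")) {
  dataset <- match.arg(dataset)
  p <- as.list(params)
  eta <- p$r + p$c * records$A +
    if (dataset == "CMDD") p$d * records$M + p$f * records$HMH
    else p$d * records$H
  mu <- records$A * exp(eta)
  sum(dnbinom(records$S, size = p$theta, mu = mu, log = TRUE))
}

#' Fit the Ricker recruitment model for one species-by-site
#'
#' Negative-binomial GLM with log link and offset `log(A)`: the linear
#' predictor of `S` is `log(A) + r + c*A + d*H` (CDD) or
#' `log(A) + r + c*A + d*M + f*HMH` (CMDD), which maximises the NB
#' likelihood of the Ricker form. Dispersion `theta` is estimated by
#' maximum likelihood (alternating with the coefficient updates) unless
#' supplied. Non-convergence is flagged on the returned object, never
#' silently dropped.
#'
#' @param records Quadrat table rows for one species-by-site (from
#'   [build_quadrat_table()]).
#' @param dataset `"CDD"` or `"CMDD"` (selects the heterospecific
#'   terms).
#' @param theta Optional fixed NB dispersion; estimated when `NULL`.
#' @return Object of class `ricker_fit`: coefficients `r`, `c`, `d`
#'   (`f` for CMDD), `theta`, `vcov` (named, conditional on `theta`),
#'   `loglik`, `n`, and flags `converged` and `informative`. All-zero
#'   responses yield an uninformative flagged fit with NA coefficients.
#'   A constant conspecific density is a singular design and errors.
#' @export
fit_species_model <- function(records, dataset = c("CDD", "CMDD"),
                              theta = NULL) {
  dataset <- match.arg(dataset)
  x <- as.data.frame(records)
  nm <- if (dataset == "CDD") c("r", "c", "d") else c("r", "c", "d", "f")
  if (nrow(x) == 0L || all(x$S == 0)) {
    return(structure(list(r = NA_real_, c = NA_real_, d = NA_real_,
                          f = if (dataset == "CMDD") NA_real_ else NULL,
                          theta = NA_real_, vcov = NULL,
                          loglik = NA_real_, n = nrow(x),
                          dataset = dataset, converged = FALSE,
                          informative = FALSE, model = NULL),
                     class = "ricker_fit"))
  }
  if (sd(x$A) < 1e-12)
    stop("singular design: conspecific adult density is constant")
  x$log_A <- log(x$A)
  form <- if (dataset == "CDD") S ~ A + H + offset(log_A)
          else S ~ A + M + HMH + offset(log_A)
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 200)
  warned <- FALSE
  muffle <- function(w) {
    warned <<- TRUE
    invokeRestart("muffleWarning")
  }
  theta_used <- theta
  if (is.null(theta)) {
    fit <- withCallingHandlers(
      tryCatch(MASS::glm.nb(form, data = x, control = ctrl),
               error = function(e) NULL),
      warning = muffle)
    if (is.null(fit)) {
      # theta ML diverged (near-Poisson counts): quasi-Poisson limit
      # with a large fixed dispersion, flagged as non-converged
      warned <- TRUE
      theta_used <- 1e6
      fit <- withCallingHandlers(
        stats::glm(form, data = x,
                   family = MASS::negative.binomial(theta_used),
                   control = ctrl),
        warning = muffle)
    } else theta_used <- fit$theta
  } else {
    fit <- withCallingHandlers(
      stats::glm(form, data = x,
                 family = MASS::negative.binomial(theta), control = ctrl),
      warning = muffle)
  }
  cf <- coef(fit)
  if (any(is.na(cf)) || length(cf) != length(nm))
    stop("singular design: collinear density predictors")
  vc <- vcov(fit)
  dimnames(vc) <- list(nm, nm)
  th <- theta_used
  pars <- as.list(setNames(cf, nm))
  pars$theta <- th
  structure(list(r = pars$r, c = pars$c, d = pars$d,
                 f = if (dataset == "CMDD") pars$f else NULL,
                 theta = th, vcov = vc,
                 loglik = ricker_loglik(pars, x, dataset),
                 n = nrow(x), dataset = dataset,
                 converged = isTRUE(fit$converged) && !warned,
                 informative = TRUE, model = fit),
            class = "ricker_fit")
}

#' @export
print.ricker_fit <- function(x, ...) {
  if (!x$informative) {
    cat("ricker_fit: uninformative (all-zero response)\n")
    return(invisible(x))
  }
  cat(sprintf("ricker_fit (%s, n = %d): r = %.4g, c = %.4g, d = %.4g",
              x$dataset, x$n, x$r, x$c, x$d))
  if (!is.null(x$f)) cat(sprintf(", f = %.4g", x$f))
  cat(sprintf(", theta = %.4g%s\n", x$theta,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# locate a fixed-effect column for a density term and mycorrhizal level
# robustly against R's interaction naming order
global_fixed_name <- function(cf_names, var, level) {
  cand <- if (is.null(var)) paste0("myco", level)
          else c(paste0(var, ":myco", level), paste0("myco", level, ":", var))
  hit <- cf_names[cf_names %in% cand]
  if (length(hit) != 1L)
    stop("cannot locate fixed effect for ", var %||% "intercept",
         " x ", level)
  hit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the global integrated recruitment model
#'
#' One penalised NB regression over all species-by-site groups:
#' type-specific fixed intercepts and density slopes (an interaction of
#' each density with mycorrhizal type), plus independent Gaussian random
#' intercepts and random slopes on conspecific density `A` for every
#' species-by-site group, with offset `log(A)` and log link. Random
#' effects are ridge penalties whose variance components are selected by
#' Laplace-approximate restricted marginal likelihood (mgcv's `fREML`
#' for `bam`, `REML` for `gam`); the random intercept and slope are
#' penalised independently (diagonal random-effects covariance).
#'
#' @param records Quadrat table (all plots) from [build_quadrat_table()];
#'   needs both mycorrhizal types and at least two groups.
#' @param dataset `"CDD"` (`H` term) or `"CMDD"` (`M` and `HMH` terms).
#' @param theta Optional fixed NB dispersion; estimated when `NULL`.
#' @param sp Optional fixed smoothing parameters (length 2: random
#'   intercept, random slope); `c(0, 0)` turns shrinkage off.
#' @param engine `"auto"` (bam for large tables, gam otherwise),
#'   `"bam"` or `"gam"`.
#' @return Object of class `global_fit`: `fixed` (per-type `r`, `c`,
#'   `d`, `f`), `groups` (per species-by-site effective coefficients
#'   `r = r_type + b0`, `c = c_type + b1`, plus the type-level `d`/`f`),
#'   `vcomp` (random-effect standard deviations), `theta`, `model`.
#' @export
fit_global_model <- function(records, dataset = c("CDD", "CMDD"),
                             theta = NULL, sp = NULL,
                             engine = c("auto", "bam", "gam")) {
  dataset <- match.arg(dataset)
  engine <- match.arg(engine)
  x <- as.data.frame(records)
  x$group <- factor(x$group)
  if (nlevels(x$group) < 2L)
    stop("at least two species-by-site groups are required")
  x$myco <- droplevels(factor(x$mycorrhizal_type, levels = c("AM", "EM")))
  if (nlevels(x$myco) < 2L)
    stop("only one mycorrhizal type present: the type contrast of the ",
         "global model is unavailable")
  x$log_A <- log(x$A)
  form <- if (dataset == "CDD")
    S ~ 0 + myco + A:myco + H:myco +
      s(group, bs = "re") + s(group, A, bs = "re") + offset(log_A)
  else
    S ~ 0 + myco + A:myco + M:myco + HMH:myco +
      s(group, bs = "re") + s(group, A, bs = "re") + offset(log_A)
  fam <- if (is.null(theta)) mgcv::nb() else mgcv::negbin(theta)
  if (engine == "auto") engine <- if (nrow(x) >= 20000) "bam" else "gam"
  fit <- if (engine == "bam")
    mgcv::bam(form, data = x, family = fam, discrete = TRUE,
              sp = sp, nthreads = 1)
  else
    mgcv::gam(form, data = x, family = fam, method = "REML", sp = sp)

  cf <- coef(fit)
  nms <- names(cf)
  types <- levels(x$myco)
  fixed <- do.call(rbind, lapply(types, function(tp) {
    data.frame(type = tp,
               r = unname(cf[global_fixed_name(nms, NULL, tp)]),
               c = unname(cf[global_fixed_name(nms, "A", tp)]),
               d = unname(cf[global_fixed_name(
                 nms, if (dataset == "CDD") "H" else "M", tp)]),
               f = if (dataset == "CMDD")
                 unname(cf[global_fixed_name(nms, "HMH", tp)])
               else NA_real_)
  }))

  sm_terms <- lapply(fit$smooth, function(s) s$term)
  i_b0 <- which(vapply(sm_terms, function(tm) setequal(tm, "group"), TRUE))
  i_b1 <- which(vapply(sm_terms, function(tm) setequal(tm, c("group", "A")),
                       TRUE))
  idx_b0 <- fit$smooth[[i_b0]]$first.para:fit$smooth[[i_b0]]$last.para
  idx_b1 <- fit$smooth[[i_b1]]$first.para:fit$smooth[[i_b1]]$last.para
  glv <- levels(x$group)
  meta <- unique(x[, c("group", "plot_id", "species", "mycorrhizal_type")])
  meta <- meta[match(glv, meta$group), ]
  fi <- match(meta$mycorrhizal_type, fixed$type)
  groups <- data.frame(
    group = glv, plot_id = meta$plot_id, species = meta$species,
    mycorrhizal_type = meta$mycorrhizal_type,
    b0 = unname(cf[idx_b0]), b1 = unname(cf[idx_b1]),
    r = fixed$r[fi] + unname(cf[idx_b0]),
    c = fixed$c[fi] + unname(cf[idx_b1]),
    d = fixed$d[fi], f = fixed$f[fi],
    coef_b1 = idx_b1, row.names = NULL)

  vcomp <- tryCatch({
    vc <- NULL
    utils::capture.output(vc <- mgcv::gam.vcomp(fit, rescale = TRUE))
    if (is.matrix(vc)) setNames(vc[, 1], rownames(vc)) else vc
  }, error = function(e) NULL)
  th <- if (is.null(theta)) fit$family$getTheta(TRUE) else theta

  structure(list(model = fit, dataset = dataset, fixed = fixed,
                 groups = groups, vcomp = vcomp, theta = th,
                 engine = engine,
                 converged = isTRUE(fit$converged) || is.null(fit$converged),
                 mean_A = mean(x$A), max_A = max(x$A),
                 mean_H = if (is.null(x$H)) NA_real_ else mean(x$H),
                 mean_M = if (is.null(x$M)) NA_real_ else mean(x$M),
                 mean_HMH = if (is.null(x$HMH)) NA_real_ else mean(x$HMH)),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("global_fit (%s, %s): %d species-by-site groups, theta = %.3g\n",
              x$dataset, x$engine, nrow(x$groups), x$theta))
  print(x$fixed, row.names = FALSE)
  invisible(x)
}
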