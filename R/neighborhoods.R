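#' Quadrat grid of a plot
#'
#' Quadrats tile the plot from the south-west corner; stem membership
#' uses half-open intervals `[k*q, (k+1)*q)`. Trailing partial quadrats
#' (when an extent is not a multiple of the quadrat size) are retained
#' with their true, smaller rectangle.
#'
#' @param census A [plot_census()].
#' @return data.frame with 0-based `qrow`, `qcol` and rectangle bounds
#'   `x0`, `x1`, `y0`, `y1` (m).
#' @export
quadrat_grid <- function(census) {
  q <- census$quadrat_size
  nqx <- ceiling(census$x_extent / q - 1e-9)
  nqy <- ceiling(census$y_extent / q - 1e-9)
  g <- expand.grid(qcol = seq_len(nqx) - 1L, qrow = seq_len(nqy) - 1L)
  data.frame(qrow = g$qrow, qcol = g$qcol,
             x0 = g$qcol * q, x1 = pmin((g$qcol + 1) * q, census$x_extent),
             y0 = g$qrow * q, y1 = pmin((g$qrow + 1) * q, census$y_extent))
}

# Q x N matrix of kernel weights: adults inside a quadrat get weight 1;
# outside, the Clark 2Dt weight of the Euclidean distance from the stem
# to the nearest point of the quadrat rectangle (weights join
# continuously at the edge because the kernel is 1 at distance 0)
quadrat_weight_matrix <- function(grid, x, y, kernel) {
  dx <- pmax(outer(grid$x0, x, `-`), outer(-grid$x1, x, `+`), 0)
  dy <- pmax(outer(grid$y0, y, `-`), outer(-grid$y1, y, `+`), 0)
  kernel_weight(sqrt(dx^2 + dy^2), kernel)
}

#' Distance-weighted adult density around one quadrat
#'
#' Sums kernel weights over the adults of a neighbour group: weight 1
#' inside the focal quadrat, Clark 2Dt weight of the distance to the
#' quadrat edge outside. Groups: `conspecific` (adults of the focal
#' species), `heterospecific` (all other typed species), `CMH`
#' (heterospecifics of the focal species' mycorrhizal type), `HMH`
#' (heterospecifics of the other type).
#'
#' @param census A [plot_census()] (living analysis stems).
#' @param assignments Size classes from [assign_size_classes()].
#' @param traits Assignment from [assign_mycorrhizal_type()]; needed for
#'   the mycorrhizal groups.
#' @param species Focal species.
#' @param qrow,qcol 0-based quadrat indices.
#' @param kernel A [clark2dt()] kernel.
#' @param group One of `"conspecific"`, `"heterospecific"`, `"CMH"`, `"HMH"`.
#' @return A single non-negative density (weighted adult count).
#' @export
weighted_adult_density <- function(census, assignments, traits, species,
                                   qrow, qcol, kernel,
                                   group = c("conspecific", "heterospecific",
                                             "CMH", "HMH")) {
  group <- match.arg(group)
  stems <- census$stems
  cutoff <- assignments$sapling_cutoff[match(stems$species,
                                             assignments$species)]
  adults <- stems[!is.na(cutoff) & stems$dbh >= cutoff, , drop = FALSE]
  type <- traits$mycorrhizal_type[match(adults$species, traits$species)]
  focal_type <- traits$mycorrhizal_type[traits$species == species]
  keep <- switch(group,
    conspecific = adults$species == species,
    heterospecific = adults$species != species & type %in% c("AM", "EM"),
    CMH = adults$species != species & !is.na(type) & length(focal_type) &
      type == focal_type[1],
    HMH = adults$species != species & type %in% c("AM", "EM") &
      length(focal_type) & type != focal_type[1])
  adults <- adults[keep, , drop = FALSE]
  if (nrow(adults) == 0L) return(0)
  q <- census$quadrat_size
  grid <- data.frame(qrow = qrow, qcol = qcol,
                     x0 = qcol * q, x1 = min((qcol + 1) * q, census$x_extent),
                     y0 = qrow * q, y1 = min((qrow + 1) * q, census$y_extent))
  sum(quadrat_weight_matrix(grid, adults$x, adults$y, kernel))
}

#' Per-quadrat, per-species response and neighbourhood densities
#'
#' Builds the model table: one row per retained species x quadrat with
#' the sapling count `S` and the distance-weighted adult densities `A`
#' (conspecific), `H` (all heterospecific), `M` (conmycorrhizal
#' heterospecific) and `HMH` (heteromycorrhizal heterospecific), so that
#' `H = M + HMH`. Heterospecific neighbour pools contain adults of every
#' strictly typed (AM/EM) species; species without a strict type are
#' excluded from the analysis entirely.
#'
#' A species is retained as a response only if its saplings and its
#' adults each occur in at least `min_quadrats` quadrats. For
#' `dataset = "CMDD"`, a plot whose retained species are all of one
#' mycorrhizal type is dropped entirely (zero rows, logged), because
#' conmycorrhizal density dependence is not estimable there.
#'
#' Conspecific densities below `floor` are floored to `floor` so that
#' the model offset `log(A)` is always defined; the heterospecific
#' densities enter only as linear covariates and are left exact (so
#' `H = M + HMH` holds to machine precision).
#'
#' @param census A [plot_census()] filtered to living main stems.
#' @param assignments Size classes from [assign_size_classes()].
#' @param traits Assignment from [assign_mycorrhizal_type()].
#' @param kernel A [clark2dt()] kernel.
#' @param dataset `"CDD"` (full) or `"CMDD"` (mixed-type plots only).
#' @param min_quadrats Occupancy threshold for species retention
#'   (default 10).
#' @param floor Density floor (default 1e-12).
#' @return data.frame with columns `plot_id`, `qrow`, `qcol`, `species`,
#'   `S`, `A`, `H`, `M`, `HMH`, `mycorrhizal_type`, `group`
#'   (plot:species label used as the random-effect grouping factor).
#' @export
build_quadrat_table <- function(census, assignments, traits, kernel,
                                dataset = c("CDD", "CMDD"),
                                min_quadrats = 10, floor = 1e-12) {
  dataset <- match.arg(dataset)
  stopifnot(inherits(census, "plot_census"))
  stems <- census$stems
  empty <- data.frame(plot_id = character(), qrow = integer(),
                      qcol = integer(), species = character(),
                      S = integer(), A = numeric(), H = numeric(),
                      M = numeric(), HMH = numeric(),
                      mycorrhizal_type = character(), group = character())
  if (nrow(stems) == 0L) return(empty)
  type <- traits$mycorrhizal_type[match(stems$species, traits$species)]
  typed <- !is.na(type) & type %in% c("AM", "EM")
  if (any(!typed))
    mycodd_log("plot ", census$plot_id, ": ",
               length(unique(stems$species[!typed])),
               " untyped species removed from the analysis")
  stems <- stems[typed, , drop = FALSE]
  type <- type[typed]
  if (nrow(stems) == 0L) return(empty)
  cutoff <- assignments$sapling_cutoff[match(stems$species,
                                             assignments$species)]
  known <- !is.na(cutoff)
  stems <- stems[known, , drop = FALSE]
  type <- type[known]
  cutoff <- cutoff[known]
  is_adult <- stems$dbh >= cutoff
  q <- census$quadrat_size
  qcol <- floor(stems$x / q)
  qrow <- floor(stems$y / q)
  grid <- quadrat_grid(census)
  qid <- match(paste(qrow, qcol), paste(grid$qrow, grid$qcol))

  species <- sort(unique(stems$species))
  sp_idx <- match(stems$species, species)
  sp_type <- type[match(species, stems$species)]

  # occupancy-based inclusion rule
  occ <- function(sel) {
    tab <- unique(data.frame(sp = sp_idx[sel], qid = qid[sel]))
    tabulate(tab$sp, nbins = length(species))
  }
  n_adult_q <- occ(is_adult)
  n_sap_q <- occ(!is_adult)
  retained <- n_adult_q >= min_quadrats & n_sap_q >= min_quadrats
  if (!any(retained)) {
    mycodd_log("plot ", census$plot_id, ": no species passes the ",
               min_quadrats, "-quadrat inclusion rule")
    return(empty)
  }
  if (dataset == "CMDD" &&
      length(unique(sp_type[retained])) < 2L) {
    mycodd_log("plot ", census$plot_id, ": all retained species are one ",
               "mycorrhizal type; plot excluded from the CMDD dataset")
    return(empty)
  }

  # Q x S weighted adult density matrix over all typed species
  ad <- stems[is_adult, , drop = FALSE]
  W <- quadrat_weight_matrix(grid, ad$x, ad$y, kernel)
  ind <- matrix(0, nrow(ad), length(species))
  ind[cbind(seq_len(nrow(ad)), sp_idx[is_adult])] <- 1
  D <- W %*% ind                       # quadrat x species
  tot_am <- rowSums(D[, sp_type == "AM", drop = FALSE])
  tot_em <- rowSums(D[, sp_type == "EM", drop = FALSE])

  # per-quadrat sapling counts for retained species
  ret <- which(retained)
  sap <- !is_adult
  Scount <- matrix(0L, nrow(grid), length(ret))
  st <- table(factor(qid[sap], levels = seq_len(nrow(grid))),
              factor(sp_idx[sap], levels = ret))
  Scount[] <- as.integer(st)

  out <- do.call(rbind, lapply(seq_along(ret), function(j) {
    s <- ret[j]
    A <- D[, s]
    same <- if (sp_type[s] == "AM") tot_am else tot_em
    other <- if (sp_type[s] == "AM") tot_em else tot_am
    data.frame(plot_id = census$plot_id, qrow = grid$qrow,
               qcol = grid$qcol, species = species[s],
               S = Scount[, j],
               A = pmax(A, floor),
               H = pmax(same - A, 0) + pmax(other, 0),
               M = pmax(same - A, 0),
               HMH = pmax(other, 0),
               mycorrhizal_type = sp_type[s],
               group = paste0(census$plot_id, ":", species[s]))
  }))
  rownames(out) <- NULL
  out
}
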