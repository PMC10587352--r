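#' Construct a plot census object
#'
#' A `plot_census` bundles one census of a stem-mapped forest plot: plot
#' geometry, geographic metadata and a stem table with one row per
#' measured stem. Coordinates are metres from the plot's south-west
#' corner; quadrat membership downstream uses half-open intervals
#' `[k*q, (k+1)*q)` so boundary stems are assigned unambiguously.
#'
#' @param stems data.frame with columns `stem_id`, `tree_id`, `species`
#'   (character), `x`, `y`, `dbh` (numeric; metres, metres, centimetres),
#'   `status` (`"alive"`/`"dead"`) and `main_stem` (logical, may be `NA`
#'   when the census does not record it).
#' @param plot_id Plot identifier.
#' @param x_extent,y_extent Plot extents (m), positive.
#' @param quadrat_size Quadrat side (m), default 20 as in large
#'   stem-mapped forest plots.
#' @param latitude,longitude Degrees; latitude checked against [-90, 90].
#' @param mat,map Optional mean annual temperature (deg C) and
#'   precipitation (mm).
#' @return An object of class `plot_census`.
#' @export
plot_census <- function(stems, plot_id, x_extent, y_extent,
                        quadrat_size = 20, latitude = NA_real_,
                        longitude = NA_real_, mat = NA_real_,
                        map = NA_real_) {
  required <- c("stem_id", "tree_id", "species", "x", "y", "dbh",
                "status", "main_stem")
  missing_cols <- setdiff(required, names(stems))
  if (length(missing_cols))
    stop("stem table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (x_extent <= 0 || y_extent <= 0) stop("plot extents must be positive")
  if (!is.na(latitude) && abs(latitude) > 90)
    stop("latitude must lie in [-90, 90]")
  if (quadrat_size <= 0) stop("quadrat_size must be positive")
  if (x_extent %% quadrat_size != 0 || y_extent %% quadrat_size != 0)
    mycodd_log("plot ", plot_id, ": extents are not a multiple of the ",
               "quadrat size; trailing partial quadrats are used as-is")
  stems <- as.data.frame(stems)[, required]
  stems$stem_id <- as.character(stems$stem_id)
  stems$tree_id <- as.character(stems$tree_id)
  stems$species <- as.character(stems$species)
  bad <- which(stems$x < 0 | stems$x >= x_extent |
                 stems$y < 0 | stems$y >= y_extent)
  if (length(bad))
    stop("stem coordinates outside plot bounds at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  structure(list(plot_id = as.character(plot_id),
                 x_extent = x_extent, y_extent = y_extent,
                 quadrat_size = quadrat_size,
                 latitude = latitude, longitude = longitude,
                 mat = mat, map = map, stems = stems),
            class = "plot_census")
}

#' @export
print.plot_census <- function(x, ...) {
  cat(sprintf("plot_census '%s': %d stems, %d species, %g x %g m (quadrat %g m)\n",
              x$plot_id, nrow(x$stems), length(unique(x$stems$species)),
              x$x_extent, x$y_extent, x$quadrat_size))
  invisible(x)
}

# normalise heterogeneous census status strings; unknown labels are
# treated as dead (conservative exclusion) and logged
normalize_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  out <- rep("dead", length(s))
  out[s %in% c("alive", "a", "live", "l")] <- "alive"
  unknown <- !(s %in% c("alive", "a", "live", "l", "dead", "d"))
  if (any(unknown))
    mycodd_log(sum(unknown), " stem(s) with unrecognised status (",
               paste(unique(s[unknown]), collapse = ", "),
               ") treated as dead")
  out
}

#' Read a plot census from delimited text
#'
#' Reads one census in the universal stem format. Censuses with
#' different column names are accommodated through `schema`, a named
#' character vector mapping file columns to canonical names, e.g.
#' `c(gx = "x", gy = "y")`. Canonical columns: `stem_id`, `tree_id`,
#' `species`, `x`, `y`, `dbh`, `status`, `main_stem` (the last may be
#' absent; it is then derived later from the largest stem per tree).
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional named character vector, `file_column = "canonical"`.
#' @param plot_id Plot identifier; defaults to the file name.
#' @param x_extent,y_extent Plot extents (m); when `NULL` they are
#'   inferred as the smallest multiple of `quadrat_size` covering the
#'   coordinates (logged).
#' @param quadrat_size Quadrat side (m), default 20.
#' @param latitude,longitude,mat,map Site metadata, optional.
#' @param sep Field separator, default comma.
#' @return A [plot_census()].
#' @export
read_census <- function(path, schema = NULL, plot_id = NULL,
                        x_extent = NULL, y_extent = NULL,
                        quadrat_size = 20, latitude = NA_real_,
                        longitude = NA_real_, mat = NA_real_,
                        map = NA_real_, sep = ",") {
  if (!file.exists(path)) stop("census file not found: ", path)
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE)
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), names(raw))
    if (length(unknown))
      stop("schema maps absent column(s): ", paste(unknown, collapse = ", "))
    names(raw)[match(names(schema), names(raw))] <- unname(schema)
  }
  required <- c("stem_id", "tree_id", "species", "x", "y", "dbh", "status")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("census file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("x", "y", "dbh")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val))
    if (length(bad))
      stop("non-numeric ", col, " at row(s): ",
           paste(head(bad, 10), collapse = ", "))
    raw[[col]] <- val
  }
  below <- which(raw$dbh < 1)
  if (length(below)) {
    mycodd_log(length(below), " stem(s) below the 1 cm census floor dropped")
    raw <- raw[-below, , drop = FALSE]
  }
  raw$status <- normalize_status(raw$status)
  if ("main_stem" %in% names(raw)) {
    ms <- tolower(trimws(raw$main_stem))
    raw$main_stem <- ms %in% c("true", "t", "1", "yes", "y")
  } else {
    raw$main_stem <- NA
  }
  if (is.null(plot_id)) plot_id <- tools::file_path_sans_ext(basename(path))
  if (is.null(x_extent)) {
    x_extent <- ceiling(max(raw$x, 0) / quadrat_size + 1e-9) * quadrat_size
    mycodd_log("plot ", plot_id, ": x_extent inferred as ", x_extent, " m")
  }
  if (is.null(y_extent)) {
    y_extent <- ceiling(max(raw$y, 0) / quadrat_size + 1e-9) * quadrat_size
    mycodd_log("plot ", plot_id, ": y_extent inferred as ", y_extent, " m")
  }
  plot_census(raw, plot_id = plot_id, x_extent = x_extent,
              y_extent = y_extent, quadrat_size = quadrat_size,
              latitude = latitude, longitude = longitude,
              mat = mat, map = map)
}

#' Write a plot census to delimited text
#'
#' Writes the stem table in the canonical column order; reading the file
#' back with [read_census()] round-trips every retained field.
#'
#' @param census A [plot_census()].
#' @param path Output path.
#' @param sep Field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path, sep = ",") {
  stopifnot(inherits(census, "plot_census"))
  write.table(census$stems, path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Filter a census to the analysis stem set
#'
#' Drops dead stems and, by default, restricts to main stems — the
#' largest living stem of each tree. When the census records a
#' `main_stem` flag it is respected; otherwise the main stem is the
#' living stem with the largest DBH, ties broken by smallest `stem_id`.
#'
#' @param census A [plot_census()].
#' @param main_stems_only Restrict to one main stem per tree (default
#'   `TRUE`, the analysis convention; metadata summaries use all stems).
#' @return A filtered [plot_census()].
#' @export
filter_stems <- function(census, main_stems_only = TRUE) {
  stopifnot(inherits(census, "plot_census"))
  stems <- census$stems
  stems <- stems[stems$status == "alive", , drop = FALSE]
  if (nrow(stems) == 0L) {
    warning("no living stems remain in plot ", census$plot_id)
  } else if (main_stems_only) {
    keep <- logical(nrow(stems))
    for (idx in split(seq_len(nrow(stems)), stems$tree_id)) {
      flags <- stems$main_stem[idx]
      if (any(flags %in% TRUE)) {
        cand <- idx[which(flags %in% TRUE)]
      } else {
        cand <- idx
      }
      dbh <- stems$dbh[cand]
      cand <- cand[dbh == max(dbh)]
      if (length(cand) > 1L)
        cand <- cand[order(stems$stem_id[cand])][1L]
      keep[cand] <- TRUE
    }
    stems <- stems[keep, , drop = FALSE]
    stems$main_stem <- TRUE
  }
  out <- census
  out$stems <- stems
  out
}

#' Delineate adult and sapling size classes per species
#'
#' Saplings are stems below a species-specific DBH cutoff chosen by a
#' cascade: 10 cm if at least 20% of the species' stems are >= 10 cm
#' DBH; otherwise 5 cm if at least 20% are >= 5 cm; otherwise 2 cm,
#' which is terminal regardless of the resulting adult fraction (1 cm is
#' the smallest measured stem). The cascade depends only on the species'
#' DBH values, not their order. The 20% thresholds are inclusive.
#'
#' @param census A [plot_census()], typically after [filter_stems()].
#' @return data.frame with columns `species`, `sapling_cutoff` (10, 5 or
#'   2 cm), `adult_fraction_at_cutoff` and `n_stems`. Species with zero
#'   stems are not emitted.
#' @export
assign_size_classes <- function(census) {
  stopifnot(inherits(census, "plot_census"))
  stems <- census$stems
  if (nrow(stems) == 0L)
    return(data.frame(species = character(), sapling_cutoff = numeric(),
                      adult_fraction_at_cutoff = numeric(),
                      n_stems = integer()))
  res <- lapply(split(stems$dbh, stems$species), function(dbh) {
    cutoff <- size_class_cutoff(dbh)
    c(cutoff = cutoff, frac = mean(dbh >= cutoff), n = length(dbh))
  })
  out <- data.frame(species = names(res),
                    sapling_cutoff = vapply(res, `[[`, 0, "cutoff"),
                    adult_fraction_at_cutoff = vapply(res, `[[`, 0, "frac"),
                    n_stems = as.integer(vapply(res, `[[`, 0, "n")),
                    row.names = NULL)
  out[order(out$species), , drop = FALSE]
}

# the 10 / 5 / 2 cm cascade on a species' DBH multiset
size_class_cutoff <- function(dbh) {
  if (mean(dbh >= 10) >= 0.20) return(10)
  if (mean(dbh >= 5) >= 0.20) return(5)
  2
}

#' Summarise a site: richness, mycorrhizal composition, abundances
#'
#' Computes species richness among retained (strictly AM or EM) species,
#' the proportion of EM species, the proportion of total basal area in
#' EM stems (basal area per stem = pi * (dbh/2)^2), and per-species
#' abundance and relative abundance. Metadata conventionally uses the
#' full living stem set (all stems, not only main stems); pass the
#' census filtered accordingly.
#'
#' @param census A [plot_census()].
#' @param traits Mycorrhizal assignment as returned by
#'   [assign_mycorrhizal_type()]: data.frame with `species` and
#'   `mycorrhizal_type` in `{"AM","EM","excluded"}`.
#' @return A list of class `site_summary`: `plot_id`, `species_richness`,
#'   `proportion_EM_species`, `proportion_EM_basal_area`, `n_excluded_species`,
#'   `latitude`, `mat`, `map`, and `abundance` (data.frame `species`,
#'   `mycorrhizal_type`, `n_stems`, `relative_abundance`, `basal_area`).
#' @export
summarize_site <- function(census, traits) {
  stopifnot(inherits(census, "plot_census"))
  stems <- census$stems
  if (nrow(stems) == 0L) stop("no stems in plot ", census$plot_id)
  type <- traits$mycorrhizal_type[match(stems$species, traits$species)]
  type[is.na(type)] <- "excluded"
  retained <- type %in% c("AM", "EM")
  excluded_species <- unique(stems$species[!retained])
  if (length(excluded_species))
    mycodd_log("plot ", census$plot_id, ": ", length(excluded_species),
               " species without a strict AM/EM assignment excluded ",
               "from site metadata")
  stems <- stems[retained, , drop = FALSE]
  type <- type[retained]
  if (nrow(stems) == 0L)
    stop("no retained species in plot ", census$plot_id)
  ba <- pi * (stems$dbh / 2)^2
  sp_type <- tapply(type, stems$species, `[`, 1)
  n_sp <- tapply(stems$species, stems$species, length)
  ba_sp <- tapply(ba, stems$species, sum)
  abundance <- data.frame(species = names(n_sp),
                          mycorrhizal_type = unname(sp_type),
                          n_stems = as.integer(unname(n_sp)),
                          relative_abundance = as.numeric(n_sp / sum(n_sp)),
                          basal_area = as.numeric(ba_sp),
                          row.names = NULL)
  structure(list(
    plot_id = census$plot_id,
    species_richness = nrow(abundance),
    proportion_EM_species = mean(abundance$mycorrhizal_type == "EM"),
    proportion_EM_basal_area =
      sum(abundance$basal_area[abundance$mycorrhizal_type == "EM"]) /
      sum(abundance$basal_area),
    n_excluded_species = length(excluded_species),
    latitude = census$latitude, mat = census$mat, map = census$map,
    abundance = abundance), class = "site_summary")
}
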