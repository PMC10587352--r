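#' Assign mycorrhizal types to species with genus-level fallback
#'
#' Looks each species up in a trait table (species- and genus-level
#' rows, in the style of database-derived mycorrhizal compilations).
#' Species-level labels take precedence; when a species is absent, the
#' genus-level label is used. Only strict `"AM"` or `"EM"` labels are
#' retained; ambiguous categories (e.g. `"AMEM"`, `"AMNM"`), other
#' mycorrhizal types and unmatched species are marked `"excluded"` and
#' dropped from all downstream models. Assignment is deterministic and
#' independent of input order.
#'
#' @param species Character vector of Latin binomials (genus taken as
#'   the first whitespace-delimited token) or bare species codes.
#' @param trait_table data.frame with columns `species`, `genus`,
#'   `mycorrhizal_type` and optionally `level` (`"species"` / `"genus"`)
#'   and `max_height` (m). Rows with `level = "genus"` (or with an empty
#'   `species` field) act as genus-level records.
#' @return data.frame with one row per unique input species: `species`,
#'   `genus`, `mycorrhizal_type` in `{"AM","EM","excluded"}`,
#'   `max_height` (NA when unknown) and `source`
#'   (`"species"`/`"genus"`/`"unmatched"`). The excluded fraction is
#'   logged.
#' @export
assign_mycorrhizal_type <- function(species, trait_table) {
  species <- sort(unique(as.character(species)))
  tt <- as.data.frame(trait_table)
  if (!all(c("species", "mycorrhizal_type") %in% names(tt)))
    stop("trait table needs `species` and `mycorrhizal_type` columns")
  if (is.null(tt$level))
    tt$level <- ifelse(is.na(tt$species) | tt$species == "", "genus",
                       "species")
  if (is.null(tt$genus))
    tt$genus <- vapply(strsplit(tt$species, "\\s+"), `[`, "", 1L)
  if (is.null(tt$max_height)) tt$max_height <- NA_real_
  tt$max_height <- suppressWarnings(as.numeric(tt$max_height))
  sp_rows <- tt[tt$level == "species", , drop = FALSE]
  gn_rows <- tt[tt$level == "genus", , drop = FALSE]
  genus_of <- vapply(strsplit(species, "\\s+"), `[`, "", 1L)

  i_sp <- match(species, sp_rows$species)
  i_gn <- match(genus_of, gn_rows$genus)
  raw_type <- ifelse(!is.na(i_sp), sp_rows$mycorrhizal_type[i_sp],
                     ifelse(!is.na(i_gn), gn_rows$mycorrhizal_type[i_gn],
                            NA_character_))
  source <- ifelse(!is.na(i_sp), "species",
                   ifelse(!is.na(i_gn), "genus", "unmatched"))
  type <- ifelse(!is.na(raw_type) & raw_type %in% c("AM", "EM"),
                 raw_type, "excluded")
  height <- ifelse(!is.na(i_sp), sp_rows$max_height[i_sp],
                   ifelse(!is.na(i_gn), gn_rows$max_height[i_gn], NA_real_))
  n_excl <- sum(type == "excluded")
  if (n_excl)
    mycodd_log(n_excl, "/", length(species), " species excluded ",
               "(ambiguous, non-AM/EM or unmatched mycorrhizal label)")
  data.frame(species = species, genus = genus_of,
             mycorrhizal_type = type, max_height = as.numeric(height),
             source = source, row.names = NULL)
}

#' Read a species trait table from delimited text
#'
#' @param path Path to a delimited file with columns `species`, `genus`,
#'   `mycorrhizal_type`, optionally `max_height` and `level`.
#' @param sep Field separator, default comma.
#' @return data.frame as read, with `max_height` numeric.
#' @export
read_traits <- function(path, sep = ",") {
  if (!file.exists(path)) stop("trait file not found: ", path)
  tt <- read.csv(path, sep = sep, colClasses = "character",
                 check.names = FALSE)
  if (!is.null(tt$max_height))
    tt$max_height <- suppressWarnings(as.numeric(tt$max_height))
  tt
}

#' Mean seed dispersal distance from maximum plant height
#'
#' Interspecific allometry on the log10 scale:
#' `distance = 10^(a + b * log10(max_height))`. Meta-analyses of seed
#' dispersal report such power-law relationships between mean dispersal
#' distance and maximum plant height; the coefficients here are package
#' defaults chosen to give plausible tree dispersal distances (height
#' 10 m -> 10 m, height 40 m -> 20 m), not values from any specific
#' compilation, and should be set from the literature relevant to the
#' flora at hand.
#'
#' @param max_height Maximum plant height (m), positive; vectorised.
#' @param allometry Named numeric vector `c(intercept = a, slope = b)`.
#' @return Mean dispersal distance(s), metres.
#' @export
dispersal_from_height <- function(max_height,
                                  allometry = c(intercept = 0.5,
                                                slope = 0.5)) {
  if (any(!is.finite(max_height)) || any(max_height <= 0))
    stop("max_height must be positive and finite")
  10^(allometry[["intercept"]] +
        allometry[["slope"]] * log10(max_height))
}
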