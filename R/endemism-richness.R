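# Five-way endemism categorization and stacked richness / uncertainty
# maps built from per-species binary suitability maps.

ENDEMISM_CATEGORIES <- c("wide_endemic", "narrow_endemic_lowland",
                         "narrow_endemic_montane", "nonendemic_dry",
                         "nonendemic_wet")

#' Per-species profile feeding the endemism classifier
#'
#' @param species name.
#' @param endemic logical (taxonomic input).
#' @param current_area current suitable area, km2.
#' @param breadth Levins niche breadth in [0, 1].
#' @param occ_elevations occurrence elevations (m).
#' @param zone_overlap named fractions of suitable area per climate zone
#'   (`wet`, `intermediate`, `dry`, `arid`); must sum to 1 when any
#'   suitable area exists.
#' @return object of class `species_profile`.
#' @export
species_profile <- function(species, endemic, current_area, breadth,
                            occ_elevations, zone_overlap) {
  if (length(zone_overlap) && abs(sum(zone_overlap) - 1) > 1e-6)
    stop("zone_overlap fractions must sum to 1")
  structure(list(species = species, endemic = endemic,
                 current_area = current_area, breadth = breadth,
                 occ_elevations = occ_elevations,
                 zone_overlap = zone_overlap),
            class = "species_profile")
}

#' Classify a species into the five endemism categories
#'
#' Rules, in order: an explicit override (flagged); endemic with area >=
#' 10,000 km2 and breadth >= 0.5 -> wide endemic; endemic with area <
#' 10,000 and breadth < 0.5 -> narrow endemic, montane iff the minimum
#' occurrence elevation exceeds 300 m, lowland otherwise; an endemic
#' matching neither rule raises an error asking for an override;
#' nonendemic -> wet-zone when the wet zone holds the largest share of
#' suitable area, dry-zone when dry or arid does (ties raise an error).
#' The strict ">" cutoffs are applied as ">=" so boundary profiles (area
#' exactly 10,000 or breadth exactly 0.5) classify as wide.
#'
#' @param profile a [species_profile()].
#' @param overrides optional named character vector species -> label.
#' @param area_cutoff_km2,breadth_cutoff,montane_elevation_m rule
#'   constants (10,000 km2; 0.5; 300 m).
#' @return list: `label`, `rule_trace`, `overridden`.
#' @export
classify_endemism <- function(profile, overrides = NULL,
                              area_cutoff_km2 = 10000,
                              breadth_cutoff = 0.5,
                              montane_elevation_m = 300) {
  sp <- profile$species
  if (!is.null(overrides) && sp %in% names(overrides)) {
    lab <- overrides[[sp]]
    stopifnot(lab %in% ENDEMISM_CATEGORIES)
    return(list(label = lab, rule_trace = "override", overridden = TRUE))
  }
  if (profile$endemic) {
    wide <- profile$current_area >= area_cutoff_km2 &&
      profile$breadth >= breadth_cutoff
    narrow <- profile$current_area < area_cutoff_km2 &&
      profile$breadth < breadth_cutoff
    if (wide)
      return(list(label = "wide_endemic",
                  rule_trace = sprintf("endemic & area %.0f >= %0.f & B %.2f >= %.2f",
                                       profile$current_area, area_cutoff_km2,
                                       profile$breadth, breadth_cutoff),
                  overridden = FALSE))
    if (narrow) {
      minel <- min(profile$occ_elevations, na.rm = TRUE)
      lab <- if (minel > montane_elevation_m) "narrow_endemic_montane"
             else "narrow_endemic_lowland"
      return(list(label = lab,
                  rule_trace = sprintf("endemic & narrow; min elevation %.0f m", minel),
                  overridden = FALSE))
    }
    stop("unresolved-endemic error: ", sp,
         " matches neither wide nor narrow rule; supply an override")
  }
  zo <- profile$zone_overlap
  if (!length(zo)) stop("nonendemic ", sp, " has no zone overlap data")
  top <- names(zo)[which(zo == max(zo))]
  if (length(top) > 1)
    stop("tie error: ", sp, " has tied zone fractions; supply an override")
  lab <- if (top == "wet") "nonendemic_wet"
         else if (top %in% c("dry", "arid")) "nonendemic_dry"
         else stop("tie error: ", sp, " peaks in the intermediate zone; ",
                   "supply an override")
  list(label = lab,
       rule_trace = sprintf("nonendemic; dominant zone %s (%.2f)", top, max(zo)),
       overridden = FALSE)
}

#' Fractions of suitable area per climate zone
#'
#' @param bm binary suitability map.
#' @param zones zone raster (1 wet, 2 intermediate, 3 dry, 4 arid).
#' @param areas per-cell areas.
#' @return named fractions summing to 1 (empty vector if no suitable
#'   cells).
#' @export
zone_overlap_fractions <- function(bm, zones, areas) {
  zn <- c("wet", "intermediate", "dry", "arid")
  sel <- which(bm == 1 & !is.na(zones))
  if (!length(sel)) return(stats::setNames(numeric(0), character(0)))
  tot <- sum(areas[sel])
  out <- vapply(1:4, function(z) sum(areas[sel][zones[sel] == z]) / tot,
                numeric(1))
  stats::setNames(out, zn)
}

#' Stacked species richness
#'
#' Cell-wise sum of member binary maps (NA-safe: a cell is NA only when
#' every member is NA there).
#'
#' @param binary_maps list of 0/1 matrices.
#' @return list: `counts` matrix, `max_count`.
#' @export
stack_richness <- function(binary_maps) {
  stopifnot(length(binary_maps) >= 1)
  acc <- matrix(0L, nrow(binary_maps[[1]]), ncol(binary_maps[[1]]))
  any_ok <- matrix(FALSE, nrow(acc), ncol(acc))
  for (bm in binary_maps) {
    ok <- !is.na(bm)
    acc[ok] <- acc[ok] + bm[ok]
    any_ok <- any_ok | ok
  }
  acc[!any_ok] <- NA_integer_
  list(counts = acc, max_count = max(acc, na.rm = TRUE))
}

#' Area of the richness band
#'
#' Area of the cells whose species count equals `level` or more;
#' `level = NULL` (default) uses the maximum observed count, matching the
#' "maximum number of overlapping species" convention.
#'
#' @param rm a [stack_richness()] result.
#' @param areas per-cell areas.
#' @param level richness level (default: the maximum).
#' @return km2.
#' @export
richness_area <- function(rm, areas, level = NULL) {
  if (is.null(level)) level <- rm$max_count
  sum(areas[which(rm$counts >= level)])
}

#' Tri-state uncertainty map across replicate binary maps
#'
#' Per cell: `always` when every replicate of every member predicts
#' presence; `absent` when some member has no presence-predicting
#' replicate; `mixed` otherwise.
#'
#' @param member_replicates list over species; each element a list of
#'   replicate 0/1 matrices.
#' @return character matrix with values "always"/"mixed"/"absent" (NA on
#'   nodata).
#' @export
uncertainty_map <- function(member_replicates) {
  stopifnot(length(member_replicates) >= 1)
  proto <- member_replicates[[1]][[1]]
  all_always <- matrix(TRUE, nrow(proto), ncol(proto))
  all_some <- matrix(TRUE, nrow(proto), ncol(proto))
  valid <- matrix(FALSE, nrow(proto), ncol(proto))
  for (reps in member_replicates) {
    sp_all <- matrix(TRUE, nrow(proto), ncol(proto))
    sp_any <- matrix(FALSE, nrow(proto), ncol(proto))
    for (bm in reps) {
      ok <- !is.na(bm)
      valid <- valid | ok
      sp_all <- sp_all & (!ok | bm == 1)
      sp_any[ok] <- sp_any[ok] | bm[ok] == 1
    }
    all_always <- all_always & sp_all
    all_some <- all_some & sp_any
  }
  out <- matrix(NA_character_, nrow(proto), ncol(proto))
  out[valid] <- "absent"
  out[valid & all_some] <- "mixed"
  out[valid & all_always] <- "always"
  out
}
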