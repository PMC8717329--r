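# Overlay of per-category richness areas with protected-area and
# forest-cover layers: gap reports and conservation recommendation maps.

#' Area of richness cells intersecting a mask
#'
#' @param richness_cells logical or 0/1 matrix of richness-area cells.
#' @param layer_mask logical or 0/1 matrix (e.g. rasterized protected
#'   areas).
#' @param areas per-cell areas.
#' @return km2 of the intersection.
#' @export
overlay_extent <- function(richness_cells, layer_mask, areas) {
  sel <- which(richness_cells == 1 & layer_mask == 1)
  sum(areas[sel])
}

#' Gap-analysis report rows for one period
#'
#' For each category: the richness area (cells at the maximum overlap
#' level, or `level`), its extent within all protected land, within
#' conservation forests, and (current period only) within forest cover,
#' plus the derived percentages. Future periods keep the current
#' protected layers fixed. A category with no richness cells yields an
#' N/A row (total loss).
#'
#' @param richness_by_category named list of [stack_richness()] results.
#' @param protected_all,conservation_forest,forest binary masks on the
#'   grid (`forest` may be NULL for future periods).
#' @param areas per-cell areas.
#' @param period period label.
#' @param level optional richness level (default: per-category maximum).
#' @return data.frame, one row per category.
#' @export
gap_report <- function(richness_by_category, protected_all,
                       conservation_forest, forest = NULL, areas,
                       period = "current", level = NULL) {
  rows <- lapply(names(richness_by_category), function(cat) {
    rm <- richness_by_category[[cat]]
    lev <- if (is.null(level)) rm$max_count else level
    cells <- !is.na(rm$counts) & rm$counts >= lev & rm$counts > 0
    ra <- sum(areas[which(cells)])
    if (ra == 0) {
      return(data.frame(category = cat, period = period,
                        richness_area_km2 = NA_real_,
                        protected_km2 = NA_real_, protected_pct = NA_real_,
                        conservation_forest_km2 = NA_real_,
                        conservation_forest_pct = NA_real_,
                        forest_km2 = NA_real_, forest_pct = NA_real_,
                        not_applicable = TRUE))
    }
    pa <- overlay_extent(cells, protected_all, areas)
    cfa <- overlay_extent(cells, conservation_forest, areas)
    fa <- if (!is.null(forest)) overlay_extent(cells, forest, areas) else NA_real_
    data.frame(category = cat, period = period,
               richness_area_km2 = ra,
               protected_km2 = pa, protected_pct = 100 * pa / ra,
               conservation_forest_km2 = cfa,
               conservation_forest_pct = 100 * cfa / ra,
               forest_km2 = fa,
               forest_pct = if (is.na(fa)) NA_real_ else 100 * fa / ra,
               not_applicable = FALSE)
  })
  do.call(rbind, rows)
}

#' Conservation recommendation map
#'
#' Flags forested, unprotected cells that fall either in any category's
#' high-confidence richness area or in the designated dry-zone richness
#' area.
#'
#' @param high_confidence list of logical matrices (one per category):
#'   cells where all replicates of the highest-overlap species set
#'   predict presence.
#' @param dry_zone_richness logical matrix of dry-zone nonendemic
#'   richness cells (may be NULL).
#' @param forest_mask,protected_mask binary masks.
#' @return logical matrix; flagged cells are a subset of
#'   `forest & !protected`.
#' @export
recommendation_map <- function(high_confidence, dry_zone_richness = NULL,
                               forest_mask, protected_mask) {
  stopifnot(length(high_confidence) >= 1 || !is.null(dry_zone_richness))
  proto <- if (length(high_confidence)) high_confidence[[1]] else dry_zone_richness
  pool <- matrix(FALSE, nrow(proto), ncol(proto))
  for (m in high_confidence) pool <- pool | (!is.na(m) & m == 1)
  if (!is.null(dry_zone_richness))
    pool <- pool | (!is.na(dry_zone_richness) & dry_zone_richness == 1)
  pool & forest_mask == 1 & protected_mask != 1
}
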