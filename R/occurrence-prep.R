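#' Clean occurrence records
#'
#' Applies, in order: (1) collapse of exact duplicates (species +
#' coordinates rounded to 6 decimals, roughly GPS precision); (2) removal
#' of records without environmental data (off-grid or on nodata cells);
#' (3) spatial thinning to one record per raster cell per species (the
#' first-seen record in input order is kept); (4) dropping of species left
#' with fewer than `min_count` distinct cells ("min-count") or with all
#' records in one cell ("single-location"). The report reconciles every
#' stage count.
#'
#' @param occ occurrence data.frame (`species, lon, lat, ...`).
#' @param stack a [climate_stack()] defining the grid and nodata cells.
#' @param min_count minimum distinct occupied cells per retained species.
#' @return list with `occurrences` (cleaned data.frame) and `report`
#'   (list: `n_input`, `n_after_dedupe`, `n_missing_env_removed`,
#'   `n_same_cell_removed`, `species_dropped` data.frame, `n_final`).
#' @export
clean_occurrences <- function(occ, stack, min_count = 10) {
  stopifnot(min_count >= 1)
  empty_report <- function(n_input = 0L) list(
    n_input = n_input, n_after_dedupe = 0L, n_missing_env_removed = 0L,
    n_same_cell_removed = 0L,
    species_dropped = data.frame(species = character(0), reason = character(0)),
    n_final = 0L)
  if (nrow(occ) == 0)
    return(list(occurrences = occ, report = empty_report()))

  n_input <- nrow(occ)
  key <- paste(occ$species, round(occ$lon, 6), round(occ$lat, 6))
  occ1 <- occ[!duplicated(key), , drop = FALSE]
  n_after_dedupe <- nrow(occ1)

  idx <- cell_index(stack$grid, occ1$lon, occ1$lat)
  land <- land_mask(stack)
  has_env <- !is.na(idx$row) & !is.na(idx$col)
  has_env[has_env] <- land[cbind(idx$row[has_env], idx$col[has_env])]
  occ2 <- occ1[has_env, , drop = FALSE]
  idx2 <- idx[has_env, , drop = FALSE]
  n_missing_env_removed <- n_after_dedupe - nrow(occ2)

  cellkey <- paste(occ2$species, idx2$row, idx2$col)
  keep <- !duplicated(cellkey)
  occ3 <- occ2[keep, , drop = FALSE]
  n_same_cell_removed <- nrow(occ2) - nrow(occ3)

  counts <- table(occ3$species)
  dropped <- data.frame(species = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (sp in names(counts)) {
    if (counts[[sp]] == 1)
      dropped <- rbind(dropped, data.frame(species = sp,
                                           reason = "single-location"))
    else if (counts[[sp]] < min_count)
      dropped <- rbind(dropped, data.frame(species = sp,
                                           reason = "min-count"))
  }
  occ4 <- occ3[!(occ3$species %in% dropped$species), , drop = FALSE]
  rownames(occ4) <- NULL

  list(occurrences = occ4,
       report = list(n_input = n_input,
                     n_after_dedupe = n_after_dedupe,
                     n_missing_env_removed = n_missing_env_removed,
                     n_same_cell_removed = n_same_cell_removed,
                     species_dropped = dropped,
                     n_final = nrow(occ4)))
}
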