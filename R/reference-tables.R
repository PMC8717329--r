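# Published Sri Lankan Memecylon summary tables, shipped as plain CSV.
# These printed tables are treated as *inputs*: the habitat-change and
# gap-analysis arithmetic can be recomputed and checked against the
# printed derived quantities without any external downloads.

#' Published Memecylon reference tables
#'
#' `memecylon_species()` returns the species list with endemism category
#' and cleaned occurrence counts; `memecylon_habitat_areas()` the current
#' and 12-scenario future suitable-habitat extents (km2) with niche
#' breadth, kappa and printed percent changes; `memecylon_gap_table()`
#' the per-category richness areas and protected/forest extents;
#' `memecylon_category_overrides()` the two species whose published
#' category label contradicts the stated area/breadth rule and is kept as
#' explicit override data.
#'
#' @return data.frame (or named character vector for the overrides).
#' @export
memecylon_species <- function() {
  utils::read.csv(system.file("extdata", "memecylon_table1.csv",
                              package = "enmgap"), stringsAsFactors = FALSE)
}

#' @rdname memecylon_species
#' @export
memecylon_habitat_areas <- function() {
  utils::read.csv(system.file("extdata", "memecylon_table4.csv",
                              package = "enmgap"), check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' @rdname memecylon_species
#' @export
memecylon_gap_table <- function() {
  utils::read.csv(system.file("extdata", "memecylon_table5.csv",
                              package = "enmgap"), stringsAsFactors = FALSE)
}

#' @rdname memecylon_species
#' @export
memecylon_category_overrides <- function() {
  df <- utils::read.csv(system.file("extdata", "category_overrides.csv",
                                    package = "enmgap"),
                        stringsAsFactors = FALSE)
  stats::setNames(df$label, df$species)
}

#' Count species gaining habitat under every future scenario
#'
#' A species is a consistent gainer when its suitable habitat increases
#' in all 12 scenarios. The published percent-change sign is the
#' accounting criterion: one printed area cell contradicts its own
#' printed percent (M. capitellatum, MIROC5 RCP2.6 2050), and the
#' percent column is the self-consistent record of the direction of
#' change.
#'
#' @param tab output of [memecylon_habitat_areas()].
#' @return integer count.
#' @export
count_consistent_gainers <- function(tab = memecylon_habitat_areas()) {
  pct_cols <- grep("^pct_", names(tab), value = TRUE)
  stopifnot(length(pct_cols) == 12)
  sum(apply(tab[pct_cols] > 0, 1, all))
}
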