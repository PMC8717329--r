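# Calibration areas (100-km occurrence buffers) and the low-collinearity
# bioclim subset retained for each species.

#' Great-circle distance (haversine)
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; vectors recycle.
#' @return distance in km on a sphere of radius 6371 km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Buffer calibration mask around occurrences
#'
#' A cell belongs to the calibration area iff the great-circle distance
#' from its center to the nearest occurrence is at most `buffer_km`.
#' Sea/nodata cells are excluded.
#'
#' @param occ occurrence data.frame for one species.
#' @param stack a [climate_stack()] (grid + nodata).
#' @param buffer_km buffer radius in km (default 100).
#' @return list: `mask` (logical matrix), `buffer_km`, `species`.
#' @export
buffer_mask <- function(occ, stack, buffer_km = 100) {
  if (nrow(occ) == 0) stop("input error: no occurrences to buffer")
  grid <- stack$grid
  land <- land_mask(stack)
  lon <- cell_center_lon(grid)
  lat <- cell_center_lat(grid)
  mind2 <- matrix(Inf, grid$n_rows, grid$n_cols)
  for (i in seq_len(nrow(occ))) {
    d <- outer(lat, lon, function(la, lo)
      haversine_km(occ$lon[i], occ$lat[i], lo, la))
    mind2 <- pmin(mind2, d)
  }
  mask <- mind2 <= buffer_km & land
  # degenerate buffer: always keep the occurrence cells themselves
  idx <- cell_index(grid, occ$lon, occ$lat)
  ok <- !is.na(idx$row)
  mask[cbind(idx$row[ok], idx$col[ok])] <- land[cbind(idx$row[ok], idx$col[ok])]
  list(mask = mask, buffer_km = buffer_km,
       species = if (nrow(occ)) occ$species[1] else NA_character_)
}

#' Pairwise Pearson correlation matrix over masked cells
#'
#' Pairwise-complete over the cells where `mask` is TRUE. Zero-variance
#' layers get NA correlations, treated as |r| = 1 (conservative) by the
#' collinearity filter.
#'
#' @param stack a [climate_stack()].
#' @param mask logical matrix selecting cells (default: all land).
#' @return list: `variables`, `r` (symmetric matrix, unit diagonal).
#' @export
pearson_matrix <- function(stack, mask = NULL) {
  if (is.null(mask)) mask <- land_mask(stack)
  if (sum(mask, na.rm = TRUE) < 3)
    stop("need at least 3 cells in the mask")
  vals <- vapply(stack$layers, function(m) m[which(mask)],
                 numeric(sum(mask, na.rm = TRUE)))
  r <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  diag(r) <- 1
  list(variables = colnames(r), r = r)
}

#' Greedy collinearity filter
#'
#' While any surviving pair exceeds the threshold, drop the variable with
#' the largest mean absolute correlation to the other survivors
#' (findCorrelation-style); ties broken by candidate order. NA entries
#' count as |r| = 1.
#'
#' @param cm output of [pearson_matrix()].
#' @param threshold retain set must satisfy pairwise |r| <= threshold
#'   (default 0.65).
#' @return list: `kept` (ordered names), `dropped` (data.frame: name,
#'   partner, abs_r).
#' @export
filter_collinear <- function(cm, threshold = 0.65) {
  r <- abs(cm$r)
  r[is.na(r)] <- 1
  diag(r) <- 0
  vars <- cm$variables
  alive <- rep(TRUE, length(vars))
  dropped <- data.frame(name = character(0), partner = character(0),
                        abs_r = numeric(0), stringsAsFactors = FALSE)
  repeat {
    sub <- r[alive, alive, drop = FALSE]
    if (all(sub <= threshold)) break
    means <- rowMeans(sub)
    worst_local <- which.max(means)            # first max = candidate order
    worst <- which(alive)[worst_local]
    partner_local <- which.max(sub[worst_local, ])
    partner <- which(alive)[partner_local]
    dropped <- rbind(dropped, data.frame(
      name = vars[worst], partner = vars[partner],
      abs_r = r[worst, partner]))
    alive[worst] <- FALSE
  }
  list(kept = vars[alive], dropped = dropped)
}
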