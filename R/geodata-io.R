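#' Geographic grid descriptor
#'
#' A lightweight descriptor of a regular geographic (longitude/latitude)
#' raster grid. The grid is registered by its upper-left corner (GeoTIFF
#' convention): row 1 is the northernmost row, and cell values are
#' conceptually attached to cell centers.
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param x_origin,y_origin longitude/latitude of the upper-left corner of
#'   the upper-left cell, in decimal degrees.
#' @param resolution cell size in degrees (square cells). Defaults to
#'   1/120 degree (30 arc-seconds).
#' @param nodata sentinel value used when writing to disk; in memory,
#'   missing cells are `NA`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(n_rows, n_cols, x_origin, y_origin,
                        resolution = 1 / 120, nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, resolution > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
         resolution = as.numeric(resolution), nodata = as.numeric(nodata),
         crs = "WGS84"),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, res %.6g deg, UL corner (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$resolution, x$x_origin, x$y_origin))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_origin - b$x_origin) < tol && abs(a$y_origin - b$y_origin) < tol &&
    abs(a$resolution - b$resolution) < tol
}

#' Latitude / longitude of cell centers
#'
#' @param grid a [raster_grid()].
#' @return `cell_center_lat` returns the vector of row-center latitudes
#'   (north to south); `cell_center_lon` the column-center longitudes.
#' @export
cell_center_lat <- function(grid) {
  grid$y_origin - (seq_len(grid$n_rows) - 0.5) * grid$resolution
}

#' @rdname cell_center_lat
#' @export
cell_center_lon <- function(grid) {
  grid$x_origin + (seq_len(grid$n_cols) - 0.5) * grid$resolution
}

#' Map coordinates to cell indices
#'
#' Points on the grid boundary are assigned to the cell they open
#' (half-open cells, consistent with upper-left registration). Points
#' outside the grid get `NA` indices.
#'
#' @param grid a [raster_grid()].
#' @param lon,lat numeric vectors of coordinates in degrees.
#' @return data.frame with integer columns `row`, `col` (NA outside grid).
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$x_origin) / grid$resolution) + 1
  row <- floor((grid$y_origin - lat) / grid$resolution) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Multi-layer climate stack
#'
#' Named raster layers sharing one grid: the environmental space used for
#' niche modeling. Layer names carry bioclim semantics (`bio1`..`bio19`).
#'
#' @param grid a [raster_grid()].
#' @param layers named list of numeric matrices `n_rows x n_cols`; `NA`
#'   marks nodata (sea) cells.
#' @param period_label free-text period tag (`"current"` or a scenario id).
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(grid, layers, period_label = "current") {
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must be uniquely named")
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop("layer '", nm, "' does not match grid dimensions")
  }
  structure(list(grid = grid, layers = layers, period_label = period_label),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack '%s': %d layers on %d x %d grid\n",
              x$period_label, length(x$layers), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Land mask of a stack
#'
#' A cell is land only if it is non-missing in every layer: a cell missing
#' in any selected layer is excluded from background sampling and area sums.
#'
#' @param stack a [climate_stack()].
#' @return logical matrix, TRUE on complete (land) cells.
#' @export
land_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]])
  for (l in stack$layers[-1]) m <- m & !is.na(l)
  m
}

# ---- ESRI ASCII grid I/O ------------------------------------------------

#' Read / write a single raster layer as ESRI ASCII grid
#'
#' Plain-text `.asc` format: 6 header lines (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows north to south.
#'
#' @param path file path.
#' @return `read_ascii_grid` returns `list(grid, values)` with `NA` at
#'   nodata cells.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (format error): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid value count mismatch in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  grid <- raster_grid(hdr$nrows, hdr$ncols,
                      x_origin = hdr$xllcorner,
                      y_origin = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                      resolution = hdr$cellsize, nodata = nodata)
  list(grid = grid, values = m)
}

#' @rdname read_ascii_grid
#' @param grid a [raster_grid()].
#' @param values numeric matrix matching the grid.
#' @export
write_ascii_grid <- function(values, grid, path) {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$x_origin),
    sprintf("yllcorner %.17g", grid$y_origin - grid$n_rows * grid$resolution),
    sprintf("cellsize %.17g", grid$resolution),
    sprintf("NODATA_value %.17g", grid$nodata)), con)
  v <- values
  v[is.na(v)] <- grid$nodata
  for (i in seq_len(grid$n_rows))
    writeLines(paste(format(v[i, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' Read several aligned layers into a climate stack
#'
#' @param paths character vector of `.asc` file paths.
#' @param names layer names, same length as `paths`.
#' @param period_label period tag for the stack.
#' @return a [climate_stack()]. Misaligned layers raise an error naming the
#'   offending layer.
#' @export
read_raster_stack <- function(paths, names, period_label = "current") {
  stopifnot(length(paths) == length(names), length(paths) >= 1)
  first <- read_ascii_grid(paths[1])
  layers <- stats::setNames(vector("list", length(paths)), names)
  layers[[1]] <- first$values
  if (length(paths) > 1) {
    for (i in 2:length(paths)) {
      li <- read_ascii_grid(paths[i])
      if (!grids_equal(first$grid, li$grid))
        stop("alignment error: layer '", names[i],
             "' does not match the grid of '", names[1], "'")
      layers[[i]] <- li$values
    }
  }
  climate_stack(first$grid, layers, period_label)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param stack a [climate_stack()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, one per layer.
#' @export
write_raster_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(stack$layers)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], stack$grid, p)
    paths[nm] <- p
  }
  paths
}

# ---- occurrences --------------------------------------------------------

#' Read / write occurrence tables
#'
#' CSV with header `species,lon,lat,elevation,source`; `elevation` and
#' `source` may be empty.
#'
#' @param path CSV file path.
#' @return data.frame with those five columns.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species, lon, lat")
  if (is.null(df$elevation)) df$elevation <- NA_real_
  if (is.null(df$source)) df$source <- ""
  if (nrow(df) && (any(df$lon < -180 | df$lon > 180) ||
                   any(df$lat < -90 | df$lat > 90)))
    stop("occurrence coordinates out of range")
  df[c("species", "lon", "lat", "elevation", "source")]
}

#' @rdname read_occurrences
#' @param occ occurrence data.frame.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

# ---- cell areas ---------------------------------------------------------

KM_PER_DEGREE <- 111.320  # spherical earth, R = 6371 km

#' Per-cell area in square kilometres
#'
#' Spherical cosine approximation on a geographic grid:
#' `area(row) = (111.320 * res) * (111.320 * res * cos(lat_center(row)))`,
#' constant across columns.
#'
#' @param grid a [raster_grid()].
#' @return numeric matrix of km2 per cell.
#' @export
cell_area_km2 <- function(grid) {
  lat <- cell_center_lat(grid)
  row_area <- (KM_PER_DEGREE * grid$resolution)^2 * cos(lat * pi / 180)
  matrix(row_area, nrow = grid$n_rows, ncol = grid$n_cols)
}

# ---- polygons -----------------------------------------------------------

#' Polygon layer
#'
#' Minimal polygon container: a list of features, each with a geometry
#' (list of rings; each ring a two-column lon/lat matrix; interior rings
#' are holes under the even-odd rule) and a class label.
#'
#' @param features list of `list(geometry = list(<matrix>), class_label = <chr>)`.
#' @return object of class `polygon_layer`.
#' @export
polygon_layer <- function(features = list()) {
  for (f in features) {
    if (is.null(f$class_label) || !nzchar(f$class_label))
      stop("class_label must be non-empty")
    for (ring in f$geometry) {
      if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3)
        stop("geometry error: each ring needs >= 3 lon/lat vertices")
      if (any(!is.finite(ring))) stop("geometry error: non-finite vertex")
    }
  }
  structure(list(features = features), class = "polygon_layer")
}

#' Rectangle helper for building polygon layers
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds in degrees.
#' @param class_label feature label.
#' @return a single polygon feature (closed ring).
#' @export
rect_feature <- function(xmin, xmax, ymin, ymax, class_label) {
  ring <- cbind(c(xmin, xmax, xmax, xmin, xmin),
                c(ymin, ymin, ymax, ymax, ymin))
  list(geometry = list(ring), class_label = class_label)
}

# Even-odd ray-casting point-in-polygon for one ring.
# Boundary points are treated by the half-open edge rule, adequate for
# cell-center tests against synthetic rectangles.
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_feature <- function(px, py, feature) {
  inside <- rep(FALSE, length(px))
  for (ring in feature$geometry)
    inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

#' Rasterize a polygon layer onto a grid
#'
#' Center-point rule: a cell is covered iff its center falls inside any
#' feature (even-odd over rings). Polygons outside the grid give all
#' zeros, not an error.
#'
#' @param polygons a [polygon_layer()].
#' @param grid a [raster_grid()].
#' @param classes optional character vector: only rasterize features whose
#'   `class_label` is in this set.
#' @return binary (0/1) integer matrix on the grid.
#' @export
rasterize_polygons <- function(polygons, grid, classes = NULL) {
  out <- matrix(0L, grid$n_rows, grid$n_cols)
  feats <- polygons$features
  if (!is.null(classes))
    feats <- Filter(function(f) f$class_label %in% classes, feats)
  if (!length(feats)) return(out)
  lon <- cell_center_lon(grid)
  lat <- cell_center_lat(grid)
  px <- rep(lon, each = grid$n_rows)
  py <- rep(lat, times = grid$n_cols)
  covered <- rep(FALSE, length(px))
  for (f in feats) {
    # cheap bounding-box reject
    bb <- do.call(rbind, f$geometry)
    if (max(bb[, 1]) < grid$x_origin ||
        min(bb[, 1]) > grid$x_origin + grid$n_cols * grid$resolution ||
        max(bb[, 2]) < grid$y_origin - grid$n_rows * grid$resolution ||
        min(bb[, 2]) > grid$y_origin) next
    covered <- covered | points_in_feature(px, py, f)
  }
  out[covered] <- 1L
  out
}

#' Read / write polygon layers as GeoJSON
#'
#' Supports Polygon and MultiPolygon features; the feature property
#' `class_label` is preserved.
#'
#' @param path GeoJSON file path.
#' @return a [polygon_layer()].
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("format error: expected a GeoJSON FeatureCollection")
  feats <- lapply(gj$features, function(f) {
    label <- f$properties$class_label
    if (is.null(label)) label <- "feature"
    geom <- f$geometry
    rings <- list()
    to_ring <- function(coords)
      do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    if (geom$type == "Polygon") {
      rings <- lapply(geom$coordinates, to_ring)
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates)
        rings <- c(rings, lapply(poly, to_ring))
    } else stop("format error: unsupported geometry ", geom$type)
    list(geometry = rings, class_label = label)
  })
  polygon_layer(feats)
}

#' @rdname read_polygons_geojson
#' @param polygons a [polygon_layer()].
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(polygons$features, function(f) {
    coords <- lapply(f$geometry, function(ring)
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
    list(type = "Feature",
         properties = list(class_label = f$class_label),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
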