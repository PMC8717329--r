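# Synthetic island world: elevation-driven, mutually correlated bioclim
# layers, precipitation zones, virtual species, occurrence sampling,
# future-scenario deltas and conservation polygons. Everything downstream
# is tested against this world, so all randomness is drawn through a
# single integer seed with the caller's RNG state left untouched.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Layer typing used for scenario deltas: additive shifts act on mean-like
# temperature layers; range (bio2, bio7), ratio (bio3) and dispersion
# (bio4, bio15) layers are shift-invariant by construction.
TEMP_MEAN_LAYERS <- c("bio1", "bio5", "bio6", "bio8", "bio9", "bio10", "bio11")
PRECIP_LAYERS <- paste0("bio", 12:19)

#' Specification of a synthetic island
#'
#' @param n_rows,n_cols grid size in cells (default 120 x 150).
#' @param resolution cell size in degrees; default 30 arc-seconds.
#' @param seed integer seed driving every random field.
#' @param elevation_peaks data.frame with columns `row`, `col`,
#'   `height` (m) and `decay` (cells, Gaussian length scale). Default: one
#'   central massif and a lower southern ridge.
#' @param coast_threshold elevation (m) below which a cell is sea.
#' @param x_origin,y_origin upper-left corner in degrees.
#' @return object of class `island_spec`.
#' @export
island_spec <- function(n_rows = 120, n_cols = 150, resolution = 1 / 120,
                        seed = 1,
                        elevation_peaks = NULL,
                        coast_threshold = 0,
                        x_origin = 79.7, y_origin = 7.6) {
  if (is.null(elevation_peaks))
    elevation_peaks <- data.frame(
      row = c(round(n_rows * 0.55), round(n_rows * 0.75)),
      col = c(round(n_cols * 0.40), round(n_cols * 0.30)),
      height = c(2200, 900),
      decay = c(n_rows * 0.12, n_rows * 0.10))
  stopifnot(nrow(elevation_peaks) >= 1, all(elevation_peaks$height > 0))
  structure(list(n_rows = n_rows, n_cols = n_cols, resolution = resolution,
                 seed = as.integer(seed), elevation_peaks = elevation_peaks,
                 coast_threshold = coast_threshold,
                 x_origin = x_origin, y_origin = y_origin),
            class = "island_spec")
}

# smooth random field: white noise blurred by a separable moving average
smooth_noise <- function(n_rows, n_cols, sd = 1, half_window = 4) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  k <- 2 * half_window + 1
  run <- function(m) {
    out <- m
    cs <- apply(m, 2, cumsum)
    for (i in seq_len(n_rows)) {
      lo <- max(1, i - half_window); hi <- min(n_rows, i + half_window)
      top <- if (lo > 1) cs[lo - 1, ] else 0
      out[i, ] <- (cs[hi, ] - top) / (hi - lo + 1)
    }
    out
  }
  z <- run(z)
  z <- t(run(t(z)))
  z * sd / stats::sd(as.vector(z))
}

correlated_field <- function(parent, target_r, n_rows, n_cols) {
  zp <- (parent - mean(parent, na.rm = TRUE)) / stats::sd(as.vector(parent), na.rm = TRUE)
  noise <- smooth_noise(n_rows, n_cols, sd = 1)
  target_r * zp + sqrt(1 - target_r^2) * noise
}

#' Generate the synthetic island climate
#'
#' Builds a 19-layer bioclim-style stack on an island-shaped domain:
#' temperature layers fall with elevation at a ~6.5 degC/km lapse rate,
#' annual precipitation follows a west-to-east gradient with orographic
#' enhancement, and the remaining layers are correlated noise fields
#' (pairwise target |r| drawn from 0.3-0.9) so the collinearity filter has
#' something to do. Sea cells are nodata in every layer.
#'
#' @param spec an [island_spec()].
#' @return list with elements `stack` (a [climate_stack()]), `elevation`
#'   (matrix, m; NA at sea), `zones` (integer matrix: 1 wet, 2
#'   intermediate, 3 dry, 4 arid; NA at sea) and `grid`.
#' @export
make_island_climate <- function(spec) {
  nr <- spec$n_rows; nc <- spec$n_cols
  grid <- raster_grid(nr, nc, spec$x_origin, spec$y_origin, spec$resolution)
  with_local_seed(spec$seed, {
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    # elliptical coastal base: positive inside the island, negative outside
    dy <- (rows - (nr + 1) / 2) / (nr * 0.45)
    dx <- (cols - (nc + 1) / 2) / (nc * 0.45)
    elev <- 400 * (1 - (dx^2 + dy^2)) + smooth_noise(nr, nc, sd = 60)
    for (i in seq_len(nrow(spec$elevation_peaks))) {
      pk <- spec$elevation_peaks[i, ]
      d2 <- (rows - pk$row)^2 + (cols - pk$col)^2
      elev <- elev + pk$height * exp(-d2 / (2 * pk$decay^2))
    }
    sea <- elev < spec$coast_threshold
    elev[sea] <- NA

    elev_km <- elev / 1000
    x_norm <- (cols - 1) / (nc - 1)          # 0 west -> 1 east

    bio1 <- 27.5 - 6.5 * elev_km + smooth_noise(nr, nc, sd = 0.3)
    amp <- 3 + smooth_noise(nr, nc, sd = 0.5) + 1.5 * x_norm
    amp[amp < 0.5] <- 0.5
    bio5 <- bio1 + amp
    bio6 <- bio1 - amp
    bio7 <- bio5 - bio6
    bio2 <- 0.9 * amp + 0.5 + smooth_noise(nr, nc, sd = 0.2)
    bio3 <- 100 * bio2 / bio7
    bio4 <- 120 * amp + smooth_noise(nr, nc, sd = 25)

    bio12 <- 1100 + 3400 * (1 - x_norm)^1.6 + 0.25 * ifelse(is.na(elev), 0, elev) +
      smooth_noise(nr, nc, sd = 150)
    bio12[bio12 < 600] <- 600
    bio13 <- 0.28 * bio12 + smooth_noise(nr, nc, sd = 40)

    layers <- list(bio1 = bio1, bio2 = bio2, bio3 = bio3, bio4 = bio4,
                   bio5 = bio5, bio6 = bio6, bio7 = bio7,
                   bio12 = bio12, bio13 = bio13)
    # remaining temperature layers track bio1, remaining precipitation
    # layers track bio12, each with its own target correlation
    for (nm in c("bio8", "bio9", "bio10", "bio11")) {
      r <- stats::runif(1, 0.3, 0.9)
      layers[[nm]] <- bio1 + 2 * correlated_field(bio1, r, nr, nc) +
        stats::runif(1, -2, 2)
    }
    for (nm in c("bio14", "bio15", "bio16", "bio17", "bio18", "bio19")) {
      r <- stats::runif(1, 0.3, 0.9)
      f <- correlated_field(bio12, r, nr, nc)
      scale <- switch(nm, bio14 = 30, bio15 = 20, bio16 = 400,
                      bio17 = 80, bio18 = 250, bio19 = 300)
      base <- switch(nm, bio14 = 40, bio15 = 60, bio16 = 900,
                     bio17 = 150, bio18 = 500, bio19 = 600)
      v <- base + scale * f
      v[v < 0] <- 0
      layers[[nm]] <- v
    }
    layers <- layers[paste0("bio", 1:19)]
    for (nm in names(layers)) layers[[nm]][sea] <- NA

    zones <- classify_zones(layers$bio12)
    zones[sea] <- NA

    list(stack = climate_stack(grid, layers, "current"),
         elevation = elev, zones = zones, grid = grid)
  })
}

#' Precipitation zones from annual precipitation
#'
#' Wet > 2500 mm, intermediate 1750-2500 mm, dry < 1750 mm, arid below
#' `arid_cutoff`.
#'
#' @param bio12 annual precipitation matrix (mm).
#' @param arid_cutoff mm; default 1200.
#' @return integer matrix: 1 wet, 2 intermediate, 3 dry, 4 arid.
#' @export
classify_zones <- function(bio12, arid_cutoff = 1200) {
  z <- matrix(NA_integer_, nrow(bio12), ncol(bio12))
  z[bio12 > 2500] <- 1L
  z[bio12 <= 2500 & bio12 >= 1750] <- 2L
  z[bio12 < 1750] <- 3L
  z[bio12 < arid_cutoff] <- 4L
  z
}

#' Future-scenario delta
#'
#' @param label scenario id, e.g. `"MIROC5-rcp26-2050"`.
#' @param temp_shift degC added to mean-type temperature layers.
#' @param precip_scale multiplier on precipitation layers (> 0).
#' @return object of class `scenario_delta`.
#' @export
scenario_delta <- function(label, temp_shift, precip_scale) {
  stopifnot(precip_scale > 0)
  structure(list(label = label, temp_shift = temp_shift,
                 precip_scale = precip_scale), class = "scenario_delta")
}

#' Default scenario registry (2 GCMs x 3 RCPs x 2 periods)
#'
#' Warming magnitudes step up with the concentration pathway and the
#' period; the two synthetic GCMs differ in warming and drying strength.
#'
#' @return named list of [scenario_delta()] objects (12 scenarios).
#' @export
default_scenarios <- function() {
  out <- list()
  shifts <- c(rcp26 = 1.0, rcp45 = 1.8, rcp85 = 3.2)
  for (gcm in c("BCC", "MIROC5")) {
    gw <- if (gcm == "MIROC5") 1.25 else 1.0       # MIROC5 runs warmer/drier
    for (rcp in names(shifts)) {
      for (period in c("2050", "2070")) {
        pw <- if (period == "2070") 1.4 else 1.0
        lab <- paste(gcm, rcp, period, sep = "-")
        out[[lab]] <- scenario_delta(lab,
          temp_shift = shifts[[rcp]] * gw * pw,
          precip_scale = 1 - 0.05 * gw * pw * match(rcp, names(shifts)))
      }
    }
  }
  out
}

#' Apply a scenario delta to a climate stack
#'
#' Mean-type temperature layers get the additive shift; precipitation
#' layers are scaled; derived layers (`bio7 = bio5 - bio6`,
#' `bio3 = 100 bio2 / bio7`) are recomputed so the stack stays internally
#' consistent. Range/dispersion layers (bio2, bio4) are shift-invariant.
#'
#' @param stack a [climate_stack()].
#' @param delta a [scenario_delta()].
#' @return a new [climate_stack()] labelled with the scenario id.
#' @export
apply_scenario <- function(stack, delta) {
  layers <- stack$layers
  for (nm in intersect(TEMP_MEAN_LAYERS, names(layers)))
    layers[[nm]] <- layers[[nm]] + delta$temp_shift
  for (nm in intersect(PRECIP_LAYERS, names(layers)))
    layers[[nm]] <- layers[[nm]] * delta$precip_scale
  if (all(c("bio5", "bio6", "bio7") %in% names(layers)))
    layers[["bio7"]] <- layers[["bio5"]] - layers[["bio6"]]
  if (all(c("bio2", "bio3", "bio7") %in% names(layers)))
    layers[["bio3"]] <- 100 * layers[["bio2"]] / layers[["bio7"]]
  climate_stack(stack$grid, layers, delta$label)
}

#' Virtual species with known environmental response
#'
#' @param name species name.
#' @param response named list: per layer, numeric `c(linear, quadratic)`
#'   coefficients on the standardized layer.
#' @param prevalence_target mean suitability over land, in (0, 1); the
#'   intercept is auto-tuned to hit it.
#' @param endemic logical flag carried through to profiles.
#' @return object of class `virtual_species`.
#' @export
virtual_species <- function(name, response, prevalence_target = 0.2,
                            endemic = TRUE) {
  stopifnot(length(response) >= 1,
            prevalence_target > 0, prevalence_target < 1)
  if (!any(vapply(response, function(cf) any(cf != 0), logical(1))))
    stop("virtual species needs at least one nonzero coefficient")
  structure(list(name = name, response = response,
                 prevalence_target = prevalence_target, endemic = endemic),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' `plogis(intercept + sum(a * z + b * z^2))` over standardized layers,
#' with the intercept tuned so mean land suitability equals the species'
#' prevalence target (within 0.01).
#'
#' @param sp a [virtual_species()].
#' @param stack a [climate_stack()].
#' @return probability matrix (NA at sea).
#' @export
true_suitability <- function(sp, stack) {
  missing_layers <- setdiff(names(sp$response), names(stack$layers))
  if (length(missing_layers))
    stop("configuration error: response layer(s) not in stack: ",
         paste(missing_layers, collapse = ", "))
  land <- land_mask(stack)
  eta <- matrix(0, stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(sp$response)) {
    v <- stack$layers[[nm]]
    z <- (v - mean(v[land])) / stats::sd(v[land])
    cf <- sp$response[[nm]]
    eta <- eta + cf[1] * z + if (length(cf) > 1) cf[2] * z^2 else 0
  }
  ev <- eta[land]
  f <- function(b) mean(stats::plogis(b + ev)) - sp$prevalence_target
  b0 <- stats::uniroot(f, c(-60, 60), tol = 1e-10)$root
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  out[land] <- stats::plogis(b0 + ev)
  out
}

#' Sample presence records from a true suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability; an optional Gaussian jitter of `cluster_sd` cells emulates
#' clustered collecting. Jittered points falling in the sea are redrawn.
#'
#' @param truth probability matrix from [true_suitability()].
#' @param grid the [raster_grid()] the truth lives on.
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @param cluster_sd jitter scale in cells (0 = none).
#' @param species name written into the table.
#' @param elevation optional elevation matrix used to fill the elevation
#'   column.
#' @return occurrence data.frame (species, lon, lat, elevation, source).
#' @export
sample_occurrences <- function(truth, grid, n, seed = 1, cluster_sd = 0,
                               species = "virtual", elevation = NULL) {
  stopifnot(n >= 1)
  w <- as.vector(truth)
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("sampling error: suitability is zero everywhere")
  land <- !is.na(truth)
  with_local_seed(seed, {
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    row <- (idx - 1) %% nrow(truth) + 1
    col <- (idx - 1) %/% nrow(truth) + 1
    if (cluster_sd > 0) {
      for (i in seq_len(n)) {
        repeat {
          r2 <- row[i] + round(stats::rnorm(1, 0, cluster_sd))
          c2 <- col[i] + round(stats::rnorm(1, 0, cluster_sd))
          if (r2 >= 1 && r2 <= nrow(truth) && c2 >= 1 && c2 <= ncol(truth) &&
              land[r2, c2]) { row[i] <- r2; col[i] <- c2; break }
        }
      }
    }
    lon <- cell_center_lon(grid)[col]
    lat <- cell_center_lat(grid)[row]
    elev <- if (!is.null(elevation)) elevation[cbind(row, col)] else NA_real_
    data.frame(species = species, lon = lon, lat = lat,
               elevation = elev, source = "synthetic",
               stringsAsFactors = FALSE)
  })
}

#' Synthetic protected-area and forest-cover polygon layers
#'
#' Random axis-aligned rectangles on land. The conservation-forest
#' features are shrunken copies of the first protected rectangles, so
#' their rasterized mask is contained in the all-conserved mask by
#' construction. Forest rectangles are added until they cover 20-35% of
#' land.
#'
#' @param island output of [make_island_climate()].
#' @param seed integer seed.
#' @return list with `protected` (a [polygon_layer()] with class labels
#'   `conservation_forest` and `other_conserved`) and `forest` (class
#'   label `forest`).
#' @export
make_conservation_layers <- function(island, seed = 1) {
  grid <- island$grid
  land <- !is.na(island$elevation)
  lon <- cell_center_lon(grid); lat <- cell_center_lat(grid)
  res <- grid$resolution
  with_local_seed(seed, {
    rand_rect <- function(w_cells, h_cells, label) {
      # center on a random land cell
      cand <- which(land, arr.ind = TRUE)
      ctr <- cand[sample.int(nrow(cand), 1), ]
      cx <- lon[ctr[2]]; cy <- lat[ctr[1]]
      rect_feature(cx - w_cells / 2 * res, cx + w_cells / 2 * res,
                   cy - h_cells / 2 * res, cy + h_cells / 2 * res, label)
    }
    # rectangle sizes scale with the island so coverage fractions are
    # grid-size independent
    wr <- function(lo, hi) stats::runif(1, lo, hi) * grid$n_cols
    hr <- function(lo, hi) stats::runif(1, lo, hi) * grid$n_rows
    prot <- list()
    for (i in 1:6)
      prot[[i]] <- rand_rect(wr(0.05, 0.12), hr(0.05, 0.12), "other_conserved")
    # conservation forests: shrunken copies of the first three rectangles
    cf <- lapply(prot[1:3], function(f) {
      ring <- f$geometry[[1]]
      cx <- mean(range(ring[, 1])); cy <- mean(range(ring[, 2]))
      s <- 0.6
      ring2 <- cbind(cx + (ring[, 1] - cx) * s, cy + (ring[, 2] - cy) * s)
      list(geometry = list(ring2), class_label = "conservation_forest")
    })
    protected <- polygon_layer(c(prot, cf))

    n_land <- sum(land)
    forest <- list()
    frac <- 0
    while (frac < 0.22 && length(forest) < 80) {
      forest[[length(forest) + 1]] <- rand_rect(wr(0.05, 0.11), hr(0.05, 0.11),
                                                "forest")
      fm <- rasterize_polygons(polygon_layer(forest), grid)
      frac <- sum(fm == 1 & land) / n_land
    }
    list(protected = protected, forest = polygon_layer(forest))
  })
}
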