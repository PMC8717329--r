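# Config-driven orchestration: clean -> select variables -> tune -> fit
# replicates -> project scenarios -> metrics -> classify -> richness ->
# gap analysis, with artifact checksums in a run manifest.

#' Default pipeline configuration
#'
#' Pre-fills every analysis default: 100-km buffers, |r| <= 0.65
#' collinearity threshold, min 10 occupied cells per species, all seven
#' L/Q/H feature-class combinations with regularization multipliers 1-5
#' step 0.5, 10,000 background points, 20 bootstrap replicates with a
#' 70/30 split, 5000 optimizer iterations, clamped transfer and the
#' sensitivity = specificity operational threshold.
#'
#' @param seed integer seed.
#' @return named list of parameters.
#' @export
default_pipeline_params <- function(seed = 1) {
  list(min_count = 10, buffer_km = 100, r_threshold = 0.65,
       fc_grid = FC_GRID_DEFAULT, rm_grid = seq(1, 5, by = 0.5),
       hinge_knots = 20, n_background = 10000, n_replicates = 20,
       train_fraction = 0.7, max_iter = 5000, threshold_rule = "eq_ss",
       richness_level = NULL,
       area_cutoff_km2 = 10000, breadth_cutoff = 0.5,
       montane_elevation_m = 300, seed = as.integer(seed))
}

#' Run the full niche-modeling and gap-analysis pipeline
#'
#' @param occurrences occurrence data.frame (species, lon, lat, ...).
#' @param current_stack a [climate_stack()] for the current period.
#' @param scenario_stacks named list of future [climate_stack()]s.
#' @param zones climate-zone raster (1 wet, 2 intermediate, 3 dry,
#'   4 arid).
#' @param elevation elevation raster (m), used for montane/lowland calls
#'   when occurrence elevations are missing.
#' @param protected,forest [polygon_layer()]s; `protected` uses class
#'   labels `conservation_forest` / `other_conserved`.
#' @param endemic_flags named logical vector per species.
#' @param params parameter list, see [default_pipeline_params()].
#' @param overrides optional named character vector species -> category.
#' @param out_dir output directory; artifacts and the manifest are
#'   written there (NULL = no artifacts).
#' @return list: `cleaning`, `species` (per-species results), `profiles`,
#'   `categories`, `richness`, `uncertainty`, `gap`, `recommendation`,
#'   `manifest`.
#' @export
run_enm_pipeline <- function(occurrences, current_stack, scenario_stacks,
                             zones, elevation, protected, forest,
                             endemic_flags, params = default_pipeline_params(),
                             overrides = NULL, out_dir = NULL) {
  t_start <- Sys.time()
  timings <- list(); warnings_log <- character(0)
  stage <- function(nm, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, paste0(nm, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[nm]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  grid <- current_stack$grid
  areas <- cell_area_km2(grid)
  land <- land_mask(current_stack)

  cleaned <- stage("clean", clean_occurrences(occurrences, current_stack,
                                              min_count = params$min_count))
  occ <- cleaned$occurrences
  species <- unique(occ$species)
  if (!length(species)) stop("data error: no species survive cleaning")

  protected_all <- rasterize_polygons(protected, grid)
  conservation_forest <- rasterize_polygons(protected, grid,
                                            classes = "conservation_forest")
  forest_mask <- rasterize_polygons(forest, grid)

  sp_results <- list()
  for (sp in species) {
    sp_occ <- occ[occ$species == sp, , drop = FALSE]
    res <- stage(paste0("fit:", sp), {
      cal <- buffer_mask(sp_occ, current_stack, params$buffer_km)
      cm <- pearson_matrix(current_stack, cal$mask)
      sel <- filter_collinear(cm, params$r_threshold)
      vars <- sel$kept

      bg_cells <- sample_background(cal$mask, params$n_background,
                                    seed = params$seed)
      bg_env <- env_at_cells(current_stack, bg_cells, vars)
      pres_cells <- as.matrix(cell_index(grid, sp_occ$lon, sp_occ$lat))
      pres_env <- env_at_cells(current_stack, pres_cells, vars)
      study_cells <- which(land, arr.ind = TRUE)
      study_env <- env_at_cells(current_stack, study_cells, vars)

      tun <- tune_maxent(pres_env, bg_env, study_env,
                         fc_grid = params$fc_grid, rm_grid = params$rm_grid,
                         hinge_knots = params$hinge_knots,
                         max_iter = params$max_iter)
      reps <- replicate_fit(pres_env, bg_env, current_stack,
                            classes = fc_to_classes(tun$fc), rm = tun$rm,
                            hinge_knots = params$hinge_knots,
                            n_replicates = params$n_replicates,
                            train_fraction = params$train_fraction,
                            seed = params$seed, max_iter = params$max_iter)
      mean_map <- reps$mean_map
      pres_scores <- mean_map[pres_cells]
      bg_scores <- mean_map[cbind(bg_cells[, 1], bg_cells[, 2])]
      th <- thresholds(pres_scores, bg_scores)
      tau <- th[[params$threshold_rule]]
      # kappa is prevalence-sensitive: evaluate against a balanced
      # background subsample so the score is comparable across species
      bal <- with_local_seed(params$seed,
        sample(length(bg_scores), min(length(bg_scores), length(pres_scores))))
      kap <- kappa_at_threshold(pres_scores, bg_scores[bal], tau)
      bm <- binary_map(mean_map, tau)
      rep_bms <- lapply(reps$replicates, function(r) binary_map(r$map, tau))

      future <- list()
      for (lab in names(scenario_stacks)) {
        fmaps <- lapply(reps$replicates, function(r)
          logistic_map(r$fit, scenario_stacks[[lab]], clamp = TRUE))
        fmean <- Reduce(`+`, fmaps) / length(fmaps)
        fbm <- binary_map(fmean, tau)
        mess <- mess_map(scenario_stacks[[lab]], bg_env, vars)
        future[[lab]] <- list(
          mean_map = fmean, binary = fbm,
          replicate_binaries = lapply(fmaps, binary_map, tau = tau),
          area_km2 = suitable_area(fbm, areas),
          mess_min = min(mess$mess, na.rm = TRUE))
      }
      area_cur <- suitable_area(bm, areas)
      list(species = sp, vars = vars, tuning = tun$table,
           fc = tun$fc, rm = tun$rm,
           thresholds = th, tau = tau, kappa = kap$kappa,
           mean_map = mean_map, binary = bm,
           replicate_binaries = rep_bms,
           breadth = niche_breadth(mean_map),
           area_km2 = area_cur,
           future = future,
           occ_cells = pres_cells,
           occ_elev = if (all(is.na(sp_occ$elevation)))
             elevation[pres_cells] else sp_occ$elevation)
    })
    sp_results[[sp]] <- res
  }

  profiles <- list(); categories <- list()
  for (sp in species) {
    r <- sp_results[[sp]]
    zo <- zone_overlap_fractions(r$binary, zones, areas)
    prof <- species_profile(sp, endemic = isTRUE(endemic_flags[[sp]]),
                            current_area = r$area_km2, breadth = r$breadth,
                            occ_elevations = r$occ_elev, zone_overlap = zo)
    profiles[[sp]] <- prof
    categories[[sp]] <- classify_endemism(
      prof, overrides = overrides,
      area_cutoff_km2 = params$area_cutoff_km2,
      breadth_cutoff = params$breadth_cutoff,
      montane_elevation_m = params$montane_elevation_m)
  }
  labels <- vapply(categories, function(x) x$label, character(1))

  richness <- list(); uncertainty <- list()
  future_richness <- stats::setNames(
    rep(list(list()), length(scenario_stacks)), names(scenario_stacks))
  for (cat in unique(labels)) {
    members <- names(labels)[labels == cat]
    richness[[cat]] <- stack_richness(lapply(sp_results[members],
                                             function(r) r$binary))
    uncertainty[[cat]] <- uncertainty_map(lapply(sp_results[members],
                                                 function(r) r$replicate_binaries))
    for (lab in names(scenario_stacks))
      future_richness[[lab]][[cat]] <- stack_richness(
        lapply(sp_results[members], function(r) r$future[[lab]]$binary))
  }

  gap <- stage("gap", {
    g <- gap_report(richness, protected_all, conservation_forest,
                    forest_mask, areas, period = "current",
                    level = params$richness_level)
    for (lab in names(scenario_stacks))
      g <- rbind(g, gap_report(future_richness[[lab]], protected_all,
                               conservation_forest, NULL, areas,
                               period = lab, level = params$richness_level))
    g
  })

  dry_richness <- if ("nonendemic_dry" %in% names(richness)) {
    rm <- richness[["nonendemic_dry"]]
    !is.na(rm$counts) & rm$counts >= rm$max_count & rm$counts > 0
  } else NULL
  high_conf <- lapply(uncertainty, function(u) !is.na(u) & u == "always")
  recommendation <- recommendation_map(high_conf, dry_richness,
                                       forest_mask, protected_all)

  manifest <- list(
    created = format(t_start), seed = params$seed,
    n_species = length(species),
    config_hash = digest_params(params),
    stage_seconds = timings, warnings = warnings_log, files = list())

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    metr <- data.frame(
      species = species,
      category = labels[species],
      fc = vapply(sp_results[species], function(r) r$fc, character(1)),
      rm = vapply(sp_results[species], function(r) r$rm, numeric(1)),
      tau = vapply(sp_results[species], function(r) r$tau, numeric(1)),
      kappa = vapply(sp_results[species], function(r) r$kappa, numeric(1)),
      breadth = vapply(sp_results[species], function(r) r$breadth, numeric(1)),
      area_current_km2 = vapply(sp_results[species],
                                function(r) r$area_km2, numeric(1)))
    for (lab in names(scenario_stacks)) {
      fut <- vapply(sp_results[species],
                    function(r) r$future[[lab]]$area_km2, numeric(1))
      metr[[paste0("area_", lab)]] <- fut
      metr[[paste0("pct_", lab)]] <- ifelse(
        metr$area_current_km2 > 0,
        pct_change(metr$area_current_km2, fut), NA_integer_)
    }
    paths <- c(metrics = file.path(out_dir, "species_metrics.csv"),
               gap = file.path(out_dir, "gap_report.csv"),
               cleaning = file.path(out_dir, "cleaning_report.json"))
    utils::write.csv(metr, paths["metrics"], row.names = FALSE)
    utils::write.csv(gap, paths["gap"], row.names = FALSE)
    jsonlite::write_json(cleaned$report, paths["cleaning"],
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    for (cat in names(richness)) {
      p <- file.path(out_dir, paste0("richness_", cat, ".asc"))
      write_ascii_grid(richness[[cat]]$counts, grid, p)
      paths[paste0("richness_", cat)] <- p
    }
    p <- file.path(out_dir, "recommendation.asc")
    write_ascii_grid(recommendation * 1, grid, p)
    paths["recommendation"] <- p
    manifest$files <- as.list(tools::md5sum(paths))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(cleaning = cleaned$report, species = sp_results,
       profiles = profiles, categories = categories,
       richness = richness, uncertainty = uncertainty,
       future_richness = future_richness, gap = gap,
       recommendation = recommendation, manifest = manifest)
}

digest_params <- function(params) {
  # cheap stable hash of the configuration (md5 of its deparsed form)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(params[order(names(params))]), tf)
  unname(tools::md5sum(tf))
}
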