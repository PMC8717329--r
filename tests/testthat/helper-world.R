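# Shared fixtures, built in code. The "small world" is a scaled-down
# island (40 x 50 cells instead of the 120 x 150 default) so the unit
# suite stays fast; tests that depend on the stated full-scale world say
# so explicitly.

small_island_spec <- function(seed = 11) {
  island_spec(n_rows = 40, n_cols = 50, seed = seed)
}

# memoized: the same world is reused across test files
.world_cache <- new.env(parent = emptyenv())

small_world <- function(seed = 11) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- make_island_climate(small_island_spec(seed))
  .world_cache[[key]]
}

# a virtual species responding to the two canonical climate axes
lq_species <- function(prevalence = 0.15) {
  virtual_species("vsp", list(bio1 = c(1.5, -1), bio12 = c(1, 0)),
                  prevalence_target = prevalence)
}

# presence/background environment matrices for a species in a world
model_inputs <- function(world, truth, n_pres = 60, seed = 1,
                         n_background = 2000, buffer_km = 100) {
  occ <- sample_occurrences(truth, world$grid, n_pres, seed = seed)
  cal <- buffer_mask(occ, world$stack, buffer_km)
  vars <- filter_collinear(pearson_matrix(world$stack, cal$mask))$kept
  bg <- sample_background(cal$mask, n_background, seed = seed)
  pres_cells <- as.matrix(cell_index(world$grid, occ$lon, occ$lat))
  list(occ = occ, vars = vars, mask = cal$mask,
       pres_cells = pres_cells,
       pres_env = env_at_cells(world$stack, pres_cells, vars),
       bg_cells = bg,
       bg_env = env_at_cells(world$stack, bg, vars))
}

# full-scale (120 x 150) island, memoized: shared by the recovery tests
full_island <- function(seed = 7) {
  key <- paste0("full", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- make_island_climate(island_spec(seed = seed))
  .world_cache[[key]]
}

with_seed_rnorm <- function(seed, n) {
  withr::with_seed(seed, rnorm(n))
}

# tiny deterministic stack for exact-arithmetic tests
toy_stack <- function(layers, n_rows, n_cols, resolution = 1) {
  grid <- raster_grid(n_rows, n_cols, x_origin = 0, y_origin = n_rows * resolution,
                      resolution = resolution)
  climate_stack(grid, layers)
}
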