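test_that("island generation is deterministic and physically sane", {
  w1 <- make_island_climate(small_island_spec(5))
  w2 <- make_island_climate(small_island_spec(5))
  expect_identical(w1$stack$layers, w2$stack$layers)
  expect_identical(w1$zones, w2$zones)

  land <- land_mask(w1$stack)
  expect_gt(sum(land), 100)
  # temperature falls with elevation (lapse-driven)
  expect_lt(cor(w1$stack$layers$bio1[land], w1$elevation[land]), -0.8)
  # every land cell carries exactly one zone, sea is NA everywhere
  expect_true(all(w1$zones[land] %in% 1:4))
  expect_true(all(is.na(w1$zones[!land])))
  expect_true(all(is.na(w1$stack$layers$bio12[!land])))
})

test_that("zone raster reproduces the precipitation partition from bio12", {
  w <- small_world()
  land <- land_mask(w$stack)
  z <- classify_zones(w$stack$layers$bio12)
  expect_identical(z[land], w$zones[land])
  p <- w$stack$layers$bio12[land]
  expect_true(all(z[land][p > 2500] == 1))
  expect_true(all(z[land][p >= 1750 & p <= 2500] == 2))
  expect_true(all(z[land][p < 1750 & p >= 1200] == 3))
  expect_true(all(z[land][p < 1200] == 4))
})

test_that("scenario deltas shift, scale and keep derived layers consistent", {
  w <- small_world()
  land <- land_mask(w$stack)
  ident <- apply_scenario(w$stack, scenario_delta("null", 0, 1))
  expect_equal(ident$layers, w$stack$layers)

  warm <- apply_scenario(w$stack, scenario_delta("warm", 2, 1))
  expect_equal(mean(warm$layers$bio1[land]),
               mean(w$stack$layers$bio1[land]) + 2, tolerance = 1e-12)
  # annual range bio7 = bio5 - bio6 is invariant under a uniform shift
  expect_equal(warm$layers$bio7, w$stack$layers$bio7, tolerance = 1e-12)
  expect_equal(warm$layers$bio7, warm$layers$bio5 - warm$layers$bio6,
               tolerance = 1e-12)

  dry <- apply_scenario(w$stack, scenario_delta("dry", 0, 0.8))
  expect_equal(dry$layers$bio12, w$stack$layers$bio12 * 0.8, tolerance = 1e-12)
  expect_length(default_scenarios(), 12)
})

test_that("true suitability hits its prevalence target and response shape", {
  w <- small_world()
  land <- land_mask(w$stack)
  tr <- true_suitability(lq_species(0.15), w$stack)
  expect_equal(mean(tr[land]), 0.15, tolerance = 0.01)

  # all-zero response: constant surface at the prevalence target
  flat <- structure(list(name = "flat", response = list(bio1 = c(0, 0)),
                         prevalence_target = 0.3, endemic = TRUE),
                    class = "virtual_species")
  trf <- true_suitability(flat, w$stack)
  expect_equal(unique(round(trf[land], 10)), 0.3)
  expect_error(virtual_species("bad", list(bio1 = c(0, 0))), "nonzero")

  # single negative linear coefficient: monotone decreasing in the layer
  dec <- virtual_species("dec", list(bio1 = c(-1, 0)), prevalence_target = 0.3)
  trd <- true_suitability(dec, w$stack)
  ord <- order(w$stack$layers$bio1[land])
  expect_true(all(diff(trd[land][ord]) <= 1e-12))

  # quadratic-only species peaks at the standardized mean
  quad <- virtual_species("quad", list(bio1 = c(0, -1)), prevalence_target = 0.3)
  trq <- true_suitability(quad, w$stack)
  b1 <- w$stack$layers$bio1[land]
  z <- abs(b1 - mean(b1)) / sd(b1)
  expect_equal(which.max(trq[land]), which.min(z))

  expect_error(true_suitability(lq_species(), climate_stack(
    w$grid, w$stack$layers["bio2"])), "configuration error")
})

test_that("occurrence sampling is seeded, weighted and validated", {
  w <- small_world()
  tr <- true_suitability(lq_species(), w$stack)
  one <- sample_occurrences(tr, w$grid, 1, seed = 9)
  expect_equal(nrow(one), 1)
  a <- sample_occurrences(tr, w$grid, 30, seed = 4, cluster_sd = 1)
  b <- sample_occurrences(tr, w$grid, 30, seed = 4, cluster_sd = 1)
  expect_identical(a, b)
  expect_error(sample_occurrences(matrix(0, 4, 4), raster_grid(4, 4, 0, 4, 1), 5),
               "sampling error")
})

test_that("sampling concentrates in the high-suitability quadrant", {
  grid <- raster_grid(20, 20, 0, 20, 1)
  truth <- matrix(0.01, 20, 20)
  truth[1:10, 1:10] <- 0.9    # hot NW quadrant
  for (s in 1:20) {
    occ <- sample_occurrences(truth, grid, 50, seed = s)
    nw <- mean(occ$lon < 10 & occ$lat > 10)
    expect_gte(nw, 0.8)
  }
})

test_that("conservation layers nest, replay and cover the stated band", {
  w <- small_world()
  land <- land_mask(w$stack)
  c1 <- make_conservation_layers(w, seed = 21)
  c2 <- make_conservation_layers(w, seed = 21)
  expect_identical(c1, c2)
  all_prot <- rasterize_polygons(c1$protected, w$grid)
  cf <- rasterize_polygons(c1$protected, w$grid, classes = "conservation_forest")
  expect_true(all(cf <= all_prot))
  frac <- sum(rasterize_polygons(c1$forest, w$grid) == 1 & land) / sum(land)
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.35)
})
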