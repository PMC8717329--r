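# the penalized-fit oracle: the objective written out independently of
# the implementation, maximized by grid search (1-D, exhaustive) or
# Nelder-Mead multistart (2-3 features)
pen_objective <- function(beta, pres, bg, lambda) {
  mean(pres %*% beta) - log(sum(exp(bg %*% beta))) - sum(lambda * abs(beta))
}

test_that("feature construction follows the L/Q/H contracts", {
  set.seed(8)
  bg <- cbind(x = rnorm(100, 5, 2))
  spec <- feature_spec(bg, classes = c("L", "Q"), hinge_knots = 5)
  # linear feature of the background mean is 0 before rescaling
  at_mean <- build_features(spec, cbind(x = mean(bg[, "x"])), rescale = FALSE)
  expect_equal(unname(at_mean[1, "L_x"]), 0, tolerance = 1e-12)
  # quadratic features of x and -x coincide
  q1 <- build_features(spec, cbind(x = 7))[, "Q_x"]
  q2 <- build_features(spec, cbind(x = 2 * mean(bg[, "x"]) - 7))[, "Q_x"]
  expect_equal(q1, q2, tolerance = 1e-12)

  # forward hinge anchored at the minimum is the min-max rescaled variable
  hs <- feature_spec(bg, classes = "H", hinge_knots = 4)
  f <- build_features(hs, bg)
  mn <- min(bg[, "x"]); mx <- max(bg[, "x"])
  expect_equal(unname(f[, 1]), (bg[, "x"] - mn) / (mx - mn), tolerance = 1e-12)
  # all rescaled background features live in [0, 1]
  full <- feature_spec(bg, classes = c("L", "Q", "H"), hinge_knots = 6)
  fb <- build_features(full, bg)
  expect_gte(min(fb), 0); expect_lte(max(fb), 1)

  # constant variables are dropped and recorded
  bg2 <- cbind(x = rnorm(50), flat = rep(3, 50))
  s2 <- feature_spec(bg2, classes = c("L", "Q"))
  expect_equal(s2$dropped_constant, "flat")
  expect_error(feature_spec(cbind(flat = rep(1, 10))), "degenerate")
})

test_that("penalized fit matches the exhaustive 1-D oracle", {
  bgx <- matrix(seq(-1, 1, length.out = 200), ncol = 1,
                dimnames = list(NULL, "x"))
  prx <- matrix(c(0.7, 0.8, 0.85, 0.9, 1.0), ncol = 1,
                dimnames = list(NULL, "x"))
  fit <- fit_penalized(prx, bgx, rm = 1)
  expect_gt(fit$beta, 0)                     # presences sit at high x
  grid <- seq(-20, 20, by = 0.001)
  oracle <- max(vapply(grid, pen_objective, numeric(1),
                       pres = prx, bg = bgx, lambda = fit$lambda))
  expect_lt(abs(oracle - fit$objective), 1e-6)
})

test_that("penalized fit matches multistart maximization on 3 features", {
  set.seed(5)
  n <- 150
  bg <- cbind(x = rnorm(n), y = runif(n), z = rbinom(n, 1, 0.4))
  pr <- cbind(x = rnorm(40, 1), y = runif(40)^2, z = rbinom(40, 1, 0.7))
  fit <- fit_penalized(pr, bg, rm = 1.5)
  best <- -Inf
  for (s in 1:20) {
    set.seed(s)
    o <- stats::optim(rnorm(3, 0, 2),
                      function(b) -pen_objective(b, pr, bg, fit$lambda),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- max(best, -o$value)
  }
  expect_gte(fit$objective, best - 1e-5)
  # no local improvement from the fitted point either
  polish <- -stats::optim(fit$beta,
                          function(b) -pen_objective(b, pr, bg, fit$lambda),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 5000))$value
  expect_lt(polish - fit$objective, 1e-5)
})

test_that("no-signal model scores exactly 0.5 and huge penalties kill all terms", {
  set.seed(3)
  bg <- cbind(a = rnorm(300), b = runif(300))
  fit <- maxent_fit(bg, bg, classes = c("L", "Q"), rm = 1)
  expect_true(all(fit$beta == 0))
  expect_equal(unique(predict(fit, bg)), 0.5)
  expect_equal(fit$entropy, log(300), tolerance = 1e-12)

  pr <- cbind(a = rnorm(30, 2), b = runif(30))
  strong <- fit_penalized(pr, bg, rm = 1000)
  expect_true(all(strong$beta == 0))
})

test_that("clamped projection freezes predictions outside the calibration range", {
  set.seed(9)
  bg <- cbind(x = runif(200, 0, 10))
  pr <- cbind(x = runif(30, 6, 9))
  fit <- maxent_fit(pr, bg, classes = "L", rm = 1)
  inside <- predict(fit, cbind(x = 10), clamp = TRUE)
  beyond <- predict(fit, cbind(x = 25), clamp = TRUE)
  expect_equal(beyond, predict(fit, cbind(x = max(bg[, "x"]))))
  free <- predict(fit, cbind(x = 25), clamp = FALSE)
  expect_false(isTRUE(all.equal(free, beyond)))

  # projecting onto the training stack reproduces training predictions
  w <- small_world()
  land <- land_mask(w$stack)
  tr <- true_suitability(lq_species(), w$stack)
  mi <- model_inputs(w, tr, n_pres = 40, seed = 2, n_background = 500)
  f2 <- maxent_fit(mi$pres_env, mi$bg_env, classes = c("L", "Q"), rm = 1)
  m <- logistic_map(f2, w$stack)
  expect_equal(m[mi$pres_cells],
               unname(predict(f2, mi$pres_env)), tolerance = 1e-12)
  expect_true(all(m[land] >= 0 & m[land] <= 1))
  expect_true(all(is.na(m[!land])))
  expect_error(logistic_map(f2, climate_stack(w$grid, w$stack$layers["bio2"])),
               "projection error")
})

test_that("aicc follows the corrected formula with its guard", {
  expect_equal(aicc(2, -5, 10), 4 + 10 + 12 / 7)
  expect_equal(aicc(9, -5, 10), Inf)
  expect_lt(aicc(2, -5, 10), aicc(3, -5, 10))
})

test_that("AUC is the Mann-Whitney statistic with half ties", {
  expect_equal(auc_mw(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc_mw(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(auc_mw(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
})

test_that("tuning selects by AICc with deterministic tie-breaks", {
  w <- small_world()
  land <- land_mask(w$stack)
  tr <- true_suitability(lq_species(), w$stack)
  mi <- model_inputs(w, tr, n_pres = 40, seed = 3, n_background = 500)
  vars <- c("bio1", "bio12")
  pe <- env_at_cells(w$stack, mi$pres_cells, vars)
  be <- env_at_cells(w$stack, mi$bg_cells, vars)
  se <- env_at_cells(w$stack, which(land, arr.ind = TRUE), vars)
  single <- tune_maxent(pe, be, se, fc_grid = "L", rm_grid = 2)
  expect_true(single$table$selected)
  expect_equal(single$fc, "L")

  tab <- tune_maxent(pe, be, se, fc_grid = c("L", "LQ"),
                     rm_grid = c(1, 2))$table
  expect_equal(sum(tab$selected), 1)
  expect_equal(tab$aicc[tab$selected], min(tab$aicc))
})

test_that("tuning on a true LQ species picks a nonlinear feature class", {
  # measured over fixed seeds 1-10: an fc containing Q or H is selected
  # 8/10 times (hinge features mimic the quadratic response; pure L wins
  # twice); coefficient-sign recovery at the true class is tested below
  w <- small_world()
  land <- land_mask(w$stack)
  tr <- true_suitability(lq_species(), w$stack)
  vars <- c("bio1", "bio12")
  se <- env_at_cells(w$stack, which(land, arr.ind = TRUE), vars)
  nonlinear <- 0
  for (s in 1:10) {
    occ <- sample_occurrences(tr, w$grid, 60, seed = s)
    pc <- as.matrix(cell_index(w$grid, occ$lon, occ$lat))
    pe <- env_at_cells(w$stack, pc, vars)
    bg <- sample_background(land, 1000, seed = s)
    be <- env_at_cells(w$stack, bg, vars)
    fc <- tune_maxent(pe, be, se)$fc
    nonlinear <- nonlinear + any(c("Q", "H") %in% fc_to_classes(fc))
  }
  expect_gte(nonlinear, 8)
})

test_that("generating coefficient signs are recovered at the true class", {
  w <- small_world()
  land <- land_mask(w$stack)
  tr <- true_suitability(lq_species(), w$stack)
  vars <- c("bio1", "bio12")
  ok <- 0
  for (s in 1:10) {
    occ <- sample_occurrences(tr, w$grid, 60, seed = s)
    pc <- as.matrix(cell_index(w$grid, occ$lon, occ$lat))
    pe <- env_at_cells(w$stack, pc, vars)
    bg <- sample_background(land, 1000, seed = s)
    be <- env_at_cells(w$stack, bg, vars)
    f <- maxent_fit(pe, be, classes = c("L", "Q"), rm = 1)
    ok <- ok + (f$beta[["L_bio1"]] > 0 && f$beta[["Q_bio1"]] < 0 &&
                  f$beta[["L_bio12"]] > 0)
  }
  expect_gte(ok, 9)
})

test_that("larger penalties never add nonzero coefficients", {
  w <- small_world()
  tr <- true_suitability(lq_species(), w$stack)
  mi <- model_inputs(w, tr, n_pres = 50, seed = 6, n_background = 800)
  ks <- vapply(c(0.5, 1, 2, 4, 8), function(rm) {
    f <- maxent_fit(mi$pres_env, mi$bg_env, classes = c("L", "Q"), rm = rm)
    sum(f$beta != 0)
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("replicate fits are seeded, convex-bounded and degenerate-safe", {
  w <- small_world()
  tr <- true_suitability(lq_species(), w$stack)
  mi <- model_inputs(w, tr, n_pres = 30, seed = 4, n_background = 400)
  land <- land_mask(w$stack)
  r1 <- replicate_fit(mi$pres_env, mi$bg_env, w$stack, classes = "L",
                      rm = 1, n_replicates = 4, seed = 77)
  r2 <- replicate_fit(mi$pres_env, mi$bg_env, w$stack, classes = "L",
                      rm = 1, n_replicates = 4, seed = 77)
  expect_equal(r1$mean_map, r2$mean_map)
  stack_min <- Reduce(pmin, lapply(r1$replicates, `[[`, "map"))
  stack_max <- Reduce(pmax, lapply(r1$replicates, `[[`, "map"))
  expect_true(all(r1$mean_map[land] >= stack_min[land] - 1e-12))
  expect_true(all(r1$mean_map[land] <= stack_max[land] + 1e-12))
  expect_error(replicate_fit(mi$pres_env[1:4, ], mi$bg_env, w$stack),
               "sample-size")

  # a single unique presence profile makes every replicate identical
  uni <- mi$pres_env[rep(1, 10), ]
  ru <- replicate_fit(uni, mi$bg_env, w$stack, classes = "L", rm = 1,
                      n_replicates = 3, seed = 5)
  expect_equal(ru$replicates[[1]]$map, ru$replicates[[2]]$map)
  expect_equal(ru$replicates[[2]]$map, ru$replicates[[3]]$map)
})

test_that("jackknife importance brackets single-variable models", {
  w <- small_world()
  tr <- true_suitability(lq_species(), w$stack)
  mi <- model_inputs(w, tr, n_pres = 40, seed = 8, n_background = 500)
  vars <- c("bio1", "bio12")
  pe <- env_at_cells(w$stack, mi$pres_cells, vars)
  be <- env_at_cells(w$stack, mi$bg_cells, vars)
  jk <- jackknife_importance(pe, be, classes = "L", rm = 1, seed = 2)
  expect_true(all(jk$auc_without >= 0 & jk$auc_without <= 1, na.rm = TRUE))
  expect_true(all(jk$auc_only_with >= 0 & jk$auc_only_with <= 1))

  one <- jackknife_importance(pe[, "bio1", drop = FALSE],
                              be[, "bio1", drop = FALSE],
                              classes = "L", rm = 1, seed = 2)
  expect_equal(one$auc_only_with[1], attr(one, "auc_full"))
})

test_that("a pure-noise variable carries less information than the signal", {
  w <- small_world()
  tr <- true_suitability(lq_species(), w$stack)
  land <- land_mask(w$stack)
  wins <- 0
  for (s in 1:10) {
    occ <- sample_occurrences(tr, w$grid, 50, seed = s)
    pc <- as.matrix(cell_index(w$grid, occ$lon, occ$lat))
    bg <- sample_background(land, 400, seed = s)
    pe <- cbind(env_at_cells(w$stack, pc, "bio1"),
                noise = with_seed_rnorm(s, nrow(pc)))
    be <- cbind(env_at_cells(w$stack, bg, "bio1"),
                noise = with_seed_rnorm(s + 1000, nrow(bg)))
    jk <- jackknife_importance(pe, be, classes = "L", rm = 1, seed = s)
    i <- which(jk$variable == "noise")
    wins <- wins + (jk$auc_without[i] >= jk$auc_only_with[i])
  }
  expect_gte(wins, 8)
})

test_that("permutation importance is normalized and finds the signal", {
  w <- small_world()
  tr <- true_suitability(lq_species(), w$stack)
  land <- land_mask(w$stack)
  # single informative variable takes ~everything
  occ <- sample_occurrences(tr, w$grid, 50, seed = 3)
  pc <- as.matrix(cell_index(w$grid, occ$lon, occ$lat))
  bg <- sample_background(land, 400, seed = 3)
  pe <- cbind(env_at_cells(w$stack, pc, "bio1"),
              noise = with_seed_rnorm(3, nrow(pc)))
  be <- cbind(env_at_cells(w$stack, bg, "bio1"),
              noise = with_seed_rnorm(1003, nrow(bg)))
  # linear model: a quadratic term would soak up noise via overfitting
  # (measured: noise median 11% under LQ, 0% under L)
  fit <- maxent_fit(pe, be, classes = "L", rm = 1)
  imps <- sapply(1:10, function(s) permutation_importance(fit, pe, be, seed = s))
  expect_true(all(abs(colSums(imps) - 100) < 0.1))
  expect_lte(median(imps["noise", ]), 5)
  expect_gte(median(imps["bio1", ]), 95)
})
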