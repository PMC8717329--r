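# Presence-background maximum-entropy model, fitted from scratch.
#
# The model is the Gibbs / infinitely-weighted-logistic formulation: with
# features f(x) and coefficients beta, eta(x) = beta . f(x), the fit
# maximizes
#
#   (1/m) sum_presence eta(x_i) - log sum_background exp(eta(x_j))
#       - sum_j lambda_j |beta_j|
#
# by FISTA proximal-gradient iterations with backtracking. Raw output is
# q(x) = exp(eta) / sum_bg exp(eta); logistic output is
# s(x) = q e^H / (1 + q e^H) with H the entropy of the normalized
# background distribution, so the no-signal model scores exactly 0.5.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

soft_threshold <- function(x, t) sign(x) * pmax(0, abs(x) - t)

# Maxent-default per-class regularization constant, interpolated on ln m
# between the published (m, c) anchors for linear/quadratic features;
# hinge features use the constant 0.5.
reg_constant <- function(class, m) {
  if (class == "H") return(0.5)
  anchors_m <- c(10, 30, 100)
  anchors_c <- c(1.0, 0.2, 0.05)
  if (m <= anchors_m[1]) return(anchors_c[1])
  if (m >= anchors_m[3]) return(anchors_c[3])
  stats::approx(log(anchors_m), anchors_c, xout = log(m))$y
}

#' Penalized maximum-entropy fit on prepared feature matrices
#'
#' Low-level fitter; most callers use [maxent_fit()]. Penalties are
#' `lambda_j = rm * c(class_j, m) * sd_j / sqrt(m)` with `sd_j` the
#' presence standard deviation of feature j (background sd when the
#' presence sd is zero), `c` the Maxent-style per-class constant and `m`
#' the presence count.
#'
#' @param pres_feat,bg_feat presence and background design matrices
#'   (same columns).
#' @param rm regularization multiplier (> 0).
#' @param f_class character vector: feature class ("L"/"Q"/"H") per column.
#' @param max_iter optimizer iteration cap (default 5000).
#' @param tol stop when the objective changes by less than this (1e-7).
#' @return list: `beta`, `lambda`, `objective` (the maximized value),
#'   `converged`, `iterations`.
#' @export
fit_penalized <- function(pres_feat, bg_feat, rm = 1,
                          f_class = rep("L", ncol(bg_feat)),
                          max_iter = 5000, tol = 1e-7, beta0 = NULL) {
  stopifnot(rm > 0, ncol(pres_feat) == ncol(bg_feat))
  m <- nrow(pres_feat)
  if (m < 2) stop("need at least 2 presences")
  p <- ncol(bg_feat)
  if (p == 0 || all(apply(bg_feat, 2, stats::sd) == 0))
    stop("degenerate-fit error: no variation in features")

  sd_pres <- apply(pres_feat, 2, stats::sd)
  sd_bg <- apply(bg_feat, 2, stats::sd)
  sd_j <- ifelse(sd_pres > 0, sd_pres, sd_bg)
  cc <- vapply(f_class, reg_constant, numeric(1), m = m)
  lambda <- rm * cc * sd_j / sqrt(m)

  pres_mean <- colMeans(pres_feat)
  g_of <- function(beta) {
    logsumexp(drop(bg_feat %*% beta)) - sum(pres_mean * beta)
  }

  beta <- if (is.null(beta0)) numeric(p) else beta0
  y <- beta
  tk <- 1
  L <- 1
  F_old <- g_of(beta) + sum(lambda * abs(beta))
  converged <- FALSE
  iter <- 0
  g_beta <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1
    # one pass over the background gives both g(y) and its gradient
    eta_y <- drop(bg_feat %*% y)
    lse_y <- logsumexp(eta_y)
    gy <- lse_y - sum(pres_mean * y)
    w <- exp(eta_y - lse_y)
    gr <- drop(crossprod(bg_feat, w)) - pres_mean
    repeat {
      z <- soft_threshold(y - gr / L, lambda / L)
      dz <- z - y
      gz <- g_of(z)
      if (gz <= gy + sum(gr * dz) + L / 2 * sum(dz^2) + 1e-12) break
      L <- 2 * L
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- z + ((tk - 1) / t_new) * (z - beta)
    beta <- z
    g_beta <- gz
    tk <- t_new
    L <- max(L * 0.9, 1e-4)
    F_new <- gz + sum(lambda * abs(beta))
    if (abs(F_old - F_new) < tol) { converged <- TRUE; break }
    F_old <- F_new
  }
  if (!converged)
    warning("iteration cap (", max_iter, ") hit before convergence")
  if (is.na(g_beta)) g_beta <- g_of(beta)
  list(beta = stats::setNames(beta, colnames(bg_feat)), lambda = lambda,
       objective = -(g_beta + sum(lambda * abs(beta))),
       converged = converged, iterations = iter)
}

#' Fit a maximum-entropy niche model from environment samples
#'
#' Builds L/Q/H features on the background, fits the L1-penalized model
#' and packages everything needed for (clamped) projection: the
#' coefficient vector, penalty weights, log-normalizer, background
#' entropy H and the calibration ranges.
#'
#' @param pres_env,bg_env presence / background environment matrices
#'   (named columns).
#' @param classes feature classes, subset of `c("L","Q","H")`.
#' @param rm regularization multiplier.
#' @param hinge_knots hinge knots per variable.
#' @param max_iter,tol optimizer controls.
#' @return object of class `maxent_fit`: `beta`, `lambda`,
#'   `log_normalizer`, `entropy`, `calib_range`, `fc`, `rm`, `spec`,
#'   `converged`, `objective`, `n_presence`, `n_background`.
#' @export
maxent_fit <- function(pres_env, bg_env, classes = c("L", "Q"), rm = 1,
                       hinge_knots = 20, max_iter = 5000, tol = 1e-7) {
  spec <- feature_spec(bg_env, classes, hinge_knots)
  pf <- build_features(spec, pres_env)
  bf <- build_features(spec, bg_env)
  fit <- fit_penalized(pf, bf, rm = rm, f_class = spec$f_class,
                       max_iter = max_iter, tol = tol)
  eta_bg <- drop(bf %*% fit$beta)
  logZ <- logsumexp(eta_bg)
  q <- exp(eta_bg - logZ)
  structure(list(
    beta = fit$beta, lambda = fit$lambda,
    log_normalizer = logZ, entropy = -sum(q * log(q)),
    calib_range = cbind(min = spec$vmin, max = spec$vmax),
    fc = paste(sort(spec$classes), collapse = ""), rm = rm, spec = spec,
    converged = fit$converged, objective = fit$objective,
    n_presence = nrow(pres_env), n_background = nrow(bg_env)),
    class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf("maxent_fit: fc=%s rm=%.2g, %d/%d nonzero features, H=%.3f\n",
              x$fc, x$rm, sum(x$beta != 0), length(x$beta), x$entropy))
  invisible(x)
}

#' Predict suitability for environment rows
#'
#' @param object a [maxent_fit()].
#' @param env environment matrix.
#' @param type `"logistic"` (0-1 suitability), `"raw"` (Gibbs probability
#'   normalized over the fit's background) or `"eta"` (linear predictor).
#' @param clamp clip variables into the calibration range first.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.maxent_fit <- function(object, env, type = c("logistic", "raw", "eta"),
                               clamp = TRUE, ...) {
  type <- match.arg(type)
  f <- build_features(object$spec, env, clamp = clamp)
  eta <- drop(f %*% object$beta)
  if (type == "eta") return(eta)
  logq <- eta - object$log_normalizer
  if (type == "raw") return(exp(logq))
  stats::plogis(logq + object$entropy)
}

#' Project a fitted model over a climate stack
#'
#' @param fit a [maxent_fit()].
#' @param stack a [climate_stack()] supplying every model variable.
#' @param clamp clip projected variables into the calibration range
#'   (transfer clamping; default on).
#' @return suitability matrix in [0, 1]; NA propagates from nodata cells.
#' @export
logistic_map <- function(fit, stack, clamp = TRUE) {
  missing_vars <- setdiff(fit$spec$vars, names(stack$layers))
  if (length(missing_vars))
    stop("projection error: stack lacks variable(s): ",
         paste(missing_vars, collapse = ", "))
  land <- land_mask(stack)
  idx <- which(land)
  env <- vapply(fit$spec$vars, function(v) stack$layers[[v]][idx],
                numeric(length(idx)))
  if (length(idx) == 1) env <- matrix(env, nrow = 1,
                                      dimnames = list(NULL, fit$spec$vars))
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  out[idx] <- predict(fit, env, type = "logistic", clamp = clamp)
  out
}

#' Small-sample-corrected AIC
#'
#' `2k - 2 logL + 2k(k+1)/(n-k-1)`; `+Inf` when `n - k - 1 <= 0`.
#'
#' @param k number of nonzero coefficients.
#' @param logL model log-likelihood at the presences.
#' @param n presence count.
#' @return AICc value.
#' @export
aicc <- function(k, logL, n) {
  stopifnot(n >= 1)
  if (n - k - 1 <= 0) return(Inf)
  2 * k - 2 * logL + 2 * k * (k + 1) / (n - k - 1)
}

# Presence log-likelihood for AICc: raw output normalized over the whole
# study area (all land cells), evaluated at the presence rows.
presence_loglik <- function(fit, pres_env, study_env) {
  eta_study <- drop(build_features(fit$spec, study_env) %*% fit$beta)
  eta_pres <- drop(build_features(fit$spec, pres_env) %*% fit$beta)
  sum(eta_pres - logsumexp(eta_study))
}

#' Feature-class grid used for tuning
#'
#' All seven combinations of linear, quadratic and hinge features.
#' @export
FC_GRID_DEFAULT <- c("L", "Q", "H", "LQ", "LH", "QH", "LQH")

#' Split a feature-class label like "LQH" into its classes
#' @param fc feature-class label.
#' @return character vector of single classes.
#' @export
fc_to_classes <- function(fc) strsplit(fc, "")[[1]]

#' Tune feature class and regularization multiplier by AICc
#'
#' One penalized fit per candidate (full presence data); the row with the
#' minimum finite AICc is selected, ties broken by smaller k then smaller
#' rm. Rows with `k >= n - 1` score `+Inf`.
#'
#' @param pres_env,bg_env presence / background environment matrices.
#' @param study_env environment rows of the whole study area (land cells)
#'   used to normalize the AICc likelihood.
#' @param fc_grid feature-class combinations (default all seven L/Q/H
#'   combinations).
#' @param rm_grid regularization multipliers (default 1 to 5 step 0.5).
#' @param hinge_knots hinge knots per variable.
#' @param max_iter optimizer cap per fit.
#' @return list: `table` (data.frame fc, rm, k, logL, aicc, selected),
#'   `fc`, `rm` (the winners).
#' @export
tune_maxent <- function(pres_env, bg_env, study_env,
                        fc_grid = FC_GRID_DEFAULT,
                        rm_grid = seq(1, 5, by = 0.5),
                        hinge_knots = 20, max_iter = 5000) {
  stopifnot(length(fc_grid) >= 1, length(rm_grid) >= 1)
  n <- nrow(pres_env)
  rows <- list()
  rm_grid <- sort(rm_grid, decreasing = TRUE)  # warm-start down the path
  for (fc in fc_grid) {
    spec <- feature_spec(bg_env, fc_to_classes(fc), hinge_knots)
    pf <- build_features(spec, pres_env)
    bf <- build_features(spec, bg_env)
    sf <- build_features(spec, study_env)
    beta_prev <- NULL
    for (rm in rm_grid) {
      fit <- fit_penalized(pf, bf, rm = rm, f_class = spec$f_class,
                           max_iter = max_iter, beta0 = beta_prev)
      beta_prev <- fit$beta
      k <- sum(fit$beta != 0)
      lseS <- logsumexp(drop(sf %*% fit$beta))
      ll <- sum(drop(pf %*% fit$beta) - lseS)
      rows[[length(rows) + 1]] <-
        data.frame(fc = fc, rm = rm, k = k, logL = ll,
                   aicc = aicc(k, ll, n))
    }
  }
  tab <- do.call(rbind, rows)
  if (all(!is.finite(tab$aicc)))
    stop("tuning error: all AICc infinite; more presences needed")
  ord <- order(tab$aicc, tab$k, tab$rm)
  best <- ord[1]
  tab$selected <- seq_len(nrow(tab)) == best
  list(table = tab, fc = tab$fc[best], rm = tab$rm[best])
}

#' Bootstrap replicate fits and the mean suitability map
#'
#' Per replicate: a random 70/30 train/test split of the presences, a
#' bootstrap resample within the training set, a penalized fit and a
#' (clamped) projection. The final map is the cell-wise mean of the
#' replicate logistic maps.
#'
#' @param pres_env presence environment matrix (>= 5 rows).
#' @param bg_env background environment matrix.
#' @param stack stack to project each replicate onto.
#' @param classes,rm,hinge_knots model settings (typically the tuning
#'   winners).
#' @param n_replicates number of replicates (default 20).
#' @param train_fraction training share of the presences (default 0.7).
#' @param seed integer seed fixing the whole replicate sequence.
#' @param max_iter optimizer cap per fit.
#' @return list: `replicates` (list of `fit`, `train_idx`, `test_idx`,
#'   `map`), `mean_map`.
#' @export
replicate_fit <- function(pres_env, bg_env, stack, classes = c("L", "Q"),
                          rm = 1, hinge_knots = 20, n_replicates = 20,
                          train_fraction = 0.7, seed = 1, max_iter = 5000) {
  n <- nrow(pres_env)
  if (n < 5) stop("sample-size error: need at least 5 presences")
  stopifnot(train_fraction > 0, train_fraction < 1)
  with_local_seed(seed, {
    reps <- vector("list", n_replicates)
    acc <- NULL
    for (r in seq_len(n_replicates)) {
      train_idx <- sort(sample.int(n, max(2, round(train_fraction * n))))
      test_idx <- setdiff(seq_len(n), train_idx)
      boot_idx <- sample(train_idx, length(train_idx), replace = TRUE)
      fit <- maxent_fit(pres_env[boot_idx, , drop = FALSE], bg_env,
                        classes = classes, rm = rm,
                        hinge_knots = hinge_knots, max_iter = max_iter)
      map <- logistic_map(fit, stack, clamp = TRUE)
      reps[[r]] <- list(fit = fit, train_idx = train_idx,
                        test_idx = test_idx, boot_idx = boot_idx, map = map)
      acc <- if (is.null(acc)) map else acc + map
    }
    list(replicates = reps, mean_map = acc / n_replicates)
  })
}

#' Rank-based AUC (Mann-Whitney; ties count one half)
#'
#' @param pred_pres scores at presences.
#' @param pred_bg scores at background points.
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(pred_pres, pred_bg) {
  stopifnot(length(pred_pres) > 0, length(pred_bg) > 0)
  r <- rank(c(pred_pres, pred_bg))
  m <- length(pred_pres)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(pred_bg))
}

#' Jackknife variable importance
#'
#' For each model variable: refit without it and refit with only it, and
#' score each refit by test AUC (70/30 presence split; background reused
#' as pseudo-absence).
#'
#' @param pres_env,bg_env presence / background environment matrices.
#' @param classes,rm,hinge_knots model settings.
#' @param seed seed for the split.
#' @param max_iter optimizer cap.
#' @return data.frame: variable, auc_without, auc_only_with, plus the
#'   full-model test AUC as attribute `auc_full`.
#' @export
jackknife_importance <- function(pres_env, bg_env, classes = c("L", "Q"),
                                 rm = 1, hinge_knots = 20, seed = 1,
                                 max_iter = 5000) {
  vars <- colnames(bg_env)
  n <- nrow(pres_env)
  with_local_seed(seed, {
    train <- sort(sample.int(n, max(2, round(0.7 * n))))
    test <- setdiff(seq_len(n), train)
    if (!length(test)) test <- train
    score <- function(keep_vars) {
      fit <- maxent_fit(pres_env[train, keep_vars, drop = FALSE],
                        bg_env[, keep_vars, drop = FALSE],
                        classes = classes, rm = rm,
                        hinge_knots = hinge_knots, max_iter = max_iter)
      auc_mw(predict(fit, pres_env[test, keep_vars, drop = FALSE]),
             predict(fit, bg_env[, keep_vars, drop = FALSE]))
    }
    auc_full <- score(vars)
    out <- data.frame(variable = vars,
                      auc_without = NA_real_, auc_only_with = NA_real_)
    for (i in seq_along(vars)) {
      v <- vars[i]
      out$auc_without[i] <- if (length(vars) > 1) score(setdiff(vars, v))
                            else NA_real_
      out$auc_only_with[i] <- score(v)
    }
    attr(out, "auc_full") <- auc_full
    out
  })
}

#' Permutation variable importance
#'
#' Shuffles each variable's values across the pooled presence+background
#' rows, recomputes the training AUC with the fitted coefficients, takes
#' `max(0, auc_orig - auc_perm)` and normalizes the importances to sum
#' to 100.
#'
#' @param fit a [maxent_fit()].
#' @param pres_env,bg_env the environment matrices the fit was trained on.
#' @param seed integer seed.
#' @return named numeric vector of percentages (sums to 100).
#' @export
permutation_importance <- function(fit, pres_env, bg_env, seed = 1) {
  vars <- fit$spec$vars
  auc0 <- auc_mw(predict(fit, pres_env), predict(fit, bg_env))
  m <- nrow(pres_env)
  pooled <- rbind(pres_env[, vars, drop = FALSE],
                  bg_env[, vars, drop = FALSE])
  with_local_seed(seed, {
    raw <- stats::setNames(numeric(length(vars)), vars)
    for (v in vars) {
      perm <- pooled
      perm[, v] <- sample(perm[, v])
      ap <- auc_mw(predict(fit, perm[seq_len(m), , drop = FALSE]),
                   predict(fit, perm[-seq_len(m), , drop = FALSE]))
      raw[v] <- max(0, auc0 - ap)
    }
    if (sum(raw) == 0) rep(100 / length(vars), length(vars))
    else 100 * raw / sum(raw)
  })
}

#' Sample background cells from a mask
#'
#' Uniform random cells without replacement over the mask; if fewer than
#' `n` valid cells exist, all are used (with a notice).
#'
#' @param mask logical matrix of candidate cells.
#' @param n target count (default 10000).
#' @param seed integer seed.
#' @return two-column matrix of (row, col) indices.
#' @export
sample_background <- function(mask, n = 10000, seed = 1) {
  cells <- which(mask)
  if (length(cells) <= n) {
    if (length(cells) < n)
      message("background: only ", length(cells),
              " valid cells; using all of them")
    sel <- cells
  } else {
    sel <- with_local_seed(seed, sample(cells, n))
  }
  cbind(row = (sel - 1) %% nrow(mask) + 1,
        col = (sel - 1) %/% nrow(mask) + 1)
}

#' Extract environment rows at cells of a stack
#'
#' @param stack a [climate_stack()].
#' @param cells two-column (row, col) matrix.
#' @param vars layer names (default all).
#' @return matrix with one row per cell.
#' @export
env_at_cells <- function(stack, cells, vars = names(stack$layers)) {
  out <- vapply(vars, function(v) stack$layers[[v]][cells],
                numeric(nrow(cells)))
  if (nrow(cells) == 1)
    out <- matrix(out, nrow = 1, dimnames = list(NULL, vars))
  out
}
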