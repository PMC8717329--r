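# Feature construction for the maximum-entropy model: linear (L),
# quadratic (Q) and hinge (H) transforms of the environmental variables,
# standardized against the background sample and rescaled to [0, 1].

#' Fit a feature specification on the background sample
#'
#' Records, per variable, the background mean/sd (standardization), the
#' background min/max (the calibration range used for clamping and as
#' hinge anchors) and the hinge knot positions; and, per derived feature,
#' the background min/max used for the final [0, 1] rescale. Constant
#' variables are dropped and recorded in `$dropped_constant`.
#'
#' @param bg_env background environment matrix (rows = cells, named cols).
#' @param classes subset of `c("L", "Q", "H")`.
#' @param hinge_knots knots per variable, evenly spaced between the
#'   background min and max (default 20; >= 2 when "H" is used).
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(bg_env, classes = c("L", "Q", "H"),
                         hinge_knots = 20) {
  classes <- match.arg(classes, c("L", "Q", "H"), several.ok = TRUE)
  if ("H" %in% classes && hinge_knots < 2)
    stop("hinge features need at least 2 knots")
  stopifnot(is.matrix(bg_env), !is.null(colnames(bg_env)))
  sds <- apply(bg_env, 2, stats::sd)
  dropped_constant <- colnames(bg_env)[sds == 0 | is.na(sds)]
  vars <- setdiff(colnames(bg_env), dropped_constant)
  if (!length(vars)) stop("degenerate-fit error: all variables constant")
  bg <- bg_env[, vars, drop = FALSE]
  spec <- structure(list(
    classes = classes, vars = vars,
    mean = colMeans(bg), sd = apply(bg, 2, stats::sd),
    vmin = apply(bg, 2, min), vmax = apply(bg, 2, max),
    hinge_knots = hinge_knots,
    knots = lapply(stats::setNames(vars, vars), function(v)
      seq(min(bg[, v]), max(bg[, v]), length.out = hinge_knots)),
    dropped_constant = dropped_constant,
    f_min = NULL, f_max = NULL, f_class = NULL, f_var = NULL),
    class = "feature_spec")
  raw <- raw_features(spec, bg)
  fmin <- apply(raw$m, 2, min)
  fmax <- apply(raw$m, 2, max)
  keep <- fmax > fmin
  spec$f_min <- fmin[keep]
  spec$f_max <- fmax[keep]
  spec$f_class <- raw$class[keep]
  spec$f_var <- raw$var[keep]
  spec$f_keep <- keep
  spec
}

# features before the [0,1] rescale
raw_features <- function(spec, env) {
  cols <- list(); fclass <- character(0); fvar <- character(0)
  for (v in spec$vars) {
    x <- env[, v]
    z <- (x - spec$mean[[v]]) / spec$sd[[v]]
    if ("L" %in% spec$classes) {
      cols[[paste0("L_", v)]] <- z
      fclass <- c(fclass, "L"); fvar <- c(fvar, v)
    }
    if ("Q" %in% spec$classes) {
      cols[[paste0("Q_", v)]] <- z^2
      fclass <- c(fclass, "Q"); fvar <- c(fvar, v)
    }
    if ("H" %in% spec$classes) {
      kn <- spec$knots[[v]]
      K <- length(kn)
      lo <- spec$vmin[[v]]; hi <- spec$vmax[[v]]
      for (k in kn[-K]) {
        cols[[sprintf("Hf_%s_%.6g", v, k)]] <-
          pmin(1, pmax(0, (x - k) / (hi - k)))
        fclass <- c(fclass, "H"); fvar <- c(fvar, v)
      }
      for (k in kn[-1]) {
        cols[[sprintf("Hr_%s_%.6g", v, k)]] <-
          pmin(1, pmax(0, (k - x) / (k - lo)))
        fclass <- c(fclass, "H"); fvar <- c(fvar, v)
      }
    }
  }
  m <- do.call(cbind, cols)
  list(m = m, class = fclass, var = fvar)
}

#' Build the design matrix for an environment sample
#'
#' @param spec a fitted [feature_spec()].
#' @param env environment matrix with (at least) the spec's variables.
#' @param rescale rescale features to [0, 1] using the background range
#'   (the model's convention). Set FALSE to get plain standardized
#'   features.
#' @param clamp clip each variable into the background (calibration)
#'   range before deriving features.
#' @return numeric feature matrix.
#' @export
build_features <- function(spec, env, rescale = TRUE, clamp = FALSE) {
  missing_vars <- setdiff(spec$vars, colnames(env))
  if (length(missing_vars))
    stop("projection error: missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  env <- env[, spec$vars, drop = FALSE]
  if (clamp)
    for (v in spec$vars)
      env[, v] <- pmin(spec$vmax[[v]], pmax(spec$vmin[[v]], env[, v]))
  raw <- raw_features(spec, env)$m[, spec$f_keep, drop = FALSE]
  if (!rescale) return(raw)
  sweep(sweep(raw, 2, spec$f_min, "-"), 2, spec$f_max - spec$f_min, "/")
}
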