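# Thresholding, Cohen's kappa, MESS extrapolation surfaces, Levins niche
# breadth and suitable-area / habitat-change accounting.

#' Candidate binarization thresholds
#'
#' Computes the three standard presence-background threshold rules:
#' minimum training presence (`mtp`), sensitivity = specificity
#' (`eq_ss`) and maximum sensitivity + specificity (`max_ss`, Youden).
#' Background points act as pseudo-absences for specificity. Candidate
#' thresholds are scanned at the midpoints between consecutive distinct
#' observed scores (plus the extremes); ties prefer the lower threshold.
#'
#' @param pres_scores suitability at training presences.
#' @param bg_scores suitability at background points.
#' @return list: `mtp`, `eq_ss`, `max_ss`, `degenerate` (TRUE when all
#'   scores are equal).
#' @export
thresholds <- function(pres_scores, bg_scores) {
  stopifnot(length(pres_scores) > 0, length(bg_scores) > 0)
  all_scores <- sort(unique(c(pres_scores, bg_scores)))
  degenerate <- length(all_scores) == 1
  cand <- if (degenerate) all_scores else
    c(all_scores[1], (all_scores[-1] + all_scores[-length(all_scores)]) / 2,
      all_scores[length(all_scores)] + 1e-9)
  sens <- vapply(cand, function(t) mean(pres_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(bg_scores < t), numeric(1))
  pick <- function(crit) cand[which(crit == min(crit))[1]]   # lowest tau wins
  list(mtp = min(pres_scores),
       eq_ss = pick(abs(sens - spec)),
       max_ss = pick(-(sens + spec)),
       degenerate = degenerate)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e`; defined as 0 when `p_e = 1`.
#'
#' @param tp,fp,fn,tn confusion counts (non-negative).
#' @return list: `kappa`, `confusion`.
#' @export
kappa_score <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  n <- tp + fp + fn + tn
  if (n == 0) stop("input error: empty confusion matrix")
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  k <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  list(kappa = k, confusion = c(TP = tp, FP = fp, FN = fn, TN = tn))
}

#' Evaluate a thresholded model against presences and background
#'
#' @param pres_scores,bg_scores suitability scores.
#' @param tau threshold.
#' @return a [kappa_score()] result for the induced confusion matrix.
#' @export
kappa_at_threshold <- function(pres_scores, bg_scores, tau) {
  kappa_score(tp = sum(pres_scores >= tau), fp = sum(bg_scores >= tau),
              fn = sum(pres_scores < tau), tn = sum(bg_scores < tau))
}

#' Binarize a suitability map
#'
#' Cell = 1 iff suitability >= tau; nodata stays NA.
#'
#' @param suit suitability matrix.
#' @param tau threshold.
#' @return integer 0/1 matrix with NAs preserved.
#' @export
binary_map <- function(suit, tau) {
  out <- matrix(NA_integer_, nrow(suit), ncol(suit))
  ok <- !is.na(suit)
  out[ok] <- as.integer(suit[ok] >= tau)
  out
}

#' Suitable area of a binary map
#'
#' @param bm binary 0/1 matrix ([binary_map()]).
#' @param areas per-cell area matrix ([cell_area_km2()]).
#' @return total km2 over cells equal to 1.
#' @export
suitable_area <- function(bm, areas) {
  sum(areas[which(bm == 1)])
}

#' Percent change in suitable area
#'
#' Integer percent, rounded half away from zero. `a_fut = 0` gives -100.
#'
#' @param a_cur current area (> 0), km2.
#' @param a_fut future area, km2.
#' @return integer percent.
#' @export
pct_change <- function(a_cur, a_fut) {
  stopifnot(all(a_cur > 0))
  x <- 100 * (a_fut - a_cur) / a_cur
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Levins niche breadth of a suitability surface
#'
#' With `p_i = s_i / sum(s)` over valid cells,
#' `B = (1 / sum(p_i^2) - 1) / (n - 1)`: 1 for a uniform (generalist)
#' surface, 0 for a single-cell (specialist) one. Invariant under
#' positive rescaling of the suitabilities.
#'
#' @param suit suitability matrix (NA = nodata).
#' @return breadth in [0, 1].
#' @export
niche_breadth <- function(suit) {
  s <- suit[!is.na(suit)]
  if (sum(s) == 0) stop("undefined-breadth error: all suitabilities zero")
  p <- s / sum(s)
  n <- length(p)
  if (n == 1) return(0)
  (1 / sum(p^2) - 1) / (n - 1)
}

#' Multivariate environmental similarity of one point
#'
#' Per variable, with `f` the percentage of reference values strictly
#' below the point value: `s = 100 (p - min)/(max - min)` when `f = 0`;
#' `2 f` when `0 < f <= 50`; `2 (100 - f)` when `50 < f < 100`;
#' `100 (max - p)/(max - min)` when `f = 100`. MESS is the minimum over
#' variables; negative iff some variable lies outside its reference
#' range.
#'
#' @param point named numeric vector of environment values.
#' @param ref reference environment matrix (columns >= names of `point`).
#' @return list: `mess`, `similarity` (named per-variable vector).
#' @export
mess_point <- function(point, ref) {
  vars <- names(point)
  s <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    rv <- ref[, v]
    rv <- rv[!is.na(rv)]
    p <- point[[v]]
    mn <- min(rv); mx <- max(rv)
    if (mx == mn) {
      s[v] <- if (p == mx) 0 else -Inf
      next
    }
    f <- 100 * mean(rv < p)
    s[v] <- if (f == 0) 100 * (p - mn) / (mx - mn)
      else if (f <= 50) 2 * f
      else if (f < 100) 2 * (100 - f)
      else 100 * (mx - p) / (mx - mn)
  }
  list(mess = min(s), similarity = s)
}

#' MESS surface of a stack against a reference sample
#'
#' @param stack a [climate_stack()] (the transfer climate).
#' @param ref reference environment matrix (calibration sample).
#' @param vars variables to use (default: columns of `ref`).
#' @return list: `mess` (matrix), `similarity` (named list of matrices).
#' @export
mess_map <- function(stack, ref, vars = colnames(ref)) {
  land <- land_mask(stack)
  idx <- which(land)
  nr <- stack$grid$n_rows; nc <- stack$grid$n_cols
  sim <- stats::setNames(vector("list", length(vars)), vars)
  mess <- matrix(NA_real_, nr, nc)
  acc <- rep(Inf, length(idx))
  for (v in vars) {
    rv <- ref[, v]
    rv <- rv[!is.na(rv)]
    mn <- min(rv); mx <- max(rv)
    p <- stack$layers[[v]][idx]
    if (mx == mn) {
      sv <- ifelse(p == mx, 0, -Inf)
    } else {
      # f = % of reference strictly below p, via the reference ECDF
      f <- 100 * (findInterval(p, sort(rv), left.open = TRUE)) / length(rv)
      sv <- ifelse(f == 0, 100 * (p - mn) / (mx - mn),
            ifelse(f <= 50, 2 * f,
            ifelse(f < 100, 2 * (100 - f),
                   100 * (mx - p) / (mx - mn))))
    }
    m <- matrix(NA_real_, nr, nc)
    m[idx] <- sv
    sim[[v]] <- m
    acc <- pmin(acc, sv)
  }
  mess[idx] <- acc
  list(mess = mess, similarity = sim)
}
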