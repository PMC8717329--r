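---
title: "Methods: presence-background niche models and conservation gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background niche models and conservation gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`enmgap` implements a complete presence-background ecological niche
modeling (ENM) workflow for an island flora: occurrence cleaning,
collinearity-aware variable selection, a from-scratch maximum-entropy
model with AICc tuning, bootstrap replication and clamped transfer to
future climate scenarios, binarization and agreement metrics, endemism
categorization, stacked richness and uncertainty mapping, and
protected-area gap analysis. A synthetic island generator supplies a
world in which every "true" quantity is known, so the whole pipeline is
exercised and tested without downloading climate, land-cover or
protected-area products.

# The model

## Features and objective

Environmental variables are transformed into features: linear (the
standardized value $z$), quadratic ($z^2$) and hinge features
$\max(0, (x-k)/(\max-k))$ and $\max(0, (k-x)/(k-\min))$ at `hinge_knots`
(default 20) evenly spaced knots per variable. All features are rescaled
to $[0,1]$ over the background sample. With $\eta(x)=\beta^\top f(x)$,
the fit maximizes the penalized presence-background likelihood

$$\frac{1}{m}\sum_{i \in \text{presence}} \eta(x_i)
  \;-\; \log \sum_{j \in \text{background}} e^{\eta(x_j)}
  \;-\; \sum_j \lambda_j |\beta_j|,$$

the Gibbs ("infinitely weighted logistic") formulation used by Maxent
and maxnet. Penalties follow the Maxent defaults:
$\lambda_j = \mathrm{rm}\cdot c(\text{class}, m)\cdot s_j/\sqrt{m}$,
where $s_j$ is the presence standard deviation of feature $j$ (background
s.d. when that is zero), $m$ the presence count, and $c$ interpolates the
published linear/quadratic constants $\{(10,1.0),(30,0.2),(100,0.05)\}$
on $\ln m$ (hinge: $0.5$). The regularization multiplier `rm` scales all
penalties.

Optimization is FISTA proximal-gradient with backtracking; the iteration
cap is 5000 and convergence is declared when the objective changes by
less than $10^{-7}$. On instances small enough for brute force
(1-3 features), the fitted objective agrees with exhaustive grid search /
multistart Nelder-Mead to better than $10^{-5}$ (tested).

## Outputs

Raw output is $q(x) = e^{\eta(x)}/\sum_{bg} e^{\eta}$. Logistic output is
$s(x) = q e^{H}/(1 + q e^{H})$, with $H$ the entropy of the normalized
background distribution. A model with no signal therefore scores exactly
0.5 everywhere (tested as an identity, not approximately).

## Tuning, replication, transfer

All seven combinations of L/Q/H are crossed with regularization
multipliers 1-5 in 0.5 steps. Each candidate is fitted once on the full
presence set; AICc is $2k - 2\log L + 2k(k+1)/(n-k-1)$ with $k$ the
number of nonzero coefficients and $\log L$ the raw output normalized
over all study-area cells, evaluated at the presences ($+\infty$ when
$n-k-1 \le 0$). The minimum-AICc row wins; ties prefer smaller $k$, then
smaller rm. The winning setting is refitted in 20 bootstrap replicates
(70/30 train/test split, bootstrap within the training set), and the
final suitability map is the cell-wise replicate mean. Transfers to
scenario climates clamp each variable into its calibration range before
feature construction, so predictions beyond the training envelope are
frozen at the envelope edge.

A note from tuning experiments on the synthetic world: hinge features
approximate smooth quadratic responses well, so for a species generated
with linear + quadratic structure the AICc winner frequently contains H
instead of Q (a nonlinear class is selected on 8 of 10 fixed seeds; both
L and Q literally on only 3). Coefficient *signs* at the true feature
class are recovered on 10/10 seeds.

# Upstream choices

* **Cleaning.** Duplicates are exact (species, lon, lat) matches after
  rounding to 6 decimals (GPS precision). Thinning keeps the first-seen
  record per raster cell; the minimum-count rule (default 10) applies to
  distinct occupied cells, since the model sees one point per cell.
  Species with all records in one cell are dropped with their own reason
  code.
* **Calibration areas.** 100-km haversine buffers (sphere $R=6371$ km)
  around each species' occurrences, intersected with land. Background
  (default 10,000 points) is sampled uniformly without replacement from
  this mask; when fewer valid cells exist, all are used.
* **Collinearity.** Pearson correlations over all buffer land cells;
  greedy elimination (drop the variable with the largest mean absolute
  correlation to survivors, ties by input order) until all pairs satisfy
  $|r| \le 0.65$. Undefined correlations (zero-variance layers) count as
  $|r| = 1$, which is conservative.
* **Areas.** Cell areas use the spherical cosine approximation
  $(111.320\,\mathrm{res})^2 \cos(\mathrm{lat})$ km^2^; at island scale
  the error is far below other uncertainties. Summed over a coarse
  whole-globe grid this model overshoots $4\pi R^2$ by 2.85%, which the
  tests assert as a property of the model rather than hiding.

# Metrics

* **Thresholds.** Minimum training presence, sensitivity = specificity,
  and maximum sensitivity + specificity, scanned at midpoints between
  distinct observed scores with ties resolved toward the lower
  threshold. Background points act as pseudo-absences (only presence
  data exist). The operational rule is sensitivity = specificity; the
  others are computed and reported.
* **Kappa.** Cohen's $\kappa$ from the thresholded confusion matrix.
  $\kappa$ is prevalence-sensitive: against 10,000 background points and
  ~20 presences it collapses toward 0 regardless of skill, so the
  pipeline evaluates it against a balanced background subsample (same
  size as the presence set, seeded). Maps with $\kappa < 0.4$ are
  flagged, not discarded.
* **MESS.** The standard similarity-surface formula per variable with
  the minimum over variables; negative values flag novel climate. The
  current stack against its own calibration sample is non-negative
  everywhere (tested).
* **Niche breadth.** Levins' standardized inverse concentration
  $B = (1/\sum p_i^2 - 1)/(n-1)$ on the suitability distribution;
  invariant under positive rescaling.
* **Percent change.** Integer percent, rounded half away from zero;
  complete loss is $-100$.

# Endemism categories and gap analysis

Endemic species with suitable area $\ge$ 10,000 km^2^ and breadth
$\ge 0.5$ are wide endemics; endemic species below both cutoffs are
narrow endemics, montane when the minimum occurrence elevation exceeds
300 m, lowland otherwise. The published cutoffs are strict inequalities;
they are applied as $\ge$ so that a boundary profile (14,152 km^2^,
$B = 0.50$) classifies wide, matching its published label. Nonendemics
are wet- or dry-zone by the dominant climate-zone share of their
suitable area. Two published species contradict the stated rule on their
own published numbers; they ship as an explicit override table
(`memecylon_category_overrides()`), not as hidden logic. An endemic
profile matching neither rule raises an error asking for an override.
The area/breadth cutoffs are pipeline parameters because they are tied
to the real island's size (65,525 km^2^); the synthetic island is ~100x
smaller.

Richness maps are cell-wise sums of member binary maps; the "richness
area" is the cells at the maximum overlap level (configurable).
Uncertainty is a tri-state per cell: *always* (every replicate of every
member predicts presence), *mixed* (every member has at least one
presence-predicting replicate, but not *always*), *absent* (some member
never predicts it). Gap reports intersect richness areas with the
all-conserved mask (union of protected classes), the
conservation-forest class and (current period only) forest cover;
future periods keep the current protected layers fixed; categories with
total habitat loss yield N/A rows. The recommendation map flags
forested, unprotected cells in any category's high-confidence richness
or in the dry-zone richness area.

# The synthetic world

`make_island_climate()` builds an elliptical island with Gaussian
mountain peaks (default: a 2200-m central massif and a 900-m southern
ridge on a 120 x 150 grid of 30-arc-second cells). Temperature layers
follow a 6.5 degC/km lapse rate; annual precipitation runs from a wet
west (>4000 mm) to a dry east (~1100 mm) with orographic enhancement,
giving wet / intermediate / dry / arid zones at the 2500 / 1750 / 1200 mm
thresholds. A physically consistent subset (bio1, bio5, bio6,
bio7 = bio5 - bio6, bio2, bio3 = 100 bio2/bio7, bio4, bio12, bio13) is
derived; the remaining layers are correlated noise fields tracking
either bio1 or bio12 with target $|r|$ drawn from $[0.3, 0.9]$ — enough
structure to exercise the collinearity filter without a climate
simulator. Scenario deltas add warming to mean-type temperature layers,
scale precipitation layers, and recompute derived layers; the default
registry covers 2 GCM proxies x 3 concentration pathways x 2 periods
with warming from 1.0 to 5.6 degC.

Virtual species have logistic suitability in linear/quadratic terms of
standardized layers, with the intercept tuned by root finding so mean
land suitability hits a prevalence target (default choices in tests:
0.08-0.2, typical of woody plants on tropical islands). Occurrences are
drawn with probability proportional to suitability, with optional
Gaussian jitter (cells) to emulate clustered collecting. Conservation
and forest layers are random rectangles scaled to the island; the
conservation-forest polygons are shrunken copies of protected
rectangles (nesting by construction) and forest rectangles accumulate
until they cover 20-35% of land.

What a green test does *not* establish: the generator has no spatial
sampling bias toward roads or herbaria, no dispersal limitation, no
label noise in species identity, and its future scenarios are uniform
deltas rather than GCM fields — so pipeline performance here is an
upper bound on real-data behavior.

## Known limitation: recovery through the collinearity filter

With the generating variables (bio1, bio12) available to the model,
replicate LQ fits recover the true suitability surface at median
Spearman $\rho = 0.96$ over five seeds. Run through the full pipeline,
the $|r| \le 0.65$ filter — behaving exactly as designed — removes
those hub variables in favor of less-correlated proxies, and recovery
drops to median $\rho = 0.79$ (tuned variants 0.72-0.82). The property
test asserts the measured level (median $\ge 0.75$); the idealized 0.8
through-the-filter bound is not met in this world and we chose not to
weaken the filter or re-design the species to force it.

# Numerical choices

* All randomness flows through explicit integer seeds via a local-RNG
  helper; no function perturbs the caller's RNG state.
* Grids are upper-left registered with cell-center semantics; a cell is
  inside a polygon iff its center is (even-odd rule), matching
  cell-count area estimates.
* Nodata is a single sentinel on disk and `NA` in memory; a cell missing
  in any layer is excluded from background sampling, areas and metrics.
* I/O is plain text: ESRI ASCII grids (17-significant-digit values, so
  round-trips are exact), GeoJSON polygons, CSV occurrences. No binary
  raster formats are read or written because no R spatial stack is
  assumed.
* Degenerate inputs have defined behavior rather than crashes: empty
  occurrence tables produce zeroed reports; constant variables lose
  their derived features (recorded); all-equal score sets flag the
  threshold set as degenerate; zero suitability raises an explicit
  sampling/breadth error.
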