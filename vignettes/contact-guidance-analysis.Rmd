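---
title: "Methods: quantifying contact guidance on ridge/groove substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying contact guidance on ridge/groove substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactguidance)
```

This vignette records the scientific and numerical choices behind the
package: the models, the conventions, why the defaults are what they are,
and what the tests do and do not establish. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` themselves compute.

## The measurement problem

Cells on a substrate patterned with parallel ridges and grooves reorganise
their shape and motion along the pattern. The substrate is described by
three dimensions — groove width $G_w$ and ridge width $R_w$ in µm, groove
depth $G_D$ in nm — and the flat control carries all three equal to zero.
Throughout the package the groove long axis is the **+y** direction;
control data use the same axes purely for bookkeeping. All angles are
serialised in degrees, positions in µm, times in minutes.

Two raw data types feed the analysis:

* **outlines** — manually traced cell boundaries, stored as simple closed
  polygons (µm), with two per-cell exclusion flags: the cell divided during
  the recording, or it straddled the boundary between flat and patterned
  regions. Flagged cells are excluded from all static statistics; the
  exclusion counts are logged, never silently dropped.
* **tracks** — nucleus positions sampled every $dt = 10$ min. Dynamic
  analysis keeps tracks that last strictly more than 360 min (6 h) and
  whose nucleus stays on the pattern (the control is exempt from the
  on-pattern gate). The directional-orientation statistic additionally
  requires at least 600 min (10 h) of track; this second gate is inclusive
  so that standard 10-h recordings qualify. Both gates are configurable.

## Static morphology

**Ellipse fit.** The outline is treated as a filled lamina. Its area,
centroid and second central moments are computed by exact polygon
integrals (Green's theorem edge sums), and the reported ellipse takes its
orientation from the principal axis of the covariance and its aspect ratio
$\alpha = \sqrt{\lambda_1/\lambda_2}$ from the covariance eigenvalues; the
axes are then scaled jointly so the ellipse area equals the polygon area
exactly. This matches the behaviour of the standard image-analysis fit for
filled shapes. Fitting the boundary vertices by least squares was rejected:
the scientific object is the cell body, not the trace, and vertex fitting
weights concave stretches incorrectly. A numerically isotropic covariance
(relative eigenvalue gap below $10^{-12}$) resolves the orientation to 0°
so squares and circles are deterministic. Polygons with area below
$10^{-9}$ µm² are rejected as degenerate rather than skipped.

**Alignment angle.** $\theta$ is the acute angle between the major axis
(period 180°) and the groove axis, folded into $[0°, 90°]$. Histograms use
half-open 2° bins $[lo, hi)$ with the top edge 90° assigned to the last
bin, normalised to fractions; the CDF is their cumulative sum.

**Populations.** $\bar\alpha = \alpha/\alpha_{Cont}$, where
$\alpha_{Cont}$ is the *mean* aspect ratio of included control cells pooled
across the dataset (median available via an argument; the pooled-vs-per-chip
choice is exposed only through which records the caller passes). Elongated
and aligned fractions use inclusive thresholds $\bar\alpha \ge 2$ and
$\theta \le 2°$ — the thresholds are part of the measurement definition,
not tuning knobs.

## Dynamic migration

Per-track metrics follow the standard definitions on the sampled polyline:

* mean speed = total step length / total time; the groove-axis
  decomposition sums $|\Delta x|$ and $|\Delta y|$ separately, so
  $\max(\bar v_x, \bar v_y) \le \bar v \le \bar v_x + \bar v_y$ holds per
  track by the triangle inequality (tested for every simulated track).
* angular displacement $d\theta(t,\delta)$ is the angle between the
  displacements over $[t, t+\delta]$ and $[t+\delta, t+2\delta]$, in
  $[0°, 180°]$. A zero-length displacement leaves the angle undefined;
  such pairs are skipped and counted (imputing 0° would inflate the first
  occurrence bin). $\delta$ must sit on the sampling grid — the data are
  not resampled.
* the directional displacement ratio over a window $\Delta$ is the signed
  groove-axis advance $y(\Delta) - y(0)$ divided by the path length
  $D(0,\Delta)$, the sum of consecutive 10-min step lengths. The numerator
  is signed; because the walk is symmetric under $y \to -y$, cohort means
  of the signed ratio hover near zero, so the cohort curve is also
  available as $|d_y|/D$ (`statistic = "absolute"`), which is the version
  comparable to published positive-valued decay curves. The classical
  directionality ratio $d/D$ uses the straight-line distance instead, and
  $|d_y|/D \le d/D \le 1$ always.
* MSD and the velocity autocorrelation use overlapping windows with
  time-then-ensemble averaging. The VACF default is the dot-product
  estimator normalised at lag 0; a cosine (speed-independent) variant is
  provided because speed fluctuations deflate the dot-product estimator
  relative to the pure heading correlation.

## The synthetic-data generator

The study conditions the generator emulates are: 10-min sampling, 600-min
tracks, cohorts of ~30 cells per condition (the study characterised more
than 20 per condition), mean path speeds of 0.25–0.4 µm/min, and
morphology/migration anisotropy that rises steeply from the flat control
to $G_D = 725$ nm and saturates or weakly reverses at 1000 nm.

**Heading model.** Headings update once per interval by a wrapped-normal
draw about the resultant of two pulls: a persistence pull of concentration
$A_1^{-1}(p)$ toward the current heading (so that at zero axial bias the
expected cosine of the heading change — the lag-one velocity
autocorrelation — equals the `persistence` parameter $p$ exactly), and an
axial pull of concentration `axis_bias` toward the *nearer* of the ±groove
axis. Folding the attraction to the nearer pole makes +y and −y motion
equally likely, reproducing the back-and-forth migration seen on deep
grooves, and leaves the stationary heading distribution axis-symmetric.
At `axis_bias = 0` the stationary distribution is uniform on the circle.
This construction was chosen over a Langevin discretisation of an axial
potential because it has no step-size stability limit at large bias; the
spread of each draw is matched to the resultant concentration through the
von Mises mean-resultant-length function, computed with exponentially
scaled Bessel ratios for stability. Headings are burned in for 20 updates
before positions are recorded. Step lengths are gamma with mean
`base_speed * dt` and configurable spread, so the mean path speed is
calibrated to `base_speed` (tested to within 5% at 500 cells).

**Outlines** are discretised ellipses (64 vertices) with multiplicative
radial noise (default 5%). Orientations come from an axial (period-π)
distribution about the groove axis — alignment is sign-free, so only the
doubled angle is modelled — with concentration 0 giving uniform alignment
angles on $[0°, 90°]$. Aspect ratios are $1 +$ gamma and areas lognormal;
the default mean area of 2400 µm² is a typical patterned-substrate
fibroblast spread area.

**Depth map.** `condition_sim_params()` anchors the generator at the four
depths 0/330/725/1000 nm with, respectively: axial bias 0/1.5/6/5.5, mean
speed 0.39/0.35/0.25/0.29 µm/min, mean aspect 4.81/5.92/8.66/7.64, outline
orientation concentration 0/2/8/7, and mean area 2816.8/2365.3/2115.3/
2259.4 µm². The speed, aspect and area anchors are the study's reported
cohort values; the bias and concentration anchors are package choices that
reproduce the qualitative saturation between 725 and 1000 nm — no
mechanistic depth-to-bias law is claimed, and intermediate depths are
linearly interpolated. A mild lateral modulation,
$1/(1 + 0.08\,(R_w - 2))$, scales the anisotropy parameters down as the
ridge widens, reflecting that ridge width constrains adhesion maturation
more than groove width does.

**What passing tests show.** The generator produces exactly the
distributional structure the analysis assumes: regular sampling, gamma
steps, wrapped-normal headings, elliptical outlines. Real recordings break
these assumptions — tracking jitter, cell–cell contact, pattern defects,
non-elliptical protrusive shapes — so green tests validate the *estimators*
(they recover known ground truth, respect their invariants, and are
calibrated under their nulls), not any biological claim about real cells.

## Statistics

Group comparison is the Kruskal–Wallis rank test (tie-corrected, chi-square
tail) via `stats::kruskal.test`, with an all-values-identical cohort
reported as $H = 0$, $p = 1$ and flagged degenerate instead of 0/0. The
post hoc is Dunn's mean-rank $z$ with the standard tie correction and Šidák
adjustment $1 - (1 - p)^m$ over the $m = k(k-1)/2$ pairs; it is implemented
in the package and checked against the $k = 2$ identity and the Šidák
arithmetic. Box summaries use type-5 quantiles (midpoint interpolation of
the empirical CDF, the convention of the plotting tool the 1.5·IQR outlier
rule comes from); the convention is configurable and recorded in outputs.

The population-fraction regression is unweighted OLS with an intercept,
main effects and all pairwise products; the exact published term set for
this kind of model is not always stated, so the pairwise-product default is
noted prominently in printed output and a three-way product is switchable.
The Case 1 (depths ≤ 725 nm) / Case 2 (≤ 1000 nm) split exists because the
depth response changes direction past 725 nm, which degrades a single
linear fit. Reduced condition grids (a single lateral series) can make the
product design collinear — e.g. with $G_w \in \{0, 2\}$ the $G_D G_w$
column is proportional to $G_D$ — in which case direct calls error and the
pipeline skips that regression with a log entry.

## Numerical and design notes

* Every simulation consumes an explicit integer seed and restores the
  caller's RNG state; identical inputs are bit-identical, and pipeline
  re-runs are byte-identical at the CSV level.
* Histogram bin edges are half-open with the top edge folded into the last
  bin, so boundary values (θ = 90°, dθ = 180°) are never lost.
* Test and acceptance problem sizes — 500-cell isotropy cohorts, 300 cells
  per bias level over the grid {0, 1, 3, 8, 20}, 50 oracle ellipses, 2000
  null replicates for the type-I check — were chosen so that sampling error
  sits well inside each assertion's tolerance at desk scale.
* The ellipse-fit oracle in the test suite is a raster: the polygon is
  pixelated at 0.05 µm/px and discrete moments are compared against the
  exact polygon integrals; the two routes share no code.

## Known limitations

* No segmentation or tracking from images: inputs are already-traced
  polygons and track tables (the upstream steps were manual in the kind of
  study this package serves). ImageJ binary ROI import is not provided;
  outlines exchange as CSV.
* The generator has no groove-wall collision mechanics, no cell–cell
  interactions and no photorealistic imagery; depth enters only through
  the parameter map above.
* Statistics are limited to the methods listed: no mixed-effects models,
  no multiple-testing procedures beyond Dunn–Šidák, no weighted
  regression (per-condition cell counts are reported so a caller can
  weight externally if desired).
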