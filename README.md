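# contactguidance

Quantitative analysis of **contact guidance**: how cells change shape and
migrate in response to anisotropic substrate topography. The package targets
experiments in which fibroblasts are cultured on periodic ridge/groove
patterns described by three dimensions — groove width `G_w` and ridge width
`R_w` (micrometres) and groove depth `G_D` (nanometres) — with a flat
substrate as control, and where the raw observations are manually traced
cell outlines and nucleus tracks sampled every 10 minutes. Conditions are
named by the `G<G_w>R<R_w>` grammar (e.g. `G2R8`, optionally `G2R8D330` with
the depth), with three lateral series: `G2RN` (fixed `G_w = 2` µm), `GNR2`
(fixed `R_w = 2` µm) and `GNRN` (`G_w = R_w`).

It is written for cell-biology and biomedical-engineering groups who want a
tested, reproducible version of the usual ad-hoc image-analysis spreadsheet
chain: from outline polygons and track tables to publication statistics.

## What it computes

**Static morphology** (per cell outline, a polygon in µm):

- spread area `A_cell` (shoelace formula);
- a *moment-matched ellipse fit*: the ellipse sharing the polygonal
  region's area, centroid and second-moment structure, giving the aspect
  ratio `α = major/minor` and the major-axis direction;
- the alignment angle `θ ∈ [0°, 90°]` between the major axis and the groove
  direction (+y by convention);
- the normalised aspect ratio `ᾱ = α / α_Cont` (control-cohort mean), and
  the population fractions `P_ᾱ≥2` (elongated) and `P_θ≤2°` (aligned),
  with 2°-bin alignment histograms and CDFs.

**Dynamic migration** (per nucleus track on a regular 10-min grid):

- directional orientation: the folded angle between the net start-to-end
  displacement and the groove axis;
- angular displacement `dθ(t, δ) = cos⁻¹(v⃗_t·v⃗_{t+δ} / |v⃗_t||v⃗_{t+δ}|)`
  between consecutive displacement vectors, binned at 15° for
  δ = 10/50/100/200 min;
- mean speed `v̄` and its decomposition `v̄_x`, `v̄_y` perpendicular and
  parallel to the grooves;
- the directional displacement ratio
  `d_y(0,Δ)/D(0,Δ) = (y(Δ) − y(0)) / Σ_k |step_k|` over windows
  Δ = 10–600 min, the classical directionality ratio `d/D`, MSD and
  velocity autocorrelation.

**Statistics**: Kruskal–Wallis across condition groups with a Dunn–Šidák
post hoc, box summaries with the `q3 + 1.5·IQR` outlier rule, and multiple
linear regression of population fractions on `G_D`, `R_w`, `G_w` and their
pairwise products (control rows enter with all predictors zero, so the
intercept is the control fraction). Two depth ranges are fitted: Case 1
(0–725 nm, where the response is monotone in depth) and Case 2 (0–1000 nm).

**Mechanics**: the filopodia bending-angle model
`θ_f = sin⁻¹(G_D / l_f)` — the angle a ridge-anchored filopodium of length
`l_f` makes with the groove bottom — which rationalises why deeper grooves
suppress lateral protrusions.

**Synthetic data**: a seeded generator producing nucleus tracks from an
anisotropic persistent random walk (wrapped-normal heading updates with
mean reversion toward the nearer of ±groove axis) and cell outlines as
noisy discretised ellipses with axial orientation distributions. It is the
ground-truth source for all parameter-recovery tests and for the end-to-end
pipeline.

## Worked example

```r
library(contactguidance)

parse_condition_label("G2R2D725")
#> <substrate_condition> G2R2D725: G_w = 2 um, R_w = 2 um, G_D = 725 nm

# a 30 x 6 um rectangle: aspect ratio 5, major axis along +x,
# i.e. perpendicular to the grooves
f <- fit_ellipse(cbind(x_um = c(0, 30, 30, 0), y_um = c(0, 0, 6, 6)))
f
#> <ellipse_fit> area 180.00 um^2, aspect 5.000, orientation 0.00 deg
alignment_angle(f)
#> [1] 90

# full synthetic pipeline at the study grid (3 series x 3 depths + control)
cfg <- pipeline_config("cg_run", depths_nm = c(330, 725, 1000),
                       n_cells = 30, seed = 1)
res <- run_pipeline(cfg)
res$fractions_depth
#> # A tibble: 4 x 6
#>   groove_depth_nm n_cells p_elongated p_aligned alpha_mean theta_mean
#>   <chr>             <int>       <dbl>     <dbl>      <dbl>      <dbl>
#> 1 0                    28        7.14      3.57       5.11      42.4
#> 2 330                 403        2.23      5.96       5.20      21.3
#> 3 725                 407       11.3      13.3        7.51       9.49
#> 4 1000                410        5.12     12.2        6.52       9.95
res$kw_theta$H
#> [1] 191.1742
```

The depth table reads as a contact-guidance dose response: cells on the
flat control have a mean alignment angle near 45° (no preferred direction),
while deepening the grooves to 725 nm concentrates the cohort along the
groove axis (mean θ ≈ 9.5°, more elongated and aligned cells), with
saturation and a slight reversal at 1000 nm. The Kruskal–Wallis H of ~191
across the four depth groups says the alignment distributions differ far
beyond chance.

```r
bending_angle_table(c(330, 725, 1000), 2)
#> # A tibble: 3 x 4
#>   groove_depth_nm filopodia_length_um theta_f_deg defined
#> 1             330                   2        9.50 TRUE
#> 2             725                   2       21.3  TRUE
#> 3            1000                   2       30    TRUE
```

A 2-µm filopodium reaching a 1000-nm groove bottom bends 30° — large
enough to load its adhesion normally and destabilise lateral protrusions.

All per-cell tables, histograms, ratio curves, statistics and the run log
are also written as CSVs under the configured output directory.

## Package layout

- `R/conditions.R` — substrate-condition grammar and grids
- `R/simulate.R`, `R/circular.R` — synthetic-data generator
- `R/morphology.R` — outline geometry and static metrics
- `R/migration.R` — track metrics and cohort curves
- `R/statistics.R` — group tests, box summaries, regression
- `R/mechanics.R` — filopodia bending model
- `R/io.R`, `R/pipeline.R` — CSV exchange and the end-to-end pipeline
- `vignettes/contact-guidance-analysis.Rmd` — methods notes: model
  assumptions, conventions, parameter choices and limitations
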