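---
title: "Methods: proximal canopy sensing, from side-view pixels to vigor maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximal canopy sensing, from side-view pixels to vigor maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitisense)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, the numerical choices made
where the design was genuinely open, and what a green test does — and does
not — establish.

## 1. The measurement problem

Hedgerow-trained vineyards present a tall, narrow vegetation wall to a
sensor driven along the inter-row. A tractor-front unit photographs the two
flanking walls from below with plain RGB imagers while logging microclimate
and GPS at 3 Hz. The quantity of interest is a per-location **Canopy Index
(CI)**: the fraction of the frame occupied by vegetation, scaled to
0–1000. CI is not a biomass measurement and makes no radiometric claim (no
NDVI, no reflectance model); it is a geometric cover fraction, which is
precisely why it can be calibrated against point-quadrat structure metrics
that are themselves geometric.

Because the sensor looks upward, the image background is sky only — the one
structural assumption the whole segmentation rests on.

## 2. Vegetation segmentation

`segment_vegetation()` chains three steps.

**Features.** Each pixel contributes six features: normalized R, G, B plus
Hue, Saturation, Lightness. Hue is circular; it is mapped linearly to
[0, 1] via h/360 before use, with achromatic pixels assigned the sentinel
H = 0. This is safe here because foliage hues (60–150°) and sky hues
(200–240°) do not straddle the wrap point; a frame dominated by reds would
need a different embedding.

**Projection.** The six feature planes are standardized to zero mean, unit
variance *within the image* and combined linearly into one scalar plane.
Fixed user weights are accepted; the default recomputes the weight vector
per image as the leading principal axis of the standardized feature matrix
(a 6 × 6 eigen problem, deterministic). Per-image standardization is what
buys illumination insensitivity: a global brightness change rescales
features that are then re-standardized away. The axis sign is oriented so
the lower-Lightness class (foliage, not sky) scores higher; an exact
Lightness tie falls back to mean hue distance from green (120°).

**Two-class Jenks break.** The scalar values are split at the contiguous
split of the sorted sample minimizing the total within-class sum of squared
deviations, over all n−1 splits, ties broken toward the smaller low class.
This is the two-class special case of Jenks natural breaks and is computed
exactly in O(n log n) with prefix sums; the test suite holds it equal to an
exhaustive-split oracle on a thousand random instances.

**Class orientation and degenerate frames.** The class with lower mean
Lightness is VEGETATION. A genuinely single-class frame (all sky, or a wall
so dense no sky shows) still carries color noise, and a Jenks split of
unimodal noise is always "successful", so single-class frames must be
*detected*, not assumed away. We use the goodness-of-variance fit
GVF = 1 − SSD_within/SSD_total of the break: splitting a continuous
unimodal sample cannot exceed GVF ≈ 0.75 (the uniform-distribution
ceiling), whereas true vegetation/sky mixtures measure ≥ 0.9 across the
synthetic regimes. Frames below the `min_separation = 0.8` threshold are
routed to the single-class rule: all-OTHER when the frame's mean Lightness
is at or above `sky_lightness_floor = 0.75`, else all-VEGETATION. The
threshold sits in the gap between the two regimes and was chosen from the
structural ceiling argument, not fitted.

**Scale.** `CI = 1000 × n_vegetation / n_total`. The source material prints
a ×100 multiplier in the defining formula while stating and reporting the
index on a 0–1000 scale throughout; this package adopts ×1000, since every
downstream quantity (sector values, calibration lines, reported maxima
around 900) lives on that scale.

## 3. Sector geometry

`build_sector_layout()` converts the mounting geometry — row spacing
(250 cm in the reference setup; the sensor stands off half of it), wire
height (70 cm), sensor height (50 cm), tilt (41°), canopy top plus a small
field-of-view margin (default 10 cm) — into 15 CI and 16 ST sectors.

The design choice here is **equal-angle subdivision**: the field of view
between the wire sight-line and the canopy-top sight-line is divided into
15 equal angles, and boundary heights follow h = sensor + d·tan(θ). This
reproduces the one property the source states — sector heights grow from
base to top, by convexity of the tangent — and anchors CI sector 1 exactly
at the wire. The 16 ST sectors reuse the same angular step, aligned so ST 6
starts at the wire: ST 6–16 coincide with CI 1–11 (which is what makes the
five macro-sectors — Lower ST 6–7/CI 1–2 through Upper ST 15–16/CI 10–11 —
geometrically meaningful), while ST 1–5 extend the slicing below the wire
and are carried as data only.

Interpolation (`interpolate_ci()`) assumes a linear CI variation between
adjacent sectors. The nodes are sector **mid-heights**; the source does not
say mid vs boundary, and mid-heights are the symmetric choice. No
extrapolation beyond the end sectors: out-of-range requests error (or clamp
behind an explicit flag), and repositioning onto the 18 point-quadrat
levels (−15 … +155 cm from the wire) flags unreachable levels as missing
rather than erroring, since early-season canopies simply do not reach the
top levels.

## 4. Derived vertical-profile indices

COG (CI-weighted mean sector index) and MOI (second moment about COG) are
plain weighted sums over sectors 1–15; both error on an all-zero profile,
where the center is undefined. COG is scale-invariant, MOI scales linearly
with the profile — both properties are tested.

**Background-corrected canopy temperature.** A thermal sector reading is
the mixture ST = T_V·F_V + T_B·(1 − F_V). Two inconsistent definitions of
the "CI-normalized ST" coexist in the source (a plain ST/CI ratio, and the
mixture-inversion scheme developed in detail); both are implemented and the
inversion is the default, per macro-sector:
T_V = (ST̄ − T_B(1 − F_V))/F_V with ST̄ the mean of the macro-sector's ST
sectors and F_V the mean of its CI sectors / 1000 (the unweighted mean is
an artifact choice, symmetric with ST̄). T_B defaults to a fixed 4 °C — "a
few degrees above zero" is all the source commits to — with
`estimate_background()` offering the mean of sky-dominated ST sectors 1–5
as an alternative. Bare-sky macro-sectors (F_V = 0) are flagged missing,
not errors. The inversion round-trips the forward mixture to machine
precision, and corrected temperatures exceed raw readings whenever the
background is colder — the bias the correction exists to remove.

## 5. Point-quadrat metrics and porosity

Scoring follows the standard point-quadrat conventions: **LLN** = leaf
contacts per insertion (clusters excluded from layer counts); **%CG** =
insertions with *no contact of any type*; **%IL** = leaf contacts that are
neither the first nor the last leaf of their insertion, as a percentage of
all leaf contacts — cluster contacts do not shield leaves. With no leaf
contacts at all, %IL is defined as 0 and flagged (`il_defined = FALSE`)
rather than NA, so aggregation stays numeric. Canopy porosity is
CP = 1 − mean(below)/mean(above); negative values (sensor noise pushing
below-canopy readings past the reference) clamp to 0 with a warning.

## 6. Calibration

Linear fits are ordinary least squares with R² = 1 − SS_res/SS_tot; the
exponential model y = a·e^(bx) is fitted by least squares on log y — a
deterministic choice over iterative nonlinear fitting, whose procedure the
source never states — with R² reported on the *original* scale, so the two
model families are comparable. `calibration_report()` fits per scope
(vine, date, sector) and supports the pooled presentation in which each
point is one measuring date's mean over vines. Published coefficient pairs
can be wrapped with `linear_calibration()` and evaluated with `predict()`.

## 7. Survey logs, filtering, maps

The CSV schema (timestamp, WGS84 position, side, vine id, RH, AT,
ultrasonic distance, satellite count, 15 + 16 sector values), the 2 m
default raster cell, and IDW with power 2 are artifact decisions; the
source names none of them. Numbers are written at 17 significant digits so
a write/read round trip is bit-exact.

De-trending of RH/AT is a 5-point moving median followed by removal of the
OLS linear time trend, re-centered on the survey mean: a pure ramp becomes
its mean, a constant passes through, and the refitted residual trend is
zero.

"Smart filtering" of extraneous side readings is undisclosed in the source
beyond its purpose; here it is (a) a boundary-polygon test and (b) a robust
running rule — drop a side whose vine-level CI deviates from the running
9-record median of its side by more than 4 running MADs. A dropped side
leaves its partner usable through `average_sides()`' single-side path.
Filtering never invents records.

IDW takes the exact sample value at coincident cells and leaves cells with
no in-radius neighbor as no-data; output is bounded by the data range. The
map catalog enumerates 45 products (4 whole-wall scalars, 15 + 16 sector
maps, COG, MOI, 5 macro-sector temperatures, satellite count, GPS track).
The advertised "3D Canopy Index" (a CI × ultrasonic combination) has no
published formula and deliberately raises a not-implemented error.

## 8. The synthetic world

One occupancy model drives everything. A canopy is a vertical leaf-density
profile λ(h): a scaled beta shape over the wall span (wire − 15 cm up to
the canopy top) whose mode sits in a configurable basal band, default
15–45 cm above the wire — where trellised vines hold their fruiting-zone
foliage — scaled so the peak equals the `vigor` parameter. A smooth
mean-one lognormal Fourier field g(x) (amplitude `patchiness = 0.25`) adds
horizontal structure.

* **Images:** a pixel at height h is vegetation with probability
  1 − e^(−λ(h)g(x)) — the chance a line of sight meets at least one leaf
  under Poisson foliage. Vegetation colors: H ~ N(110°, 12°),
  S ~ U(0.45, 0.75), L ~ U(0.18, 0.38); three sky models (clear blue,
  overcast, vertical gradient); everything scaled by an illumination factor
  k ∈ [0.3, 1.8].
* **Point quadrat:** leaf contacts per insertion ~ Poisson(λ(h)g(x)), so
  E[LLN] = λ and E[%CG] = 100·e^(−λ) analytically; clusters are an
  independent Poisson stream confined to the 5–35 cm fruiting band.
* **Survey:** per-vine stops on a serpentine row layout emit left/right
  sector profiles (1000 × mean occupancy over each sector's heights plus
  N(0, 12) sensor noise) and ST from the forward thermal mixture plus
  N(0, 0.3); RH/AT carry known linear drifts (0.5 %/min, 0.05 °C/min) so
  de-trending can be checked against truth.

Defaults state a moderately vigorous season: per-vine final vigor
U(0.6, 3.2) (peak LLN up to ~3), growth multipliers (0.35, 0.6, 0.9, 1, 1)
and canopy heights (160, 175, 220, 190, 190 cm) over five dates — rapid
early growth, closure, then a trim. These were chosen once as a realistic
season and are not tuned to test outcomes.

Because frames span the same wall heights the point-quadrat probes,
CI/1000 ≈ mean occupancy and %CG/100 ≈ mean e^(−λ) are tied by
construction of the *physics*, not of the answer: the calibration structure
(negative CI–%CG slope, positive CI–LLN slope, R² > 0.9 per vine) emerges
mechanistically. What a green end-to-end test establishes is that the chain
recovers a known coupled world; it says nothing about sensor optics, motion
blur, leaf angle distributions, mixed backgrounds (no sky-only guarantee),
or real microclimate dynamics — none of which the generator emulates.

## 9. Numerical choices and degenerate inputs, collected

* Hue wrap: linear h/360 embedding, sentinel 0 for achromatic pixels.
* Constant feature columns standardize to 0 (they carry no information);
  an entirely constant image errors in auto mode (undefined axis) and is
  resolved by the sky-lightness floor in `segment_vegetation()`.
* Jenks ties break toward the smaller low class; class membership is
  assigned on the sorted order, so duplicated boundary values partition
  deterministically.
* Separation threshold GVF 0.8; sky-lightness floor L = 0.75 (calibrated
  frames at k = 1; heavily darkened single-class frames can misclassify —
  a documented limit, not a tested regime).
* Interpolation nodes at sector mid-heights; no silent extrapolation.
* %IL with zero leaf contacts: 0, flagged.
* Porosity clamps negative values to 0 with a warning.
* IDW coincidence tolerance 1 nm; equidistant coincident samples average.
* All generator randomness flows through one integer seed per object, with
  private RNG state (the caller's `.Random.seed` is never touched).

## 10. Known limitations

* The projection weights of the original instrument are unpublished; the
  principal-axis default is a reconstruction that satisfies the stated
  goals (one dimension, maximal variance, illumination robustness) but is
  not claimed to match the commercial firmware.
* The angular extent and anchoring mechanism of the physical field of view
  are unpublished; both are configuration parameters here.
* Field R² values from the original campaign are not reproducible (the
  underlying vineyard dataset is not deposited); the package reproduces
  published calibration *lines* and recovers calibration structure from
  the synthetic world instead.
* The exponential calibration weighs relative errors (log-space fitting);
  for data with additive noise near zero it will differ from a nonlinear
  least-squares fit.
* Geographic handling is a local equirectangular plane around the survey
  centroid — adequate for plot-scale maps, not for large or high-latitude
  extents.
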