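---
title: "Mapping plantation landscapes and accounting for their area: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping plantation landscapes and accounting for their area: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmcover)
```

## The problem

Tropical plantation concessions are typically planted only in part; the
unplanted remainder — often standing forest — can legally be cleared at
any time and so concentrates both deforestation risk and conservation
opportunity. Quantifying *how much* of a concession estate is actually
planted with the target crop, how much of the crop sits outside
concession boundaries, and how much forest carbon is at stake, requires
three things: a reliable land-cover map, area estimates that correct
for the map's classification errors, and zonal bookkeeping against the
concession polygons. `palmcover` implements that workflow end to end
for a six-class landscape — oil palm, rubber, other trees, shrub, bare
land, water — and couples it to a synthetic-scene generator with known
ground truth so that every stage, including the uncertainty statements,
is testable without downloading a single satellite image.

## From image stacks to a feature stack

**Cloud screening and compositing.** Each optical date carries ten
reflectance bands (B2–B8A, B11, B12, on a 0–1 scale) and a quality
mask. A pixel is flagged cloudy if the delivered mask says so, if it is
simultaneously bright in blue (B2 > 0.25) and short-wave infrared
(B11 > 0.20), or if a cirrus band, when present, exceeds 0.01. Only the
*shape* of this rule is fixed (union of mask and spectral tests); the
thresholds are configuration. The multi-date stack is then reduced per
pixel and band to the mean of the clear observations falling inside the
closed 40–60 percentile window — a robust centre-of-distribution mean
that rejects residual bright (cloud) and dark (shadow) outliers.
Percentiles use the common linear-interpolation convention; because
interpolated bounds can exclude every observation (e.g. two distinct
values), the implementation falls back to the single observation
nearest the median rather than leaving a hole. Pixels with fewer than
`min_obs = 3` clear observations are treated as unobserved: a one- or
two-scene value is too cloud-sensitive to trust.

**Features.** The classifier sees 17 predictors on a common 20 m
analysis grid: the ten composite bands; NDVI `(B8 − B4)/(B8 + B4)`;
NDVI texture as the population standard deviation in a 5 × 5 moving
window, computed at the native 10 m resolution before aggregation so
fine texture is preserved; the temporal mean and population standard
deviation of the VV and VH radar backscatter (dB); and terrain slope in
degrees from a Horn 3 × 3 gradient on the 30 m DEM. Resampling to 20 m
uses the block mean for nested grids and bilinear interpolation for the
non-nested slope layer; slope is computed at the DEM's native
resolution first, then resampled. Window statistics shrink at image
edges instead of inventing padded values, and a pixel missing in any
optical band is missing in every layer. The 20 m grid matters because
the narrow red-edge bands (B5–B7, B8A) carry much of the signal that
separates visually similar tree crops.

## Classification

A random forest with 100 trees and 4 candidate predictors per split
(`round(sqrt(17))`) is trained on reference pixels extracted from
labelled polygons: one sample per 20 m pixel whose centre falls inside
a polygon. The reference set is split 50/50 per class — stratified by
class, with a seeded shuffle and a floor rule for odd strata — into
training and testing halves; polygon identity is retained so a
polygon-level split can be configured instead. The predicted map is
smoothed with a 3 × 3 majority (modal) filter; ties retain the centre
pixel's class, which is deterministic and conservative, and missing
pixels neither vote nor change. We read "majority of the connected
pixels" as this standard mode filter; a connected-component sieve with
a minimum mapping unit would be a stricter variant and is deliberately
not implemented.

## Error-adjusted area estimation

Pixel counting on a classified map is biased by misclassification, so
class areas are estimated with the standard stratified estimator that
combines the mapped class proportions with the reference sample. With
mapped-area weights $W_i = N_i / \sum_i N_i$ and confusion counts
$n_{ij}$ (rows $i$ = mapped class, columns $j$ = reference class),

$$\hat p_{\cdot j} = \sum_i W_i \frac{n_{ij}}{n_{i\cdot}}, \qquad
\hat A_j = \hat p_{\cdot j} \, A_\mathrm{tot},$$

$$\mathrm{SE}(\hat p_{\cdot j}) = \sqrt{\sum_i W_i^2\,
\frac{(n_{ij}/n_{i\cdot})(1 - n_{ij}/n_{i\cdot})}{n_{i\cdot} - 1}},$$

with 95% intervals $\hat A_j \pm 1.96\,\mathrm{SE}\,A_\mathrm{tot}$
(the level is fixed by convention; the multiplier 1.96 is the package
default and configurable). The estimated proportions sum to one and the
areas to the total mapped area exactly, for any confusion matrix. A
mapped stratum with one or zero test samples is a hard error — its
variance is undefined — rather than a silent drop. Matrix orientation
(rows = map, columns = reference) is fixed and serialised with explicit
axis labels. Both the sample-count overall accuracy and the
area-weighted overall accuracy $\sum_i W_i\, n_{ii}/n_{i\cdot}$ are
reported, since a bare "overall accuracy" does not say which is meant.
`coverage_simulation()` checks the machinery itself: repeated stratified
sampling from a known landscape and confusion model must produce
intervals that cover the true areas about 95% of the time, and does
(the test suite requires per-class coverage in [0.92, 0.975] at 1,000
replicates).

## Zonal accounting and the carbon calculator

A pixel belongs to a zone iff its centre lies inside the zone polygon —
the same pixel-count basis as the estimator, and exactly testable
against a brute-force scan. Zones of different kinds (concession,
district, park) may overlap and each receives the pixel; overlapping
zones of the *same* kind are unioned first so no hectare is counted
twice within a kind. Concession shares divide each class's
within-concession area by the six-class concession total. The
emissions calculator converts unplanted forest area to
CO~2~-equivalent mass as
`area × carbon density × 44/12 × 10⁻⁶` Tg; the molar-mass factor 44/12
is exact by default but configurable, because published figures round
it differently, and the factor used is always reported alongside the
result. Report rounding follows the conventions of published tables:
percentages to the nearest integer, areas to the nearest hectare or
thousand hectares.

## The synthetic landscape: what it emulates, and what it does not

`simulate_scene()` defines the package's standard study conditions:

* **Landscape** — 256 × 256 pixels at 10 m (≈ 655 ha). Class patches
  come from thresholding a Gaussian-smoothed random field (smoothing
  radius 32 px) at the empirical quantiles of the cumulative class
  weights (0.12, 0.15, 0.40, 0.18, 0.09, 0.06 for oil palm, rubber,
  other trees, shrub, bare, water) — contiguous, plantation-block-like
  patches with frequencies that match the weights almost exactly.
  Patch boundaries are snapped to the 20 m analysis grid, so every
  analysis cell has a single true class. This makes ground truth and
  reference purity exact at the analysis resolution and is the one
  place the generator is deliberately *cleaner* than reality: mixed
  boundary pixels are not modelled, so the pipeline's accuracy figures
  say nothing about mixed-pixel effects in real imagery.
* **Optical series** — 8 dates; per-date Gaussian band noise
  (SD 0.012); contiguous cloud blobs covering 30% of each date, filled
  with bright cloud reflectance and flagged in the QA mask; reflectance
  truncated at zero.
* **Within-class variability** — three smooth condition fields, stable
  across dates (correlation length ≈ 12 m), modulate every pixel:
  a brightness field (±6% at 1σ), a canopy-vigour field that raises the
  NIR/red-edge plateau and lowers red/SWIR (±12%), and a
  stand-condition drift that moves each pixel part of the way toward
  its most confusable partner class (oil palm ↔ rubber, other trees →
  rubber, shrub → other trees, bare → shrub, water → bare). Because
  these fields persist across dates, compositing cannot average them
  away — they are what makes held-out reference pixels genuinely
  misclassifiable. The per-class drift amplitudes (0.45, 0.45, 0.40,
  0.40, 0.60, 0.70) were chosen so held-out accuracy lands in the
  80–97% per-class band reported for real plantation mapping in this
  region, with the tree crops hardest; they are fixed study conditions,
  not tuning knobs.
* **Radar series** — 12 dates of VV/VH backscatter with multiplicative
  gamma speckle (5 looks) applied in linear power and log-standardised,
  so the dB-domain mean and SD equal the signature parameters exactly
  (raw multi-look speckle would bias the dB mean by ≈ −0.45 dB), plus a
  shared persistent texture field (0.8 dB) and the same condition
  drift.
* **Reference data** — single-cell (20 m) reference plots allocated to
  classes proportionally to their weights (1,200 plots, floor 48 per
  class), placed on pure cells with at least one free cell between
  plots. Proportional allocation gives a uniform per-cell inclusion
  rate, so the reference sample behaves like a stratified probability
  sample of the landscape — the assumption the estimator's variance
  formula actually carries. Equal-per-class allocation, or large
  clustered polygons confined to patch interiors, both break
  within-stratum representativeness and were rejected for the default
  conditions (the generator still places multi-cell polygons on
  request).
* **Ancillary layers** — a DEM as a sum of low-frequency cosine
  surfaces on its own 30 m grid (flat option for analytic slope
  checks), four random concession rectangles (overlaps allowed), two
  district rectangles partitioning the extent, and one park.

Default signatures make oil palm and rubber close in the visible bands
and separable mainly through the red-edge region and radar — the
motivation for carrying red-edge bands at 20 m in the first place.

What passing tests on this generator do **not** show: robustness to
mixed pixels and boundary digitising error, to reference labels from a
different year than the imagery, to orbit-geometry artefacts in the
radar, or to atmospheric residuals beyond bright cloud blobs. Those are
properties of real campaigns the synthetic module intentionally leaves
out.

## Numerical choices and degenerate inputs

Percentile interpolation is the "linear" (type 7) convention; the
retention interval is closed and has a nearest-to-median fallback.
Temporal and windowed standard deviations divide by *n* (population
form), so a two-date series gives SD `|a − b|/2` and one date gives 0.
The moving-window SD centres the data before accumulating sums of
squares, making constant inputs return exactly zero. Majority-filter
ties keep the centre class; modal block aggregation breaks ties toward
the smaller class code. Degenerate inputs fail loudly and early:
non-normalisable class weights, empty stacks, inverted percentile
windows, even windows, single-class training sets, strata with fewer
than two test samples, and reference-polygon requests the landscape
cannot host (the error names the class). Scene generation, splitting
and model fitting use separate, logged seeds; identical configuration
reproduces every numeric output bit for bit.

## Problem sizes

The default study conditions (256 × 256 scene, 8 + 12 dates, 1,200
plots) run the full pipeline in well under a minute on one CPU; the
test suite uses a 96-pixel variant of the same conditions for its
fast end-to-end checks and the full conditions for the recovery check;
Monte-Carlo coverage uses 1,000 replicates of 500 test samples. These
sizes were chosen so the whole validation cycle stays interactive while
keeping every per-class sample count large enough for the estimator's
variance formula to be meaningful.

## Known limitations

Test pixels drawn from polygons violate the independence the variance
formula assumes when polygons are large and clustered; the default
conditions sidestep this with spread single-cell plots, but the
polygon-based workflow mirrors common practice and inherits its
optimism. Sampling is stratified by *reference* class at selection time
while the estimator conditions on *mapped* strata; with a uniform
inclusion rate this is benign, but it is an approximation. The "within
concession" accounting is computed by pixel counting on the mapped
zones (a `stratified` re-estimation mode restricted to concession
pixels would be the natural extension). Belowground and soil carbon are
excluded from the emissions figure by construction, which therefore
understates the true emission risk.
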