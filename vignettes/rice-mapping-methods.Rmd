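---
title: "Phenology-driven multi-season rice mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-driven multi-season rice mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricesar)
```

## The problem

Multi-season paddy rice — early, middle and late crops, with early and late
often double-cropped on the same fields — is hard to map in subtropical
rainy regions. Optical imagery is lost to cloud during exactly the growth
stages that identify rice; supervised classifiers need training samples
that are expensive to collect and do not transfer across regions, because
sowing dates (and hence spectral trajectories) shift; and dense SAR time
series are redundant, with most acquisitions contributing nothing to class
separability.

`ricesar` implements a pipeline that addresses these problems by
*compressing* the time series into a few physically meaningful bands before
an unsupervised classifier ever sees the data, and by finishing with a
design-based area adjustment so that reported areas carry standard errors
and confidence intervals rather than being read off a map with unknown
bias.

## The backscatter phenology model

The core signal is the temporal trajectory of C-band VH backscatter over a
rice field. During transplanting the field is flooded and the seedlings are
small; the smooth water surface reflects the radar pulse away, so the
backscattering coefficient drops to a trough. As the canopy closes, volume
scattering from the uneven crop surface dominates and backscatter rises to
a peak, before declining again toward maturity. Water bodies stay flat near
−24 dB all season and forest/built-up land stays flat near −10 dB — neither
fluctuates.

Per rice type, two calendar windows capture this: an **early growth
window** (trough) and a **middle growth window** (peak). The *enhanced
image* for a rice type is the 3-band stack

- B1 = pixelwise **minimum** dB over the early growth window,
- B2 = pixelwise **maximum** dB over the middle growth window,
- B3 = B2 − B1 (the **difference** band).

Rice pixels have a large B3 (trough-to-peak swing); everything with a flat
trajectory has B3 near zero, whatever its absolute level. B3 is invariant
to a constant calibration offset of the whole series, which is why the
enhancement is robust to the exact radiometric level. Double-cropped
early-late fields trough twice and therefore show a large B3 in *both* the
early-rice and the late-rice enhanced images.

Window bounds are inclusive at both ends. The shipped defaults
(`default_calendar()`) use the published early-rice windows for 2016
(31 March – 6 May; 18 May – 17 July). The middle- and late-rice windows
were not published; the defaults (middle: 5 May – 15 June and 25 June –
5 August; late: 25 June – 5 August and 15 August – 25 September) are
stand-ins derived from the regional crop calendar and **should be
overridden** with locally valid dates via `pheno_calendar()` or the
`calendar:` section of a pipeline config.

## The cropland image

Rice must grow on cropland, and cropland has a seasonal NDVI signature that
evergreen forest does not: green in the growing season, bare after harvest
in winter. From per-date NDVI grids (`ndvi()`, the usual
(ρ~nir~ − ρ~red~)/(ρ~nir~ + ρ~red~) ratio, clipped to [−1, 1], undefined
where the band sum is zero) the *cropland image* stacks the growing-season
maximum, the winter minimum, and their difference. Cropland shows a large
difference; forest a small positive one; water is negative in both seasons.
Unlike the SAR product, the difference band here may legitimately be
negative (growing max pairs with winter min), and it is deliberately not
clamped — the classifier, not a threshold, handles such pixels. Water
exclusion does not rely on this product at all; the fusion step handles it
first.

## Unsupervised classification

Each 3-band product is clustered by K-Means (Lloyd's algorithm) on the
valid-pixel feature vectors, with **10 classes and 20 iterations** as the
workflow defaults. The implementation makes the reproducibility contract
explicit where generic library routines leave it unspecified:

- k-means++ seeding driven by an explicit integer seed — identical seed,
  identical labels;
- points equidistant to several centroids go to the lowest centroid index;
- a cluster that empties is re-seeded from the point farthest from its
  centroid;
- the within-cluster sum of squares is recorded per iteration
  (`$inertia_trace`) and is non-increasing, which the test suite asserts.

Clusters are then merged into binary thematic layers
(`merge_clusters()`) using a cluster-to-class mapping. Operationally that
mapping comes from survey knowledge; for unattended runs
`auto_assign_clusters()` provides a documented heuristic: in a
rice-enhanced product, clusters whose centroid difference band is above the
across-centroid midpoint *and* whose minimum band is below the midpoint are
rice (the trough-and-swing signature); in a cropland image, high-difference
clusters are cropland and high-maximum/low-difference clusters are forest.
Degenerate inputs (a single cluster, no contrast in the difference band)
map everything to "other". The heuristic is a default, not a claim —
override it with the `mappings:` config section whenever survey data exist.

## Priority decision-tree fusion

Six binary layers (water, forest, cropland, early/middle/late rice) are
fused per pixel by first-match-wins rules:

1. water → **water**
2. else forest → **forest**
3. else cropland AND middle rice → **middle rice**
4. else cropland AND early rice → **early rice**
5. else → **other**

(and analogously water → forest → cropland AND late → other for the late
map). Two choices matter. First, the *cropland gate*: a rice label is only
possible where the cropland layer agrees, which removes rice false alarms
outside agriculture. Second, *middle before early*: the per-season
classifications are independent, and middle rice resembles early rice
around transplanting, so some middle rice leaks into the early-rice layer —
but not the reverse. Testing middle first resolves every such conflict in
middle's favor. The order is hard-coded; it is part of the method, not a
tuning knob. Pixels nodata in any input layer are nodata in the output
(conservative). Double-cropping area is the area of pixels early on the
early/middle map and late on the late map.

## Design-based area adjustment

Mapped areas are biased by classification error; the assessment module
implements the standard stratified (error-matrix) adjustment. With map
categories as rows/strata `i` and reference categories as columns `j`, the
sample counts `n_ij` with row totals `n_i·`, mapped areas `A_m,i` and total
area `A_tot` give

- area proportions `p_ij = (A_m,i / A_tot) · (n_ij / n_i·)`,
- adjusted areas `A_a,j = A_tot · p_·j`,
- `S(p_·j) = sqrt( Σ_i (A_m,i/A_tot)² · (n_ij/n_i·)(1 − n_ij/n_i·) /
  (n_i· − 1) )`,
- 95% interval `A_a,j ± 1.96 · A_tot · S(p_·j)`,
- user's accuracy `p_ii/p_i·`, producer's accuracy `p_jj/p_·j`, overall
  accuracy `Σ p_jj`.

Kappa is computed on the **raw sample counts** (as classification-accuracy
reports conventionally do), not on area-weighted proportions; the two
conventions differ and the choice is deliberate. Undefined accuracies
(empty category) are reported as `NA`, never silently zero. Areas are km²
throughout (pixel area = pixel_size² · 10⁻⁶); reports round km² and
percentages to 2 decimals and proportions/SEs to 4.

Two validity notes. The estimator is design-unbiased under stratified
random sampling within map strata, which the Monte-Carlo harness
(`simulate_area_assessments()`) confirms. The 1.96-normal interval,
however, is an approximation: its coverage is nominal only when every
contributing confusion cell has a non-trivial expected count. At 100
samples per stratum with ~1–2% confusion rates the rare cells hold 1–2
counts and the interval undercovers a rare category (~90% observed over
4000 replicates); at 2500 samples per stratum — the scale of a
quadrat-based reference dataset of ~10,000 pixels — coverage is nominal
(93–96%). The coverage tests therefore run at 2500 samples per stratum,
which is a validity condition of the Wald-type interval, not a tolerance
choice.

## The synthetic scene generator

`generate_scene()` exists so every stage is testable without satellite
downloads. It emulates the study conditions: a 12-day SAR cadence from
31 March to 21 October 2016 with three missing acquisitions (23 June,
29 July, 3 September), three growing-season and two winter optical dates,
and six contiguous-patch land-cover classes (water 15%, forest/built-up
20%, double-cropped early–late rice 25%, middle rice 10%, other cropland
15%, other 15% by default). Class signatures: water flat at −24 dB,
forest/built-up flat at −10 dB (the two published anchor levels); rice
follows a piecewise-linear trajectory through an off-season baseline of
−14 dB, a −20 dB trough at the early-window midpoint and a −11 dB peak at
the middle-window midpoint (trough/peak/baseline are generator defaults,
not published values); double-cropped fields chain the early and late
trajectories. NDVI means: cropland 0.7 growing / 0.15 winter, forest
0.8 / 0.7, water −0.3, other 0.2. Noise is Gaussian, sd 1 dB (matching the
±1 dB spread of the flat signatures) and 0.05 NDVI. Patches come from
seeded region growth with exact (largest-remainder) class pixel counts, and
the whole scene is bit-reproducible from one seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mixed pixels at field boundaries (the dominant
real error source), speckle's non-Gaussian heavy tails, topographic and
incidence-angle effects, cloud contamination of the optical dates,
within-class phenological spread from staggered sowing, and georegistration
error between the SAR and optical stacks. End-to-end accuracies near 0.99
on synthetic scenes demonstrate that the pipeline's logic is correct under
its own assumptions, not that real-world accuracy would match.

## Numerical and interface choices

- **Raster format**: grids travel as ESRI ASCII (`.asc`) text rasters with
  a JSON sidecar carrying the unit tag; the format is GDAL-readable,
  diff-able and sufficient for the north-up, square-pixel grids this
  pipeline assumes. Read/write round-trips values, nodata, geotransform
  and unit exactly.
- **Unit tags** (`linear-power`, `dB`, `reflectance`, `index`, `label`)
  are checked by every operation, so e.g. dB conversion cannot run twice.
- **σ° ≤ 0** becomes nodata rather than an error: calibrated products
  contain zeros and the pipeline stays total.
- **Median filter** (5 × 5 default): reflect padding at borders; nodata
  neighbours are excluded from the window; an all-nodata window yields
  nodata. Implemented in C++ for speed; verified against a brute-force R
  oracle.
- **Nearest-neighbour resampling**: output covers the same extent at the
  target resolution (`ceil` dimensions); equidistant source centers tie to
  the smaller row, then column index — deterministic and testable. No value
  is ever interpolated.
- **Compositing** ignores nodata observations; a pixel is nodata only when
  every in-window observation is nodata; an *empty* window (no acquisition
  dates at all) is an error naming the window, since it means the calendar
  and the acquisition plan disagree.
- **Co-registration** is checked (same shape, geotransform within 1e-6)
  before any multi-grid operation.

## Problem sizes used in the shipped tests

The default synthetic scene is 200 × 200 pixels at 30 m (40,000 pixels, 15
SAR dates, 5 optical dates); the shared unit-test scene is 60 × 60. The
Monte-Carlo design checks use 500 simulated assessments of 4 strata × 2500
samples, and the bootstrap cross-check of the analytic SE uses 4000
replicates on a 2-category toy matrix. These sizes were chosen as the
smallest at which the statistical assertions are stable across seeds.

## Known limitations

- The heuristic cluster assignment assumes the scene actually contains
  contrasting clusters; on a scene without rice it correctly returns no
  rice layer, but on a scene where rice is a tiny fraction the
  across-centroid midpoint rule can mislabel — supply explicit mappings in
  that regime.
- The middle/late calendar defaults are regional stand-ins (see above).
- Areas assume an equal-area-adequate grid; reprojection is out of scope.
- The water layer is an input (an external water-extent product or the
  generator's truth); the pipeline does not derive it.
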