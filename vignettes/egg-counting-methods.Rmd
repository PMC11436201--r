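---
title: "Counting fly eggs in multiwell plates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fly eggs in multiwell plates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggquant)
```

# The assay

Fecundity — eggs laid per female per day — integrates the whole cascade of
*Drosophila* oogenesis, from nutrient sensing through ovulation, which makes
it a sensitive endpoint for dietary and chemical perturbations. A
high-throughput version of the assay cultures small cohorts (two females,
one male) in each well of a 48-well plate, transfers the flies to fresh
plates daily, and images the surface of every vacated well with a scanning
camera that positions each well identically in its frame. `eggquant`
implements the downstream computation: turning those per-well images into
egg counts, and turning counts into statistics that answer "did this
exposure reduce fecundity, and how many replicate wells would have
sufficed?".

# Plate geometry

Wells are addressed `A1`..`F8` on a 6 x 8 grid (`plate_grid()`). The camera
visits wells in a boustrophedon ("snake") path — each row traversed in
alternating direction so consecutive wells are one grid step apart
(`snake_path()`). The traversal's start corner and fast axis are not
physically constrained, so both are arguments; the default starts at the
top-left well with rows as the fast axis, matching conventional plate
reading with image y increasing downward.

Camera registration uses the centers of the four corner wells, recorded by
aligning a circular target over each (`corner_calibration()`). All 48 well
centers follow by bilinear interpolation on the fractional grid position
(`interpolate_well_centers()`): the corner wells reproduce the calibration
exactly, and the construction commutes with affine distortions of the plate
(translation, rotation, shear), which covers the placement errors a plate on
a flat stage can actually exhibit. Coordinates stay floating-point; rounding
to pixels happens only when masks are rendered.

# The synthetic-image generator

Every image-processing stage is tested against synthetic wells with exact
ground truth (`synthetic_well_spec()`, `render_well()`). A synthetic well
emulates the transmitted-light geometry of the real assay:

* a uniform bright media background (grey level 200 of 255) in a 600 x 600
  px frame, with the well as a circle of radius 260 px — chosen so the
  printed egg-size filter window (2500-4000 px^2) is meaningful on fixtures;
* eggs as filled ellipses darker than the background (raw camera polarity),
  with an egg-like 1.8-2.4:1 axis ratio; `random_well_spec()` draws areas
  uniformly in 2600-3800 px^2 by default, inside the filter window with
  margin for the ~2-3% boundary dilation that smoothing introduces at
  segmentation time;
* the well wall as a dark annulus (4 px wide) at the well radius;
* optional *wall reflections*: egg-like objects rendered outside the well
  radius, mimicking the mirror images of eggs in the clear plastic wall that
  inflate naive counts — they are deliberately excluded from ground truth;
* optional additive Gaussian noise, clipped to [0, 255].

Rendering is fully determined by the spec, including its seed: the same spec
yields byte-identical files. Rasterized ellipse areas stay within 2% of
pi.a.b for semi-axes of 10 px and up.

What the generator does *not* model: yeast texture and illumination
gradients, partially buried or stacked eggs, larvae walking through the
frame, and condensation. Passing the synthetic acceptance suite therefore
demonstrates the correctness of the pipeline's logic (geometry, filtering,
counting, statistics), not the detection performance on real plates — on
real data the learned segmentation backend and its thresholds carry that
burden.

A note on packing: at the default egg size, only on the order of 15-20
disjoint eggs fit in a well, so fixtures needing high counts (for example
Poisson draws with mean 36, the realistic day-1 egg count) must either use
smaller synthetic eggs or allow bounded overlap (`max_iou`); placement that
fails after `max_tries` attempts errors rather than silently dropping eggs,
so a truth table always matches what was rendered.

# Preprocessing and well detection

`preprocess()` channel-averages, inverts (eggs become bright), and rescales
so the 1st/99th intensity percentiles map to 0/255. Percentile rather than
min-max normalization resists isolated hot pixels; a constant image maps to
mid-grey with a warning. Whether normalization should be per-image or
per-plate is an open choice; per-image is implemented, which also makes each
well's processing independent.

`detect_well()` finds the circular well boundary from a Canny edge map
(implemented in-package: Gaussian smoothing at sigma 2, Sobel gradients,
non-maximum suppression along the quantized gradient direction, hysteresis
with thresholds at the 70th/90th percentile of above-floor gradient
magnitude). A relative magnitude floor (1e-3 of the maximum) keeps the
numerically non-zero ripples of FFT-based filtering out of the percentile
estimates. Circle fitting is seeded RANSAC over edge-point triplets,
restricted to radii within +/-15% of the user's estimated diameter, refined
by iterated algebraic least squares with an inlier band wide enough (inlier
tolerance + 2 px) to span both Canny edges of the wall, so the fitted radius
lands on the wall centerline. On clean fixtures this recovers the planted
center and radius to well under a pixel.

`fit_quality` is reported as *arc coverage*: the fraction of points sampled
on the fitted circle with an edge pixel within the inlier tolerance. (The
alternative — the fraction of all edge pixels near the fitted curve — is
dominated by egg edges on any well with many eggs and would make a fixed
quality cutoff meaningless.) Below 0.5 coverage, detection fails with a
typed condition carrying a fallback boundary (image center, radius =
estimate/2); the counting layer records the fallback in the well's flags
rather than aborting a plate.

Because the scanning camera registers every well identically,
`count_plate()` detects the boundary once on the first image of the snake
path and propagates it (`propagate_boundary()`); the per-image and
propagated routes give identical counts on registered fixtures, and the
ellipse-model fit remains available behind the circle default.

# The reference egg detector

The production segmentation model in this kind of pipeline is a trained
star-convex deep network whose weights cannot ship with a desk-testable
toolkit. `eggquant` therefore separates *contract* from *model*: the
`detection_set` interface (scored star-convex instances, thresholding, NMS,
serialization) is fixed, a registry (`register_backend()`) lets an external
learned model plug in, and a fully deterministic **reference detector**
exercises every contract:

1. Gaussian smoothing (sigma 2) and Otsu thresholding of the preprocessed
   image.
2. Morphological opening of the foreground with a disc of radius 4 px. This
   single step erases structures thinner than ~8 px — the well-wall ring and
   the smoothing bridges that fuse adjacent eggs — while provably leaving
   egg-sized convex regions untouched (an ellipse with semi-axes (40, 25)
   has minimum boundary curvature radius b^2/a ~ 16 px > 4). An earlier
   design that instead split components larger than 1.8x the median
   candidate area was abandoned: the median is itself inflated by the wall
   component and by the merged components the rule is meant to catch, so
   merged pairs slipped under the trigger.
3. Connected components; any component is offered to a watershed on its
   distance map (tolerance 1). A single convex egg has one distance maximum
   and never splits; adjacently laid eggs have a deep saddle and always do.
4. For each candidate: a star-convex polygon by casting `n_rays` (default
   32) rays from the intensity-weighted centroid to the component boundary,
   and a score in [0, 1] — the geometric mean of a foreground-contrast term
   (2 x (mean foreground - local background), clipped) and an
   ellipse-residual term (1 - 3 x mean radial residual / mean radius,
   clipped). A candidate whose centroid falls outside its own mask — a wall
   arc, never an egg — scores 0.

The score plays the role a learned model's probability plays: the default
threshold 0.7 can be adjusted for image quality, and the preset tuned for an
externally trained model (threshold 0.706, NMS IoU 0.3) is expressible in
`detector_config()`. Thresholding is applied before NMS; NMS is greedy on
mask IoU with fully specified tie-breaks (score, then area, then raster
order of the rounded centroid) so results are reproducible to the byte.

# Filtering and counting

The counting filter (`filter_detections()`) excludes instances outside the
predicted well and outside the 2500-4000 px^2 egg-size window; both area
bounds are inclusive (the exclusion rule is stated as strictly "less
than/greater than"). Inside-well means centroid-inside by default, so an egg
touching the wall still counts exactly once; a full-mask rule is available.
The counting boundary is the fitted circle eroded by 2 px, which is what
removes wall reflections: a reflection sits at or beyond the wall, so its
centroid can never be inside the eroded circle. Areas are measured on the
rasterized mask after NMS, before any cleanup. The open question of whether
the area filter precedes or follows NMS is resolved as after-NMS (before-NMS
filtering would let a large suppressed mask shield a kept one).

# Evaluation

Predictions are matched to ground truth one-to-one at an IoU threshold
(default t = 0.5). Matching maximizes the number of matched pairs
(maximum-cardinality bipartite matching on the thresholded IoU graph,
Kuhn's augmenting-path algorithm — no linear-assignment solver package is
assumed); a greedy by-IoU matcher is available behind a flag. From tp/fp/fn:
precision = tp/(tp+fp), recall = tp/(tp+fn), accuracy = tp/(tp+fp+fn) — the
worked example tp 50, fp 3, fn 2 gives 0.9434/0.9615/0.9091, confirming the
accuracy definition against its printed value (50/55 = 0.909). 0/0 ratios
report 1 with a degeneracy flag. Count-level agreement (`count_r2()`) is the
R^2 of an ordinary least-squares fit *with intercept* of automated on manual
counts — linear agreement, not identity.

# Fecundity statistics

**Inclusion rules.** Wells start with two females; a condition-day group is
dropped entirely when fewer than half its wells (strictly fewer than
ceiling(n/2)) retain both females, and in retained groups exactly the
both-alive wells are counted. The rule is idempotent and only ever removes
wells.

**Summaries and tests.** Per condition-day: mean, sample SD, CV (flagged
undefined at mean 0). Pairwise comparisons are two-sample t-tests — Welch by
default, since equal variances across doses is exactly what a toxicant
destroys; the pooled test is a flag away. The Bonferroni family is the set
of comparisons requested in one call (adjusted p = min(1, m x raw p));
comparisons against undersized groups are flagged, not silently dropped, and
still count toward m.

**Downsampling power analysis.** To ask "how many wells would have
sufficed", `downsample_power()` draws k wells per group without replacement
(k in {4, 8, 16, 24} conventionally), re-runs the pairwise test, repeats 100
times by default, and reports the p-value distribution and the fraction
below alpha. Each group is subsampled independently per iteration; one root
seed drives the whole run. Note that conditional on a *fixed* pair of
samples the significant fraction under the null need not equal alpha — the
calibration statement is marginal over data draws, which is how both the
test suite (2000 iterations on a fixed seeded draw, band 0.05 +/- 0.02) and
the acceptance script (20 fresh draws x 100 iterations) evaluate it.

**Synthetic counts.** `simulate_counts()` draws negative-binomial well
counts (Poisson available). The default dispersion 2.7 reproduces a day-1
CV of ~0.63 at a mean of ~36 eggs/well — the interwell variability of a
well-run assay — and each female survives each day independently with
probability 0.98, so exclusions appear at realistic rates in multi-day
designs.

# Dosing arithmetic

The exposure scheme dilutes a 1000x stock in 100% DMSO 1:100 with water
(10x in 1% DMSO) and adds 30 uL of that to a well holding 300 uL of media.
`plan_dilution()` reports both conventions for the final step: the *nominal*
bench convention (a 10-fold step: final 1x in 0.1% DMSO) and the *exact*
volumetric factor 30/330 (final 10/11 x ~ 0.909x), labeled so they are never
silently mixed. `intake_ng_per_day()` converts media concentration to daily
intake assuming 1.5 uL/day consumption:
intake = conc(uM) x MW(g/mol) x consumption(uL/day) x 1e-3 ng/day —
exactly linear in each factor. Display rounding follows dose-reporting
convention (2 decimals below 1 ng/day, 1 above). For 25 uM bendiocarb
(MW 223.23) the formula gives 8.37 ng/day where 8.3 is sometimes quoted;
the discrepancy is ~1% and the underlying rounding is not recoverable, so
that single value is documented rather than asserted.

# Problem sizes and numerical choices

* Fixture images are 600 x 600 px (8-bit); the acceptance suite runs 200
  seeded clean wells for count recovery, 100 random instance sets for the
  matching oracle and the monotonicity properties, 2000 resampling
  iterations for null calibration, and 20 seeds x 4 subset sizes for power
  monotonicity — sizes chosen to make sampling noise negligible relative to
  the asserted bounds while keeping a full run in the minutes range on one
  core.
* RANSAC: 500 iterations, 3 px inlier tolerance, fixed internal seed scoped
  so the session RNG is never perturbed.
* All randomness flows from explicit seeds; `derive_seed()` fans a root seed
  into per-module streams with a fixed affine map modulo 2^31 - 1.
* Ties in NMS and matching are broken by documented deterministic rules.
* Degenerate inputs have defined behavior rather than errors where a plate
  run must continue: constant images normalize to mid-grey with a warning,
  failed well detection falls back with a flag, empty foreground yields an
  empty detection set.

# Known limitations

* The reference detector is built for the synthetic geometry; on real
  images its Otsu/opening front end will underperform a trained star-convex
  model, which is what the backend adapter is for.
* Ground-truth label masks resolve overlapping planted eggs by draw order,
  so generator overlap is capped (IoU 0.2) to keep truth unambiguous.
* The statistics layer treats wells as independent replicates; plate- or
  replicate-level random effects are out of scope.
* The circle boundary model assumes round wells; the ellipse fit handles
  mild perspective but strong oblique imaging is unsupported.
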