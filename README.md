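# eggquant

High-throughput quantification of *Drosophila melanogaster* egg laying in
48-well plates.

Fecundity — eggs laid per female per day — is a whole-organism readout of
oogenesis and a sensitive endpoint for reproductive toxicology. In the
high-throughput form of the assay, small fly cohorts (2 females + 1 male per
well) are cultured in 48-well plates, transferred daily, and each vacated
well is photographed by a scanning camera that registers every well at the
same image position. `eggquant` is the computational side of that assay, for
the lab that runs it: it turns per-well images into egg counts and counts
into statistics.

The pipeline, per well image:

1. **Preprocess** — grayscale, invert (eggs become bright), rescale the
   1st/99th intensity percentiles to 0/255.
2. **Well detection** — Canny edge map, seeded RANSAC circle fit restricted
   to ±15% of the estimated well diameter; the boundary found on a plate's
   first image is propagated to the rest.
3. **Segmentation** — scored star-convex egg instances. A deterministic
   reference detector (Otsu threshold → morphological opening → watershed
   split of touching eggs → radial polygons with a contrast × ellipse-fit
   score) exercises every contract; an externally trained star-convex model
   can be registered as a drop-in backend.
4. **Filtering** — keep instances with score ≥ 0.7 (adjustable), mask IoU
   ≤ 0.3 after greedy NMS, centroid inside the fitted well (eroded 2 px,
   which removes wall-reflection artifacts), and area in 2500–4000 px².
5. **Export** — per-well counts with provenance flags, CSV tables, overlay
   images with outlines, boundary and count burned in.

Downstream: instance-level evaluation against ground truth at an IoU
threshold *t* (precision = tp/(tp+fp), recall = tp/(tp+fn), accuracy =
tp/(tp+fp+fn); count agreement as OLS R²), survival-based inclusion rules,
per-condition summaries (mean, SD, CV), Bonferroni-corrected pairwise
*t*-tests, a downsampling power analysis (resample k ∈ {4, 8, 16, 24} wells
per group, re-test, repeat), and chemical dosing arithmetic (serial dilution
planning for the 1000× → 10× → 1× scheme and conversion of media
concentration to daily dietary intake, intake = conc·MW·consumption·10⁻³
ng/day).

A synthetic-image generator renders wells with exact instance-level ground
truth (eggs, well wall, wall reflections, noise — all seeded and
byte-reproducible), so the whole pipeline is testable without a camera.

## Worked example

Generate a small synthetic plate, count it, and compare to truth:

```r
library(eggquant)

dir <- file.path(tempdir(), "demo")
grid <- plate_grid(2, 3)
set.seed(derive_seed(42, 1))
n_eggs <- rpois(6, 8)
specs <- lapply(1:6, function(k)
  random_well_spec(n_eggs[k], seed = derive_seed(42, 100 + k)))
truth <- render_plate(grid, specs, dir, plate_id = "demo")

layout <- data.frame(plate_id = "demo", well_label = truth$label,
                     condition = rep(c("dmso", "rapa25"), 3), day = 1L)
res <- count_plate(dir, layout, est_diameter = 520, grid = grid)
res
#>  plate_id well_label condition day count n_prefilter flags
#>      demo         A1      dmso   1     8           8
#>      demo         A2    rapa25   1    11          11
#>      demo         A3      dmso   1     7           7
#>      demo         B3    rapa25   1     7           7
#>      demo         B2      dmso   1     5           5
#>      demo         B1    rapa25   1     7           7
truth$true_count
#> [1]  8 11  7  7  5  7
```

Every planted count is recovered; wells are listed in the camera's
snake-path order (A1 → A3, then B3 → B1), and `flags` would record a
fallback well detection or a missing layout row. Evaluation and dosing:

```r
metrics(list(tp = 50, fp = 3, fn = 2))
#> precision 0.9434  recall 0.9615  accuracy 0.9091

format_intake(intake_ng_per_day(25, "rapamycin"))
#> [1] 34.3        # ng/day at 1.5 uL consumed per day

plan_dilution()
#>         stage fold_nominal dmso_pct_nominal fold_exact dmso_pct_exact
#>         stock         1000            100.0  1000.0000      100.00000
#>  intermediate           10              1.0    10.0000        1.00000
#>         final            1              0.1     0.9091        0.09091
```

A command-line interface wraps the same functions
(`exec/eggquant <command>`, commands `synth`, `count`, `evaluate`, `stats`,
`power`, `dose`, `calibrate`), e.g.:

```sh
Rscript exec/eggquant dose --conc 25 --chemical rapamycin
Rscript exec/eggquant synth --out plate1 --seed 1 --mean-eggs 10
Rscript exec/eggquant count --dir plate1 --out counts.csv
```

## Package layout

- `R/plate_geometry.R` — grid addressing, snake path, corner calibration
- `R/image_synth.R` — synthetic wells/plates with ground truth
- `R/well_detection.R` — preprocessing, Canny + RANSAC well boundary
- `R/egg_segmentation.R`, `R/backends.R` — reference detector, NMS, backend
  registry
- `R/count_pipeline.R`, `R/overlay.R` — filtering, per-well/plate counting,
  exports, overlays
- `R/segmentation_eval.R` — instance matching, metrics, count R²
- `R/fecundity_stats.R` — inclusion rules, summaries, pairwise tests,
  downsampling power, count simulation
- `R/dosing.R` — dilution planning, intake estimates
- `R/config.R`, `exec/eggquant` — configuration, manifests, CLI

See the vignette (`vignettes/egg-counting-methods.Rmd`) for the methods and
the reasoning behind the design choices.
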