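test_that("the area window keeps only in-range detections, bounds inclusive", {
  H <- 700L
  b <- well_boundary(c(300, 300), 260)
  mk <- function(n_px, cx) {
    side <- floor(sqrt(n_px))
    m <- rect_mask(H, cx, cx + side - 1, 280, 280 + ceiling(n_px / side) - 1)
    make_instance(m[seq_len(n_px)], score = 1, centroid = c(cx + side / 2, 285),
                  H = H)
  }
  ds <- detection_set(list(mk(1000, 100), mk(3000, 200), mk(5000, 300)),
                      dim = c(H, H))
  expect_length(filter_detections(ds, b), 1L)
  # inclusive bounds
  ds2 <- detection_set(list(mk(2500, 150), mk(4000, 250)), dim = c(H, H))
  expect_length(filter_detections(ds2, b), 2L)
  ds3 <- detection_set(list(mk(2499, 150), mk(4001, 250)), dim = c(H, H))
  expect_length(filter_detections(ds3, b), 0L)
})

test_that("detections centered outside the boundary are excluded", {
  H <- 700L
  b <- well_boundary(c(300, 300), 100)
  inst <- make_instance(rect_mask(H, 500, 554, 300, 354)[1:3000],
                        centroid = c(527, 327), H = H)
  ds <- detection_set(list(inst), dim = c(H, H))
  expect_length(filter_detections(ds, b), 0L)
  expect_length(filter_detections(ds, b,
                                  filter_config(require_inside_well = FALSE)),
                1L)
})

test_that("wall reflections change unmasked counts but never masked counts", {
  plain <- random_well_spec(n_eggs = 6, seed = 11)
  with_refl <- random_well_spec(n_eggs = 6, seed = 11, n_reflections = 2)
  b <- detect_well(preprocess(render_well(plain)$image), 520)
  count_of <- function(spec, inside) {
    img <- preprocess(render_well(spec)$image)
    length(filter_detections(run_backend(img), b,
                             filter_config(require_inside_well = inside)))
  }
  expect_equal(count_of(plain, TRUE), 6L)
  expect_equal(count_of(with_refl, TRUE), 6L)       # masking removes them
  expect_gt(count_of(with_refl, FALSE), count_of(plain, FALSE))
})

test_that("count_well counts planted eggs and respects filter monotonicity", {
  dir <- withr::local_tempdir()
  spec <- random_well_spec(n_eggs = 5, seed = 14)
  rw <- render_well(spec)
  p <- file.path(dir, "plate01_A1.png")
  write_gray_image(rw$image, p)
  rec <- count_well(p, est_diameter = 520, well = "A1")
  expect_equal(rec$count, 5L)
  expect_lte(rec$count, rec$n_prefilter)
  expect_equal(rec$flags, "")
  # lowering area_max below all planted areas zeroes the count
  rec0 <- count_well(p, est_diameter = 520,
                     filt_cfg = filter_config(area_min = 10, area_max = 100))
  expect_equal(rec0$count, 0L)
  expect_error(count_well(file.path(dir, "missing.png"), est_diameter = 520),
               "cannot read")
})

test_that("a featureless well image is flagged and counted as zero", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "plate01_A1.png")
  write_gray_image(matrix(180, 600, 600), p)
  rec <- suppressWarnings(count_well(p, est_diameter = 520))
  expect_equal(rec$count, 0L)
  expect_match(rec$flags, "fallback_boundary")
})

test_that("count_plate totals equal the generator truth on a clean plate", {
  dir <- withr::local_tempdir()
  g <- plate_grid(2, 2)
  specs <- lapply(1:4, function(k) random_well_spec(n_eggs = k + 2, seed = 40 + k))
  truth <- render_plate(g, specs, dir, plate_id = "p2")
  layout <- data.frame(plate_id = "p2", well_label = truth$label,
                       condition = "ctrl", day = 1L)
  res <- count_plate(dir, layout, est_diameter = 520, grid = g)
  expect_equal(nrow(res), 4L)
  expect_equal(res$well_label, truth$label)    # snake order preserved
  expect_equal(res$count, truth$true_count)
  expect_equal(unique(res$condition), "ctrl")
  # totals equal the sum of independent per-well calls
  per_well <- vapply(truth$filename, function(f)
    count_well(file.path(dir, f), est_diameter = 520)$count, integer(1))
  expect_equal(sum(res$count), sum(per_well))
})

test_that("count_plate handles empty dirs, duplicates, and missing layout rows", {
  empty <- withr::local_tempdir()
  expect_warning(res <- count_plate(empty, est_diameter = 520), "no well images")
  expect_equal(nrow(res), 0L)
  dir <- withr::local_tempdir()
  rw <- render_well(random_well_spec(n_eggs = 3, seed = 1))
  write_gray_image(rw$image, file.path(dir, "p_A1.png"))
  write_gray_image(rw$image, file.path(dir, "p_A1.tif"))
  expect_error(count_plate(dir, est_diameter = 520, grid = plate_grid(1, 1)),
               "duplicate")
  dir2 <- withr::local_tempdir()
  write_gray_image(rw$image, file.path(dir2, "p_A1.png"))
  layout <- data.frame(plate_id = "p", well_label = "B9",
                       condition = "x", day = 1L)
  res <- suppressMessages(count_plate(dir2, layout, est_diameter = 520,
                                      grid = plate_grid(1, 1)))
  expect_match(res$flags, "missing_layout")
  expect_true(is.na(res$condition))
})

test_that("counts tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  tab <- data.frame(plate_id = "p1", well_label = c("A1", "A2", "B1"),
                    condition = c("ctrl", "ctrl", "dose1"), day = c(1L, 1L, 3L),
                    count = c(12L, 0L, 31L), n_prefilter = c(14L, 2L, 31L),
                    flags = c("", "fallback_boundary", ""),
                    stringsAsFactors = FALSE)
  p <- file.path(dir, "counts.csv")
  export_counts(tab, p)
  back <- read_counts(p)
  expect_equal(back, tab)
  expect_error(export_counts(tab[, -5], p), "lacks columns")
})

test_that("shrinking the filter window or boundary never increases a count", {
  for (s in 1:20) {
    set.seed(700 + s)
    masks <- random_blob_masks(12, H = 100, W = 100, r_range = c(2, 9))
    inst <- lapply(masks, function(m) make_instance(m, score = 1, H = 100L))
    ds <- detection_set(inst, dim = c(100L, 100L))
    b_big <- well_boundary(c(50, 50), 45)
    b_small <- well_boundary(c(50, 50), 30)
    wide <- filter_config(area_min = 10, area_max = 250)
    narrow <- filter_config(area_min = 30, area_max = 150)
    n_ww <- length(filter_detections(ds, b_big, wide))
    expect_lte(length(filter_detections(ds, b_big, narrow)), n_ww)
    expect_lte(length(filter_detections(ds, b_small, wide)), n_ww)
    expect_lte(length(filter_detections(ds, b_small, narrow)), n_ww)
  }
})

test_that("overlays render annotations without touching the counting path", {
  dir <- withr::local_tempdir()
  spec <- random_well_spec(n_eggs = 4, seed = 19)
  rw <- render_well(spec)
  img_path <- file.path(dir, "plate01_A1.png")
  write_gray_image(rw$image, img_path)
  rec1 <- count_well(img_path, est_diameter = 520)
  over <- file.path(dir, "overlay.png")
  save_overlay(rw$image, attr(rec1, "detections"), attr(rec1, "boundary"),
               over)
  expect_true(file.exists(over))
  arr <- png::readPNG(over)
  expect_equal(dim(arr), c(600, 600, 3))
  expect_gt(sum(arr[, , 1] == 1 & arr[, , 2] == 0 & arr[, , 3] == 0), 0)
  # re-running the count on the original image is unchanged
  rec2 <- count_well(img_path, est_diameter = 520)
  expect_equal(rec2$count, rec1$count)
  # zero detections: boundary circle only
  empty <- detection_set(dim = c(600L, 600L))
  save_overlay(rw$image, empty, attr(rec1, "boundary"),
               file.path(dir, "empty.png"))
  arr0 <- png::readPNG(file.path(dir, "empty.png"))
  expect_equal(sum(arr0[, , 1] == 1 & arr0[, , 2] == 0 & arr0[, , 3] == 0), 0)
})
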