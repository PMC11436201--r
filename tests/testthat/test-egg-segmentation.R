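test_that("a blank image yields no candidates", {
  expect_length(detect_candidates(matrix(0, 200, 200)), 0L)
  expect_length(detect_candidates(matrix(128, 200, 200)), 0L)
})

test_that("well-separated planted eggs are each recovered near their centers", {
  spec <- random_well_spec(n_eggs = 5, seed = 5)
  rw <- render_well(spec)
  cand <- detect_candidates(preprocess(rw$image))
  expect_length(cand, 5L)
  ctr <- t(sapply(cand$instances, `[[`, "centroid"))
  d <- apply(ctr, 1, function(p)
    min(sqrt((p[1] - rw$truth$centroids$x)^2 +
               (p[2] - rw$truth$centroids$y)^2)))
  expect_true(all(d < 3))
})

test_that("a single planted ellipse is measured within 5% of truth area", {
  spec <- synthetic_well_spec(eggs = list(egg_spec(c(300, 300), c(40, 25),
                                                  0.7)))
  rw <- render_well(spec)
  cand <- detect_candidates(preprocess(rw$image))
  expect_length(cand, 1L)
  expect_lt(abs(cand$instances[[1]]$area - rw$truth$areas) / rw$truth$areas,
            0.05)
  # polygon is star-convex about the centroid: vertices lie at positive radii
  poly <- cand$instances[[1]]$polygon
  ctr <- cand$instances[[1]]$centroid
  expect_true(all(sqrt((poly[, 1] - ctr[1])^2 + (poly[, 2] - ctr[2])^2) > 0))
  expect_equal(nrow(poly), detector_config()$n_rays)
})

test_that("score thresholding keeps exactly the instances at or above threshold", {
  H <- 100L
  ds <- make_detset(
    make_instance(rect_mask(H, 1, 10, 1, 10), score = 0.9),
    make_instance(rect_mask(H, 20, 30, 20, 30), score = 0.71),
    make_instance(rect_mask(H, 40, 50, 40, 50), score = 0.69))
  expect_length(apply_score_threshold(ds, 0.7), 2L)
  expect_length(apply_score_threshold(ds, 0), 3L)
  expect_length(apply_score_threshold(ds, 1), 0L)
  kept <- apply_score_threshold(ds, 0.7)
  expect_equal(sapply(kept$instances, `[[`, "score"), c(0.9, 0.71))
})

test_that("NMS suppresses overlapping lower-scoring instances", {
  H <- 100L
  a <- make_instance(rect_mask(H, 1, 20, 1, 30), score = 0.9)
  b <- make_instance(rect_mask(H, 1, 20, 11, 40), score = 0.8)  # IoU 0.5
  out <- nms(make_detset(a, b), 0.3)
  expect_length(out, 1L)
  expect_equal(out$instances[[1]]$score, 0.9)
  # disjoint instances all survive
  c2 <- make_instance(rect_mask(H, 60, 70, 60, 70), score = 0.1)
  expect_length(nms(make_detset(a, c2), 0.3), 2L)
})

test_that("NMS equals the brute-force greedy oracle on random overlapping sets", {
  for (s in 1:20) {
    set.seed(100 + s)
    masks <- random_blob_masks(10, H = 60, W = 60)
    inst <- lapply(seq_along(masks), function(i)
      make_instance(masks[[i]], score = round(runif(1), 3), H = 60L))
    ds <- detection_set(inst, dim = c(60L, 60L))
    got <- nms(ds, 0.3)
    oracle_idx <- greedy_nms_oracle(ds, 0.3)
    expect_identical(sapply(got$instances, `[[`, "score"),
                     sapply(ds$instances[oracle_idx], `[[`, "score"))
  }
})

test_that("threshold monotonicity and NMS top-score retention hold on random sets", {
  for (s in 1:20) {
    set.seed(300 + s)
    masks <- random_blob_masks(8, H = 60, W = 60)
    inst <- lapply(masks, function(m) make_instance(m, score = runif(1), H = 60L))
    ds <- detection_set(inst, dim = c(60L, 60L))
    kept <- vapply(seq(0, 1, by = 0.1), function(th)
      length(apply_score_threshold(ds, th)), integer(1))
    expect_true(all(diff(kept) <= 0))
    top <- max(sapply(inst, `[[`, "score"))
    for (th in c(0.1, 0.3, 0.6)) {
      out <- nms(ds, th)
      expect_true(any(abs(sapply(out$instances, `[[`, "score") - top) < 1e-12))
      # no surviving pair overlaps above the threshold
      if (length(out) > 1) {
        for (i in 1:(length(out) - 1)) for (j in (i + 1):length(out))
          expect_lte(instance_iou(out$instances[[i]]$mask,
                                  out$instances[[j]]$mask), th)
      }
    }
  }
})

test_that("the backend registry dispatches, validates, and passes through", {
  spec <- random_well_spec(n_eggs = 4, seed = 8)
  img <- preprocess(render_well(spec)$image)
  cfg <- detector_config()
  ref <- run_backend(img, "reference", cfg)
  manual <- nms(apply_score_threshold(detect_candidates(img, cfg),
                                      cfg$prob_thresh), cfg$nms_thresh)
  expect_equal(length(ref), length(manual))
  expect_equal(sapply(ref$instances, `[[`, "area"),
               sapply(manual$instances, `[[`, "area"))
  expect_equal(ref$provenance, "reference")
  expect_error(run_backend(img, "no_such_model"), "unknown detector backend")
  fixed <- make_detset(make_instance(rect_mask(100L, 1, 10, 1, 10), 0.5))
  register_backend("mock", function(img, cfg) fixed)
  out <- run_backend(img, "mock")
  expect_equal(out$instances, fixed$instances)
  expect_equal(out$provenance, "mock")
  expect_true("mock" %in% list_backends())
})

test_that("detection sets serialize to CSV and label masks", {
  dir <- withr::local_tempdir()
  ds <- make_detset(make_instance(rect_mask(100L, 1, 10, 1, 10), 0.8),
                    make_instance(rect_mask(100L, 30, 40, 30, 44), 0.9))
  df <- detections_to_csv(ds, file.path(dir, "dets.csv"), well = "A1")
  on_disk <- read.csv(file.path(dir, "dets.csv"))
  expect_equal(nrow(on_disk), 2L)
  expect_equal(on_disk$area_px2, c(100L, 165L))
  m <- detections_to_label_mask(ds)
  expect_equal(sort(unique(as.vector(m))), c(0L, 1L, 2L))
  expect_equal(sum(m == 2L), 165L)
})
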