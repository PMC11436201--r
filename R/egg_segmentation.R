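#' Detector configuration
#'
#' Parameters of the reference star-convex egg detector and its
#' post-processing. The probability threshold defaults to 0.7 and can be
#' adjusted for image quality; the preset tuned for an externally trained
#' model is 0.706 with NMS IoU 0.3.
#'
#' @param prob_thresh score threshold in \[0, 1\] (default 0.7).
#' @param nms_thresh IoU threshold for non-maximum suppression (default 0.3).
#' @param n_rays number of rays of the star-convex polygon (>= 8, default 32).
#' @param smoothing_sigma Gaussian smoothing sigma in px before thresholding.
#' @param threshold_method foreground threshold method (`"otsu"`).
#' @param split attempt to split adjacently laid (merged) eggs by a
#'   watershed on the component's distance map (default TRUE). A single
#'   convex egg has one distance maximum and is never split; merged pairs
#'   have a deep saddle and are.
#' @param split_tolerance watershed tolerance (minimum saddle depth) for the
#'   split, in distance-map units (default 1).
#' @param open_radius radius (px) of the morphological opening applied to
#'   the thresholded foreground (default 4). The opening erases structures
#'   thinner than about twice this radius — the well-wall ring and the
#'   smoothing bridges that fuse adjacent eggs — while leaving convex
#'   egg-sized regions (boundary curvature radius above the disc radius)
#'   untouched. 0 disables it.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(prob_thresh = 0.7, nms_thresh = 0.3,
                            n_rays = 32L, smoothing_sigma = 2,
                            threshold_method = "otsu", split = TRUE,
                            split_tolerance = 1, open_radius = 4) {
  stopifnot(prob_thresh >= 0, prob_thresh <= 1,
            nms_thresh >= 0, nms_thresh <= 1,
            n_rays >= 8L, smoothing_sigma >= 0,
            identical(threshold_method, "otsu"), is.logical(split),
            split_tolerance > 0, open_radius >= 0)
  structure(list(prob_thresh = prob_thresh, nms_thresh = nms_thresh,
                 n_rays = as.integer(n_rays),
                 smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 split = isTRUE(split), split_tolerance = split_tolerance,
                 open_radius = open_radius),
            class = "detector_config")
}

#' Construct a detection set
#'
#' A detection set holds the candidate (or final) egg instances of one well
#' image. Each instance is a list with `centroid` (x, y), `polygon`
#' (`n_rays x 2` matrix of x, y vertices), `mask` (sorted linear pixel
#' indices into the image matrix), `area` (mask pixel count) and `score`
#' in \[0, 1\].
#'
#' @param instances list of instance lists.
#' @param dim image dimensions `c(H, W)`.
#' @param provenance detector tag (`"reference"` or a backend name).
#' @return an object of class `detection_set`.
#' @export
detection_set <- function(instances = list(), dim, provenance = "reference") {
  stopifnot(length(dim) == 2L)
  structure(list(instances = instances, dim = as.integer(dim),
                 provenance = provenance),
            class = "detection_set")
}

#' @export
length.detection_set <- function(x) length(x$instances)

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %d instance(s) on %dx%d image [%s]\n",
              length(x), x$dim[1], x$dim[2], x$provenance))
  invisible(x)
}

#' Mask intersection-over-union
#'
#' IoU of two pixel masks given as linear index vectors (as stored in
#' [detection_set()] instances). Symmetric; 0 for disjoint masks; two empty
#' masks give 0 (with attribute `degenerate = TRUE`).
#'
#' @param mask_a,mask_b integer vectors of linear pixel indices.
#' @return IoU in \[0, 1\].
#' @export
instance_iou <- function(mask_a, mask_b) {
  if (length(mask_a) == 0L && length(mask_b) == 0L)
    return(structure(0, degenerate = TRUE))
  inter <- length(intersect(mask_a, mask_b))
  inter / (length(mask_a) + length(mask_b) - inter)
}

# component moments -> equivalent ellipse (semi-axes, orientation)
mask_ellipse <- function(xs, ys) {
  mx <- mean(xs); my <- mean(ys)
  # +1/12: variance of the unit pixel, so single-pixel masks stay finite
  cxx <- mean((xs - mx)^2) + 1 / 12
  cyy <- mean((ys - my)^2) + 1 / 12
  cxy <- mean((xs - mx) * (ys - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  a <- 2 * sqrt(max(ev$values[1], 1e-9))
  b <- 2 * sqrt(max(ev$values[2], 1e-9))
  theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  list(a = a, b = b, theta = theta)
}

# radius of an ellipse (a, b, theta) along absolute angle phi from its center
ellipse_radius <- function(a, b, theta, phi) {
  psi <- phi - theta
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# build one instance from component pixel indices
build_instance <- function(pix_rc, sm, H, W, n_rays) {
  xs <- pix_rc[, 2]; ys <- pix_rc[, 1]
  idx <- sort(ys + (xs - 1L) * H)
  wts <- sm[cbind(ys, xs)]
  wts <- wts / sum(wts)
  cx <- sum(xs * wts); cy <- sum(ys * wts)
  inmask <- matrix(FALSE, H, W); inmask[cbind(ys, xs)] <- TRUE
  phi <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  rmax <- 2 * max(abs(xs - cx), abs(ys - cy), 1)
  centroid_in <- {
    rc <- round(cy); cc <- round(cx)
    rc >= 1 && rc <= H && cc >= 1 && cc <= W && inmask[rc, cc]
  }
  rays <- numeric(n_rays)
  if (centroid_in) {
    steps <- seq(0, rmax, by = 0.5)
    for (j in seq_len(n_rays)) {
      px <- round(cx + steps * cos(phi[j]))
      py <- round(cy + steps * sin(phi[j]))
      okb <- px >= 1 & px <= W & py >= 1 & py <= H
      inside <- okb
      inside[okb] <- inmask[cbind(py[okb], px[okb])]
      out1 <- which(!inside)[1]
      rays[j] <- if (is.na(out1)) rmax else steps[max(out1 - 1L, 1L)]
    }
  }
  polygon <- cbind(x = cx + rays * cos(phi), y = cy + rays * sin(phi))
  # score: geometric mean of foreground-contrast and ellipse-residual scores
  score <- 0
  if (centroid_in) {
    box_r <- max(1L, floor(min(ys) - 5)):min(H, ceiling(max(ys) + 5))
    box_c <- max(1L, floor(min(xs) - 5)):min(W, ceiling(max(xs) + 5))
    ring_vals <- sm[box_r, box_c][!inmask[box_r, box_c]]
    bg <- if (length(ring_vals)) mean(ring_vals) else 0
    s_contrast <- min(max(2 * (mean(sm[idx]) - bg), 0), 1)
    el <- mask_ellipse(xs, ys)
    rhat <- ellipse_radius(el$a, el$b, el$theta, phi)
    resid <- mean(abs(rays - rhat)) / mean(rhat)
    s_ellipse <- min(max(1 - 3 * resid, 0), 1)
    score <- sqrt(s_contrast * s_ellipse)
  }
  list(centroid = c(cx, cy), polygon = polygon, mask = idx,
       area = length(idx), score = score)
}

#' Detect candidate egg instances (reference star-convex detector)
#'
#' The reference detector is a fully deterministic stand-in for a learned
#' star-convex segmentation model, preserving the same pipeline contracts:
#' the preprocessed image is Gaussian-smoothed and Otsu-thresholded;
#' connected foreground components become candidates (components much larger
#' than the median are split by a one-step watershed on the distance map, to
#' separate adjacently laid eggs); each candidate's polygon is built by
#' casting `n_rays` rays from its intensity-weighted centroid to the
#' component boundary; its score is the geometric mean of a
#' foreground-contrast score and an ellipse-fit residual score, each in
#' \[0, 1\]. A candidate whose centroid falls outside its own mask (a
#' non-star-convex region such as a wall arc) scores 0.
#'
#' Returned candidates are unthresholded and pre-NMS; see
#' [apply_score_threshold()] and [nms()].
#'
#' @param img preprocessed grayscale matrix ([preprocess()]).
#' @param cfg a [detector_config()].
#' @return a [detection_set()] (empty when no foreground is found).
#' @export
detect_candidates <- function(img, cfg = detector_config()) {
  stopifnot(is.matrix(img), inherits(cfg, "detector_config"))
  H <- nrow(img); W <- ncol(img)
  sm <- img / 255
  if (cfg$smoothing_sigma > 0) sm <- EBImage::gblur(sm, cfg$smoothing_sigma)
  if (max(sm) - min(sm) < 1e-8)
    return(detection_set(dim = c(H, W)))
  thr <- EBImage::otsu(EBImage::Image(pmin(pmax(sm, 0), 1)))
  fg <- sm > thr
  if (!any(fg)) return(detection_set(dim = c(H, W)))
  if (cfg$open_radius > 0) {
    # erase thin structures (well wall, smoothing bridges between adjacent
    # eggs); convex egg-sized regions pass through unchanged
    fg <- EBImage::opening(fg * 1,
                           EBImage::makeBrush(2L * ceiling(cfg$open_radius) +
                                                1L, "disc")) > 0
    if (!any(fg)) return(detection_set(dim = c(H, W)))
  }
  lab <- EBImage::bwlabel(fg)
  comp_pix <- split(seq_len(H * W)[lab > 0], lab[lab > 0])
  pieces <- list()
  for (k in seq_along(comp_pix)) {
    idx <- comp_pix[[k]]
    rc <- cbind((idx - 1L) %% H + 1L, (idx - 1L) %/% H + 1L)
    if (cfg$split && length(idx) > 8L) {
      # split adjacently laid eggs: watershed on the distance map; a single
      # convex egg has one maximum and survives unsplit
      r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
      sub <- matrix(0, max(rc[, 1]) - r0 + 3L, max(rc[, 2]) - c0 + 3L)
      sub[cbind(rc[, 1] - r0 + 2L, rc[, 2] - c0 + 2L)] <- 1
      ws <- EBImage::watershed(EBImage::distmap(sub),
                               tolerance = cfg$split_tolerance, ext = 1)
      if (max(ws) > 1L) {
        for (w in seq_len(max(ws))) {
          wi <- which(ws == w, arr.ind = TRUE)
          pieces[[length(pieces) + 1L]] <-
            cbind(wi[, 1] + r0 - 2L, wi[, 2] + c0 - 2L)
        }
        next
      }
    }
    pieces[[length(pieces) + 1L]] <- rc
  }
  instances <- lapply(pieces, build_instance, sm = sm, H = H, W = W,
                      n_rays = cfg$n_rays)
  detection_set(instances, dim = c(H, W))
}

#' Threshold detections by score
#'
#' Keeps exactly the instances with `score >= prob_thresh`, preserving order.
#'
#' @param dets a [detection_set()].
#' @param prob_thresh score threshold in \[0, 1\].
#' @return a [detection_set()].
#' @export
apply_score_threshold <- function(dets, prob_thresh = 0.7) {
  stopifnot(inherits(dets, "detection_set"),
            prob_thresh >= 0, prob_thresh <= 1)
  keep <- vapply(dets$instances, function(i) i$score >= prob_thresh,
                 logical(1))
  detection_set(dets$instances[keep], dets$dim, dets$provenance)
}

#' Non-maximum suppression on mask IoU
#'
#' Greedy suppression: instances are visited by decreasing score (ties broken
#' by larger area, then by raster order of the rounded centroid) and kept iff
#' their mask IoU with every already-kept instance is `<= nms_thresh`. The
#' top-scoring instance is therefore always kept.
#'
#' @param dets a [detection_set()].
#' @param nms_thresh IoU threshold in \[0, 1\].
#' @return a [detection_set()] in which no pair overlaps above `nms_thresh`.
#' @export
nms <- function(dets, nms_thresh = 0.3) {
  stopifnot(inherits(dets, "detection_set"),
            nms_thresh >= 0, nms_thresh <= 1)
  n <- length(dets)
  if (n <= 1L) return(dets)
  W <- dets$dim[2]
  score <- vapply(dets$instances, `[[`, numeric(1), "score")
  area <- vapply(dets$instances, `[[`, numeric(1), "area")
  raster <- vapply(dets$instances, function(i)
    round(i$centroid[2]) * W + round(i$centroid[1]), numeric(1))
  ord <- order(-score, -area, raster)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (instance_iou(dets$instances[[i]]$mask,
                       dets$instances[[j]]$mask) > nms_thresh) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  detection_set(dets$instances[sort(kept)], dets$dim, dets$provenance)
}

#' Detection set export
#'
#' Writes one row per instance (`well`, `x`, `y`, `area_px2`, `score`) to
#' CSV, or rasterizes the instances to an integer label mask (instances
#' numbered in list order; later instances overwrite shared pixels).
#'
#' @param dets a [detection_set()].
#' @param path CSV path.
#' @param well well label recorded in the CSV (default NA).
#' @return `detections_to_csv` returns the data.frame invisibly;
#'   `detections_to_label_mask` returns an integer `H x W` matrix.
#' @export
detections_to_csv <- function(dets, path, well = NA_character_) {
  stopifnot(inherits(dets, "detection_set"))
  df <- data.frame(
    well = well,
    x = vapply(dets$instances, function(i) i$centroid[1], numeric(1)),
    y = vapply(dets$instances, function(i) i$centroid[2], numeric(1)),
    area_px2 = vapply(dets$instances, `[[`, numeric(1), "area"),
    score = vapply(dets$instances, `[[`, numeric(1), "score"))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname detections_to_csv
#' @export
detections_to_label_mask <- function(dets) {
  stopifnot(inherits(dets, "detection_set"))
  m <- matrix(0L, dets$dim[1], dets$dim[2])
  for (k in seq_along(dets$instances)) m[dets$instances[[k]]$mask] <- k
  m
}
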