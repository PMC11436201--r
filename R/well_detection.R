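#' Preprocess a raw well image
#'
#' Standardizes a raw camera frame for segmentation: channel-averages RGB to
#' grayscale, inverts the polarity (under transmitted light eggs are darker
#' than media; after inversion they are bright), and linearly rescales so the
#' 1st and 99th intensity percentiles map to 0 and 255, clipping beyond.
#' Percentile (rather than min-max) normalization keeps isolated hot pixels
#' from compressing the usable range.
#'
#' A constant input has no contrast to normalize; it maps to a uniform
#' mid-grey (128) with a warning.
#'
#' @param raw numeric matrix (grayscale) or `H x W x C` array (RGB), values
#'   on the 0-255 scale.
#' @param invert invert polarity before normalizing (default TRUE; set FALSE
#'   to renormalize an already-inverted image).
#' @param probs the two percentiles mapped to 0 and 255.
#' @return numeric matrix of integer grey levels 0-255.
#' @export
preprocess <- function(raw, invert = TRUE, probs = c(0.01, 0.99)) {
  if (length(dim(raw)) == 3L)
    raw <- rowMeans(raw[, , 1:min(3, dim(raw)[3]), drop = FALSE], dims = 2)
  stopifnot(is.matrix(raw), nrow(raw) > 0, ncol(raw) > 0)
  if (any(raw < 0) || any(raw > 255)) stop("intensities must lie in [0, 255]")
  x <- if (invert) 255 - raw else raw
  q <- quantile(x, probs, names = FALSE)
  if (diff(q) <= 0) {
    warning("constant image: normalization degenerates to mid-grey")
    return(matrix(128, nrow(raw), ncol(raw)))
  }
  round(pmin(pmax((x - q[1]) / (q[2] - q[1]) * 255, 0), 255))
}

# Canny edge map: Gaussian smooth, Sobel gradients, non-maximum suppression
# along the quantized gradient direction, then percentile hysteresis
# thresholding (weak edges kept only when 8-connected to a strong edge).
canny_edges <- function(img, sigma = 2, lo_q = 0.70, hi_q = 0.90) {
  sm <- EBImage::gblur(img / 255, sigma)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)   # gradient along cols (x)
  gx <- EBImage::filter2(sm, kx)
  gy <- EBImage::filter2(sm, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  H <- nrow(img); W <- ncol(img)
  # quantize direction into 4 bins: 0 = horizontal gradient (compare left/
  # right neighbours), 1 = 45 deg, 2 = vertical, 3 = 135 deg
  ang <- atan2(gy, gx) %% pi
  bin <- as.integer(round(ang / (pi / 4))) %% 4L
  shift <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr); cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  nbr <- list(`0` = list(c(0, 1), c(0, -1)),  `1` = list(c(1, 1), c(-1, -1)),
              `2` = list(c(1, 0), c(-1, 0)),  `3` = list(c(1, -1), c(-1, 1)))
  keep <- matrix(FALSE, H, W)
  for (b in 0:3) {
    n1 <- nbr[[b + 1]][[1]]; n2 <- nbr[[b + 1]][[2]]
    ge <- mag >= shift(mag, n1[1], n1[2]) & mag >= shift(mag, n2[1], n2[2])
    keep <- keep | (bin == b & ge)
  }
  # relative floor: FFT-based filtering leaves ~1e-16 ripples everywhere,
  # which must not enter the percentile thresholds
  floor_v <- max(mag) * 1e-3
  cand <- keep & mag > floor_v
  if (!any(cand)) return(matrix(FALSE, H, W))
  qs <- quantile(mag[mag > floor_v], c(lo_q, hi_q), names = FALSE)
  weak <- cand & mag >= qs[1]
  strong <- cand & mag >= qs[2]
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  keep_labels <- unique(lab[strong])
  weak & matrix(lab %in% keep_labels, H, W)
}

#' Fitted well boundary
#'
#' @param center numeric (x, y) in pixels.
#' @param radius circle radius in pixels (> 0).
#' @param fit_quality fraction in \[0, 1\] of the fitted boundary arc
#'   supported by edge pixels (1 = the whole circle lies on edges).
#' @param fallback logical; TRUE when this boundary is the detection-failure
#'   fallback rather than a fit.
#' @return an object of class `well_boundary`.
#' @export
well_boundary <- function(center, radius, fit_quality = NA_real_,
                          fallback = FALSE) {
  stopifnot(is.numeric(center), length(center) == 2L, radius > 0,
            is.na(fit_quality) || (fit_quality >= 0 && fit_quality <= 1))
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 fit_quality = fit_quality, fallback = fallback),
            class = "well_boundary")
}

#' @export
print.well_boundary <- function(x, ...) {
  cat(sprintf("<well_boundary> center (%.1f, %.1f), radius %.1f, quality %s%s\n",
              x$center[1], x$center[2], x$radius,
              ifelse(is.na(x$fit_quality), "NA", sprintf("%.2f", x$fit_quality)),
              if (isTRUE(x$fallback)) " [fallback]" else ""))
  invisible(x)
}

#' Detect the circular well boundary in a preprocessed image
#'
#' Computes a Canny edge map (Gaussian smoothing sigma 2, hysteresis
#' thresholds at the 70th/90th percentile of edge-candidate gradient
#' magnitude) and fits a circle to the edge pixels by seeded RANSAC:
#' triplets of edge points propose circles, proposals are restricted to radii
#' within +/-15% of `est_diameter / 2`, the proposal with most edge inliers
#' (within 3 px) wins and is refined by an algebraic least-squares fit on its
#' inliers. Fit quality is the fraction of the fitted circle's arc supported
#' by a nearby edge pixel.
#'
#' @param img preprocessed grayscale matrix (see [preprocess()]).
#' @param est_diameter estimated well diameter in pixels, in
#'   `(0, min(dim(img))]`.
#' @param radius_tol fractional radius search band around `est_diameter / 2`.
#' @param n_iter RANSAC iterations (default 500).
#' @param inlier_tol inlier distance tolerance in px (default 3).
#' @param min_quality detection fails below this arc coverage (default 0.5).
#' @param sigma,lo_q,hi_q Canny parameters.
#' @param seed RANSAC seed (deterministic; session RNG is untouched).
#' @return a [well_boundary()]. On failure, an error of class
#'   `eggquant_detection_failure` is thrown whose `boundary` field carries
#'   the fallback: image center, radius `est_diameter / 2`, quality as
#'   measured, `fallback = TRUE`.
#' @export
detect_well <- function(img, est_diameter, radius_tol = 0.15, n_iter = 500L,
                        inlier_tol = 3, min_quality = 0.5, sigma = 2,
                        lo_q = 0.70, hi_q = 0.90, seed = 1L) {
  stopifnot(is.matrix(img), est_diameter > 0,
            est_diameter <= min(dim(img)))
  H <- nrow(img); W <- ncol(img)
  fallback <- well_boundary(c(W / 2, H / 2), est_diameter / 2,
                            fit_quality = 0, fallback = TRUE)
  fail <- function(msg, fb) {
    cond <- structure(class = c("eggquant_detection_failure", "error",
                                "condition"),
                      list(message = msg, call = sys.call(-1), boundary = fb))
    stop(cond)
  }
  edges <- canny_edges(img, sigma, lo_q, hi_q)
  pts <- which(edges, arr.ind = TRUE)            # (row = y, col = x)
  if (nrow(pts) < 3) fail("well detection failed: no edges found", fallback)
  x <- pts[, 2]; y <- pts[, 1]
  r_est <- est_diameter / 2
  r_lo <- r_est * (1 - radius_tol); r_hi <- r_est * (1 + radius_tol)
  best <- NULL; best_inl <- -1L
  with_local_seed(seed, {
    n <- length(x)
    for (it in seq_len(n_iter)) {
      i <- sample.int(n, 3L)
      x1 <- x[i[1]]; y1 <- y[i[1]]; x2 <- x[i[2]]; y2 <- y[i[2]]
      x3 <- x[i[3]]; y3 <- y[i[3]]
      d <- 2 * (x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))
      if (abs(d) < 1e-9) next
      s1 <- x1^2 + y1^2; s2 <- x2^2 + y2^2; s3 <- x3^2 + y3^2
      cx <- (s1 * (y2 - y3) + s2 * (y3 - y1) + s3 * (y1 - y2)) / d
      cy <- (s1 * (x3 - x2) + s2 * (x1 - x3) + s3 * (x2 - x1)) / d
      r <- sqrt((x1 - cx)^2 + (y1 - cy)^2)
      if (r < r_lo || r > r_hi) next
      inl <- sum(abs(sqrt((x - cx)^2 + (y - cy)^2) - r) <= inlier_tol)
      if (inl > best_inl) {
        best_inl <- inl; best <- c(cx, cy, r)
      }
    }
  })
  if (is.null(best))
    fail("well detection failed: no circle candidate in the radius band",
         fallback)
  # refine: iterated algebraic (Kasa) least-squares fits with a band wide
  # enough to span both Canny edges of the wall (inner and outer), so the
  # fitted radius lands on the wall centerline rather than one edge
  for (tol in c(inlier_tol + 2, inlier_tol + 2)) {
    din <- abs(sqrt((x - best[1])^2 + (y - best[2])^2) - best[3]) <= tol
    if (sum(din) < 10) break
    xi <- x[din]; yi <- y[din]
    A <- cbind(2 * xi, 2 * yi, 1)
    sol <- tryCatch(qr.solve(A, xi^2 + yi^2), error = function(e) NULL)
    if (is.null(sol)) break
    r_ref <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
    if (r_ref < r_lo || r_ref > r_hi) break
    best <- c(sol[1], sol[2], r_ref)
  }
  # arc coverage: fraction of circle samples with an edge pixel within tol
  dil <- EBImage::dilate(edges * 1,
                         EBImage::makeBrush(2L * ceiling(inlier_tol) + 1L,
                                            "disc")) > 0
  th <- seq(0, 2 * pi, length.out = 361L)[-361L]
  sx <- round(best[1] + best[3] * cos(th)); sy <- round(best[2] + best[3] * sin(th))
  ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  coverage <- if (!any(ok)) 0 else sum(dil[cbind(sy[ok], sx[ok])]) / length(th)
  b <- well_boundary(best[1:2], best[3], fit_quality = coverage)
  if (coverage < min_quality) {
    fallback$fit_quality <- coverage
    fail(sprintf("well detection failed: arc coverage %.2f < %.2f",
                 coverage, min_quality), fallback)
  }
  b
}

#' Propagate a boundary across a registered plate
#'
#' The scanning camera positions every well at the same image location, so
#' the boundary fitted on the first image is reused for all images of the
#' plate.
#'
#' @param boundary a [well_boundary()] from [detect_well()] on the plate's
#'   first image.
#' @param n_images number of images on the plate.
#' @return list of `n_images` references to `boundary`.
#' @export
propagate_boundary <- function(boundary, n_images) {
  stopifnot(inherits(boundary, "well_boundary"), n_images >= 1)
  rep(list(boundary), n_images)
}

#' Is a point inside the (eroded) well boundary?
#'
#' The counting mask is the fitted circle eroded by `erode_px` (default 2) so
#' wall pixels and wall reflections fall outside it.
#'
#' @param boundary a [well_boundary()].
#' @param x,y point coordinates (vectorized).
#' @param erode_px mask erosion in pixels.
#' @return logical vector.
#' @export
inside_boundary <- function(boundary, x, y, erode_px = 2) {
  stopifnot(inherits(boundary, "well_boundary"))
  sqrt((x - boundary$center[1])^2 + (y - boundary$center[2])^2) <=
    boundary$radius - erode_px
}

#' Boundary sidecar I/O
#'
#' Serializes a boundary to a small CSV (`center_x`, `center_y`, `radius`,
#' `fit_quality`, `fallback`) or JSON sidecar next to the images.
#'
#' @param boundary a [well_boundary()].
#' @param path output path (.csv or .json).
#' @return `write_boundary` returns `path` invisibly; `read_boundary` returns
#'   a [well_boundary()].
#' @export
write_boundary <- function(boundary, path) {
  stopifnot(inherits(boundary, "well_boundary"))
  rec <- list(center_x = boundary$center[1], center_y = boundary$center[2],
              radius = boundary$radius, fit_quality = boundary$fit_quality,
              fallback = boundary$fallback)
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  else write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundary
#' @export
read_boundary <- function(path) {
  rec <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else as.list(read.csv(path))
  well_boundary(c(rec$center_x, rec$center_y), rec$radius,
                rec$fit_quality, isTRUE(as.logical(rec$fallback)))
}
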