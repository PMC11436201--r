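#' Specification of one synthetic egg
#'
#' An egg is modelled as a filled ellipse: fly eggs imaged from above under
#' transmitted light are smooth ovoids roughly twice as long as wide, darker
#' than the surrounding media.
#'
#' @param center numeric (x, y) pixel coordinates of the ellipse center.
#' @param semi_axes numeric (a, b), semi-axes in pixels, both > 0.
#' @param orientation rotation in radians (major axis from the +x axis).
#' @param intensity grey level 0-255 of the egg body.
#' @return an object of class `egg_spec`.
#' @export
egg_spec <- function(center, semi_axes, orientation = 0, intensity = 70) {
  stopifnot(is.numeric(center), length(center) == 2L,
            is.numeric(semi_axes), length(semi_axes) == 2L,
            all(semi_axes > 0), intensity >= 0, intensity <= 255)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 orientation = as.numeric(orientation),
                 intensity = as.numeric(intensity)),
            class = "egg_spec")
}

#' Specification of one synthetic well image
#'
#' Describes everything needed to render a per-well image deterministically:
#' geometry of the well, planted eggs (which become ground truth), wall
#' reflection artifacts (rendered like eggs but outside the well wall, and
#' excluded from ground truth), and an additive Gaussian noise level.
#'
#' Validation enforces the geometry the ground truth relies on: every egg
#' must lie entirely inside the well radius and every reflection center must
#' lie outside it.
#'
#' @param width,height image size in pixels (default 600 x 600).
#' @param well_center numeric (x, y); defaults to the image center.
#' @param well_radius well radius in pixels (default 260).
#' @param background background (media) grey level (default 200).
#' @param eggs list of [egg_spec()] inside the well.
#' @param reflections list of [egg_spec()] outside the well radius.
#' @param noise_sigma additive Gaussian noise sd in grey levels (default 0).
#' @param wall_width,wall_intensity width (px) and grey level of the dark
#'   well-wall annulus.
#' @param seed integer seed that fully determines the rendered image.
#' @return an object of class `synthetic_well_spec`.
#' @export
synthetic_well_spec <- function(width = 600L, height = 600L,
                                well_center = c(width / 2, height / 2),
                                well_radius = 260, background = 200,
                                eggs = list(), reflections = list(),
                                noise_sigma = 0, wall_width = 4,
                                wall_intensity = 30, seed = 1L) {
  stopifnot(width >= 8, height >= 8, well_radius > 0,
            background >= 0, background <= 255, noise_sigma >= 0)
  for (e in eggs) {
    stopifnot(inherits(e, "egg_spec"))
    d <- sqrt(sum((e$center - well_center)^2))
    if (d + max(e$semi_axes) > well_radius)
      stop("egg at (", e$center[1], ", ", e$center[2],
           ") extends outside the well radius")
  }
  for (e in reflections) {
    stopifnot(inherits(e, "egg_spec"))
    d <- sqrt(sum((e$center - well_center)^2))
    if (d <= well_radius)
      stop("reflection center at (", e$center[1], ", ", e$center[2],
           ") lies inside the well radius")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 well_center = as.numeric(well_center),
                 well_radius = well_radius, background = background,
                 eggs = eggs, reflections = reflections,
                 noise_sigma = noise_sigma, wall_width = wall_width,
                 wall_intensity = wall_intensity, seed = as.integer(seed)),
            class = "synthetic_well_spec")
}

# pixel indices (matrix row/col) covered by an ellipse; pixel (r, c) has
# center (x = c, y = r)
rasterize_ellipse <- function(e, width, height) {
  a <- e$semi_axes[1]; b <- e$semi_axes[2]
  ext <- max(a, b)
  cx <- e$center[1]; cy <- e$center[2]
  cs <- max(1L, floor(cx - ext)):min(width, ceiling(cx + ext))
  rs <- max(1L, floor(cy - ext)):min(height, ceiling(cy + ext))
  if (!length(cs) || !length(rs)) return(matrix(integer(0), ncol = 2))
  g <- expand.grid(r = rs, c = cs)
  dx <- g$c - cx; dy <- g$r - cy
  ct <- cos(e$orientation); st <- sin(e$orientation)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  inside <- u * u + v * v <= 1
  cbind(r = g$r[inside], c = g$c[inside])
}

#' Render one synthetic well image with exact ground truth
#'
#' Draws the background, the dark well-wall annulus, each reflection, and
#' each egg (in list order; a later egg overwrites shared pixels in the label
#' mask), then adds seeded Gaussian noise clipped to \[0, 255\] and rounds to
#' integer grey levels. Output is fully determined by the spec, including its
#' seed.
#'
#' @param spec a [synthetic_well_spec()].
#' @return list with elements:
#'   \describe{
#'     \item{image}{numeric `height x width` matrix, integer grey levels
#'       0-255 (raw camera polarity: eggs darker than media);}
#'     \item{truth}{list with `count`, `label_mask` (integer matrix, 0 =
#'       background, k = k-th egg), `areas` (full rasterized area of each
#'       planted ellipse, px^2) and `centroids` (data.frame x, y).}
#'   }
#' @export
render_well <- function(spec) {
  stopifnot(inherits(spec, "synthetic_well_spec"))
  H <- spec$height; W <- spec$width
  img <- matrix(spec$background, nrow = H, ncol = W)
  # wall annulus
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  d <- sqrt((g$c - spec$well_center[1])^2 + (g$r - spec$well_center[2])^2)
  wall <- abs(d - spec$well_radius) <= spec$wall_width / 2
  img[cbind(g$r[wall], g$c[wall])] <- spec$wall_intensity
  mask <- matrix(0L, nrow = H, ncol = W)
  for (e in spec$reflections) {
    px <- rasterize_ellipse(e, W, H)
    if (nrow(px)) img[px] <- e$intensity
  }
  areas <- numeric(length(spec$eggs))
  cx <- cy <- numeric(length(spec$eggs))
  for (k in seq_along(spec$eggs)) {
    e <- spec$eggs[[k]]
    px <- rasterize_ellipse(e, W, H)
    areas[k] <- nrow(px)
    cx[k] <- e$center[1]; cy[k] <- e$center[2]
    if (nrow(px)) {
      img[px] <- e$intensity
      mask[px] <- k
    }
  }
  if (spec$noise_sigma > 0) {
    noise <- with_local_seed(spec$seed,
                             matrix(rnorm(H * W, 0, spec$noise_sigma), H, W))
    img <- img + noise
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img,
       truth = list(count = length(spec$eggs), label_mask = mask,
                    areas = areas,
                    centroids = data.frame(x = cx, y = cy)))
}

#' Randomly populate a well spec with eggs (and optional reflections)
#'
#' Places `n_eggs` ellipses uniformly inside the well by rejection sampling.
#' Semi-axes are drawn so rasterized areas fall in `area_range` (default
#' within the 2500-4000 px^2 egg-size window used by the counting filter)
#' with an egg-like axis ratio of about 2:1. Pairwise mask overlap is capped
#' at `max_iou` (0 = strictly disjoint). Reflections are placed just outside
#' the wall along the image diagonals, where a 600 px frame has room for
#' them.
#'
#' @param n_eggs number of eggs to plant.
#' @param seed integer seed; the spec is reproducible from it.
#' @param n_reflections number of wall-reflection artifacts (default 0).
#' @param area_range target ellipse-area window in px^2.
#' @param max_iou maximum allowed pairwise mask IoU between planted eggs.
#' @param noise_sigma,width,height,well_center,well_radius passed through to
#'   [synthetic_well_spec()].
#' @param max_tries placement attempts per egg before giving up with an error.
#' @return a [synthetic_well_spec()].
#' @export
random_well_spec <- function(n_eggs, seed = 1L, n_reflections = 0L,
                             area_range = c(2600, 3800), max_iou = 0,
                             noise_sigma = 0, width = 600L, height = 600L,
                             well_center = c(width / 2, height / 2),
                             well_radius = 260, max_tries = 400L) {
  stopifnot(n_eggs >= 0, n_reflections >= 0, area_range[1] > 0,
            area_range[2] > area_range[1])
  with_local_seed(seed, {
    draw_shape <- function() {
      area <- runif(1, area_range[1], area_range[2])
      ratio <- runif(1, 1.8, 2.4)          # major:minor, egg-like
      b <- sqrt(area / (pi * ratio))
      list(a = ratio * b, b = b, th = runif(1, 0, pi),
           intensity = runif(1, 55, 90))
    }
    key <- function(px) px[, "r"] * 100000 + px[, "c"]
    placed <- list(); masks <- list()
    for (k in seq_len(n_eggs)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- draw_shape()
        rmax <- well_radius - max(s$a, s$b) - 1
        if (rmax <= 0) stop("egg too large for the well")
        d <- sqrt(runif(1)) * rmax
        ang <- runif(1, 0, 2 * pi)
        e <- egg_spec(well_center + d * c(cos(ang), sin(ang)),
                      c(s$a, s$b), s$th, s$intensity)
        px <- key(rasterize_ellipse(e, width, height))
        clash <- FALSE
        for (m in masks) {
          inter <- length(intersect(px, m))
          if (inter > 0 &&
              inter / (length(px) + length(m) - inter) > max_iou) {
            clash <- TRUE; break
          }
          if (max_iou == 0 && inter > 0) { clash <- TRUE; break }
        }
        if (!clash) {
          placed[[k]] <- e; masks[[k]] <- px; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place egg ", k, " after ", max_tries,
                    " attempts; reduce n_eggs or egg size")
    }
    refl <- list()
    if (n_reflections > 0) {
      diag_angles <- pi / 4 + (0:3) * pi / 2
      for (k in seq_len(n_reflections)) {
        s <- draw_shape()
        ang <- diag_angles[(k - 1L) %% 4L + 1L] + runif(1, -0.2, 0.2)
        d <- well_radius + max(s$a, s$b) + 8
        ctr <- well_center + d * c(cos(ang), sin(ang))
        ext <- max(s$a, s$b)
        ctr <- pmin(pmax(ctr, ext + 1), c(width, height) - ext - 1)
        if (sqrt(sum((ctr - well_center)^2)) <= well_radius)
          stop("no room for reflection ", k, " in this frame")
        refl[[k]] <- egg_spec(ctr, c(s$a, s$b), s$th, s$intensity)
      }
    }
    synthetic_well_spec(width = width, height = height,
                        well_center = well_center, well_radius = well_radius,
                        eggs = placed, reflections = refl,
                        noise_sigma = noise_sigma, seed = seed)
  })
}

#' Render a full plate of synthetic wells
#'
#' Renders one image per well of `grid`, named with the standard
#' `<plate_id>_<label>` scheme in snake-path order, and writes a ground-truth
#' CSV (`label`, `true_count`) beside them. Optionally writes 16-bit label
#' masks.
#'
#' @param grid a [plate_grid()].
#' @param specs list of [synthetic_well_spec()], one per well, in snake order.
#' @param dir output directory (created if needed).
#' @param plate_id plate identifier used in filenames.
#' @param format `"png"` (default) or `"tif"`.
#' @param write_masks also write `<plate_id>_<label>_mask.tif` label masks.
#' @return data.frame with `index`, `label`, `true_count`, `filename`
#'   (also written to `<dir>/<plate_id>_truth.csv`).
#' @export
render_plate <- function(grid, specs, dir, plate_id = "plate01",
                         format = c("png", "tif"), write_masks = FALSE) {
  stopifnot(inherits(grid, "plate_grid"))
  format <- match.arg(format)
  n <- grid$n_rows * grid$n_cols
  if (length(specs) != n)
    stop("need ", n, " well specs for this grid, got ", length(specs))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- snake_path(grid)
  out <- sp[, c("index", "label")]
  out$true_count <- NA_integer_
  out$filename <- well_filename(plate_id, sp$label, ext = format)
  for (i in seq_len(n)) {
    rw <- render_well(specs[[i]])
    out$true_count[i] <- rw$truth$count
    write_gray_image(rw$image, file.path(dir, out$filename[i]))
    if (write_masks)
      write_label_mask(rw$truth$label_mask,
                       file.path(dir, paste0(plate_id, "_", sp$label[i],
                                             "_mask.tif")))
  }
  write.csv(out, file.path(dir, paste0(plate_id, "_truth.csv")),
            row.names = FALSE)
  out
}

#' Grayscale image I/O
#'
#' Images are plain numeric matrices (`height x width`) of integer grey
#' levels 0-255. PNG and TIFF are supported; RGB files are channel-averaged
#' on read.
#'
#' @param img numeric matrix, values 0-255.
#' @param path file path; format chosen from the extension (.png/.tif/.tiff).
#' @return `write_gray_image` returns `path` invisibly; `read_gray_image`
#'   returns a numeric matrix with values in 0-255.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is.matrix(img))
  scaled <- pmin(pmax(img, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(scaled, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(scaled, path,
                                                      bits.per.sample = 8L)
  else stop("unsupported image extension: .", ext)
  invisible(path)
}

#' @rdname write_gray_image
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension: .", ext)
  if (length(dim(arr)) == 3L) arr <- rowMeans(arr[, , 1:min(3, dim(arr)[3]),
                                                  drop = FALSE], dims = 2)
  round(arr * 255)
}

#' Instance label-mask I/O (16-bit TIFF)
#'
#' @param mask integer matrix of instance labels (0 = background).
#' @param path TIFF path.
#' @return `write_label_mask` returns `path` invisibly; `read_label_mask`
#'   returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) <= 65535)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}
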