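#' Detection filter configuration
#'
#' The counting filter excludes segmented objects that are outside the
#' predicted well or whose area falls outside the egg-size window of
#' 2500-4000 px^2 (both bounds inclusive). The inside-well rule defaults to
#' centroid-inside so an egg touching the wall still counts once;
#' `"full-mask"` requires every mask pixel inside.
#'
#' @param area_min,area_max area window in px^2 (`0 < area_min < area_max`).
#' @param require_inside_well apply the inside-well restriction (default
#'   TRUE).
#' @param inside_rule `"centroid"` (default) or `"full-mask"`.
#' @param erode_px erosion of the counting boundary in px (default 2), which
#'   keeps wall pixels and wall reflections outside the mask.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(area_min = 2500, area_max = 4000,
                          require_inside_well = TRUE,
                          inside_rule = c("centroid", "full-mask"),
                          erode_px = 2) {
  stopifnot(area_min > 0, area_max > area_min, erode_px >= 0)
  structure(list(area_min = area_min, area_max = area_max,
                 require_inside_well = isTRUE(require_inside_well),
                 inside_rule = match.arg(inside_rule), erode_px = erode_px),
            class = "filter_config")
}

#' Filter detections by well boundary and area window
#'
#' Keeps the instances whose area lies in `[area_min, area_max]` and (when
#' `require_inside_well`) whose centroid — or full mask, per `inside_rule` —
#' lies inside the boundary eroded by `erode_px`. This is the step that
#' removes wall-reflection artifacts: a reflection sits at or outside the
#' wall, so restricting detections to the fitted boundary excludes it.
#'
#' @param dets a [detection_set()].
#' @param boundary a [well_boundary()] in the same image frame.
#' @param cfg a [filter_config()].
#' @return the filtered [detection_set()].
#' @export
filter_detections <- function(dets, boundary, cfg = filter_config()) {
  stopifnot(inherits(dets, "detection_set"),
            inherits(boundary, "well_boundary"),
            inherits(cfg, "filter_config"))
  H <- dets$dim[1]
  keep <- vapply(dets$instances, function(i) {
    if (i$area < cfg$area_min || i$area > cfg$area_max) return(FALSE)
    if (!cfg$require_inside_well) return(TRUE)
    if (cfg$inside_rule == "centroid") {
      inside_boundary(boundary, i$centroid[1], i$centroid[2], cfg$erode_px)
    } else {
      xs <- (i$mask - 1L) %/% H + 1L
      ys <- (i$mask - 1L) %% H + 1L
      all(inside_boundary(boundary, xs, ys, cfg$erode_px))
    }
  }, logical(1))
  detection_set(dets$instances[keep], dets$dim, dets$provenance)
}

#' Count eggs in one well image
#'
#' Runs the full per-well pipeline: read, [preprocess()], detect the well
#' boundary (unless one is supplied, e.g. propagated from the plate's first
#' image), run the detector backend, apply the counting filter, and return a
#' one-row record. A failed well detection does not abort: the record is
#' flagged `fallback_boundary` and the fallback boundary (image center,
#' radius `est_diameter / 2`) is used.
#'
#' @param image path to a PNG/TIFF well image, or a raw image matrix/array.
#' @param boundary optional [well_boundary()]; when NULL it is detected.
#' @param det_cfg a [detector_config()].
#' @param filt_cfg a [filter_config()].
#' @param est_diameter estimated well diameter in px (required when
#'   `boundary` is NULL).
#' @param backend detector backend name.
#' @param plate_id,well,condition,day metadata carried into the record.
#' @return data.frame with one row: `plate_id`, `well_label`, `condition`,
#'   `day`, `count`, `n_prefilter`, `flags`; the filtered [detection_set()]
#'   and the boundary are attached as attributes `detections` and `boundary`.
#' @export
count_well <- function(image, boundary = NULL, det_cfg = detector_config(),
                       filt_cfg = filter_config(), est_diameter = NULL,
                       backend = "reference", plate_id = NA_character_,
                       well = NA_character_, condition = NA_character_,
                       day = NA_integer_) {
  raw <- if (is.character(image)) {
    if (!file.exists(image)) stop("cannot read image: ", image)
    read_gray_image(image)
  } else image
  img <- preprocess(raw)
  flags <- character(0)
  if (is.null(boundary)) {
    if (is.null(est_diameter))
      stop("est_diameter is required when no boundary is supplied")
    boundary <- tryCatch(detect_well(img, est_diameter),
                         eggquant_detection_failure = function(e) {
                           e$boundary
                         })
    if (isTRUE(boundary$fallback)) flags <- c(flags, "fallback_boundary")
  }
  dets <- run_backend(img, backend, det_cfg)
  filtered <- filter_detections(dets, boundary, filt_cfg)
  rec <- data.frame(plate_id = plate_id, well_label = well,
                    condition = condition, day = day,
                    count = length(filtered), n_prefilter = length(dets),
                    flags = paste(flags, collapse = ";"),
                    stringsAsFactors = FALSE)
  attr(rec, "detections") <- filtered
  attr(rec, "boundary") <- boundary
  rec
}

#' Count eggs across a plate of well images
#'
#' Processes every `<plate_id>_<label>.png/tif` image in `dir` in snake-path
#' order. The well boundary is detected on the first image of the path and
#' propagated to the rest (the scanning camera registers every well at the
#' same image position). Layout metadata (condition, day) is joined from the
#' layout table; wells missing from the layout are flagged
#' `missing_layout` and carry NA metadata.
#'
#' @param dir directory of per-well images.
#' @param layout data.frame or CSV path with columns `plate_id`,
#'   `well_label`, `condition`, `day` (extra columns such as `n_females`,
#'   `n_males` are ignored here).
#' @param est_diameter estimated well diameter in px.
#' @param grid a [plate_grid()] defining the snake order.
#' @param det_cfg,filt_cfg,backend passed to [count_well()].
#' @param overlay_dir optional directory to write overlay images into.
#' @return data.frame of per-well records (see [count_well()]), one row per
#'   image, ordered by snake path.
#' @export
count_plate <- function(dir, layout = NULL, est_diameter,
                        grid = plate_grid(), det_cfg = detector_config(),
                        filt_cfg = filter_config(), backend = "reference",
                        overlay_dir = NULL) {
  files <- list.files(dir, pattern = "_[A-Z][0-9]+\\.(png|tif|tiff)$",
                      full.names = TRUE)
  if (!length(files)) {
    warning("no well images found in ", dir)
    return(data.frame(plate_id = character(0), well_label = character(0),
                      condition = character(0), day = integer(0),
                      count = integer(0), n_prefilter = integer(0),
                      flags = character(0), stringsAsFactors = FALSE))
  }
  info <- parse_well_filename(files)
  info$path <- files
  if (anyDuplicated(paste(info$plate_id, info$label)))
    stop("duplicate well label(s) among image files in ", dir)
  if (is.character(layout)) layout <- read.csv(layout, stringsAsFactors = FALSE)
  sp <- snake_path(grid)
  info <- info[order(match(info$label, sp$label)), , drop = FALSE]
  img1 <- preprocess(read_gray_image(info$path[1]))
  first_fallback <- FALSE
  b <- tryCatch(detect_well(img1, est_diameter),
                eggquant_detection_failure = function(e) e$boundary)
  first_fallback <- isTRUE(b$fallback)
  boundaries <- propagate_boundary(b, nrow(info))
  out <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    rec <- count_well(info$path[i], boundary = boundaries[[i]],
                      det_cfg = det_cfg, filt_cfg = filt_cfg,
                      backend = backend, plate_id = info$plate_id[i],
                      well = info$label[i])
    if (first_fallback)
      rec$flags <- paste(c("fallback_boundary",
                           setdiff(strsplit(rec$flags, ";")[[1]], "")),
                         collapse = ";")
    if (!is.null(layout)) {
      j <- which(layout$plate_id == rec$plate_id &
                   layout$well_label == rec$well_label)
      if (length(j) == 1L) {
        rec$condition <- layout$condition[j]
        rec$day <- layout$day[j]
      } else {
        rec$flags <- paste(c(setdiff(strsplit(rec$flags, ";")[[1]], ""),
                             "missing_layout"), collapse = ";")
      }
    }
    if (!is.null(overlay_dir)) {
      dir.create(overlay_dir, showWarnings = FALSE, recursive = TRUE)
      save_overlay(read_gray_image(info$path[i]), attr(rec, "detections"),
                   boundaries[[i]],
                   file.path(overlay_dir,
                             paste0(info$plate_id[i], "_", info$label[i],
                                    "_overlay.png")))
    }
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  n_flag <- sum(res$flags != "")
  if (n_flag > 0)
    message(n_flag, " of ", nrow(res), " wells flagged (",
            paste(unique(unlist(strsplit(res$flags[res$flags != ""], ";"))),
                  collapse = ", "), ")")
  res
}

#' Counts table I/O
#'
#' Canonical export is CSV with the fixed column order `plate_id`,
#' `well_label`, `condition`, `day`, `count`, `n_prefilter`, `flags`; the
#' reader round-trips it.
#'
#' @param table counts data.frame (from [count_plate()]).
#' @param path CSV path.
#' @return `export_counts` returns `path` invisibly; `read_counts` returns
#'   the data.frame.
#' @export
export_counts <- function(table, path) {
  cols <- c("plate_id", "well_label", "condition", "day", "count",
            "n_prefilter", "flags")
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop("counts table lacks columns: ",
                            paste(missing, collapse = ", "))
  write.csv(table[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname export_counts
#' @export
read_counts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(flags = "character",
                                condition = "character",
                                plate_id = "character",
                                well_label = "character"))
  df$flags[is.na(df$flags)] <- ""
  df$condition[!is.na(df$condition) & df$condition == ""] <- NA_character_
  df
}
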