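#' Plate grid definition
#'
#' Describes a multiwell plate as a rectangular grid. The default is the
#' 48-well culture format (6 rows A-F by 8 columns) used for high-throughput
#' fly fecundity assays.
#'
#' @param n_rows,n_cols positive integers; grid dimensions (default 6 x 8).
#' @param well_diameter optional well diameter, with `unit` giving its unit.
#' @param unit unit tag for `well_diameter`, `"px"` or `"mm"`.
#' @return an object of class `plate_grid`.
#' @examples
#' plate_grid()            # 48-well default
#' plate_grid(2, 3)
#' @export
plate_grid <- function(n_rows = 6L, n_cols = 8L, well_diameter = NULL,
                       unit = c("px", "mm")) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            n_rows >= 1L, n_cols >= 1L)
  if (!is.null(well_diameter)) stopifnot(is.numeric(well_diameter), well_diameter > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 well_diameter = well_diameter, unit = match.arg(unit)),
            class = "plate_grid")
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf("<plate_grid> %d x %d (%d wells)\n", x$n_rows, x$n_cols,
              x$n_rows * x$n_cols))
  if (!is.null(x$well_diameter))
    cat(sprintf("  well diameter: %g %s\n", x$well_diameter, x$unit))
  invisible(x)
}

#' Well labels from 0-based grid indices
#'
#' Labels are row letter plus 1-based column number ("A1" is row 0, col 0).
#' Rows beyond "Z" are not supported (plates larger than 26 rows do not occur
#' in this assay format).
#'
#' @param row,col 0-based integer vectors (recycled).
#' @return character vector of labels.
#' @seealso [parse_well_label()]
#' @export
well_label <- function(row, col) {
  stopifnot(all(row >= 0), all(col >= 0), all(row < 26))
  paste0(LETTERS[row + 1L], col + 1L)
}

#' Parse well labels back to 0-based indices
#'
#' @param label character vector like "A1", "F8".
#' @param grid optional [plate_grid()]; if given, labels outside the grid error.
#' @return data.frame with columns `row`, `col`, `label`.
#' @export
parse_well_label <- function(label, grid = NULL) {
  ok <- grepl("^[A-Z][0-9]+$", label)
  if (!all(ok)) stop("malformed well label(s): ", paste(label[!ok], collapse = ", "))
  row <- match(substr(label, 1L, 1L), LETTERS) - 1L
  col <- as.integer(substring(label, 2L)) - 1L
  if (any(col < 0L)) stop("well column numbers are 1-based; got column 0")
  if (!is.null(grid)) {
    bad <- row >= grid$n_rows | col >= grid$n_cols
    if (any(bad)) stop("label(s) outside grid: ", paste(label[bad], collapse = ", "))
  }
  data.frame(row = row, col = col, label = label, stringsAsFactors = FALSE)
}

#' Snake-path (boustrophedon) traversal of a plate
#'
#' Orders wells the way the scanning camera visits them: row by row, with the
#' traversal direction alternating so consecutive wells are always one grid
#' step apart. By default the path starts at the top-left well (row A read
#' left to right, row B right to left, and so on).
#'
#' @param grid a [plate_grid()].
#' @param start corner where the path starts: `"top-left"` (default),
#'   `"top-right"`, `"bottom-left"`, or `"bottom-right"`.
#' @param fast_axis `"row"` (default; rows are traversed, alternating
#'   direction) or `"col"` (columns are traversed).
#' @return data.frame with columns `index` (1-based visit order), `row`,
#'   `col` (0-based) and `label`; one row per well.
#' @examples
#' snake_path(plate_grid(2, 3))$label  # "A1" "A2" "A3" "B3" "B2" "B1"
#' @export
snake_path <- function(grid, start = c("top-left", "top-right",
                                       "bottom-left", "bottom-right"),
                       fast_axis = c("row", "col")) {
  stopifnot(inherits(grid, "plate_grid"))
  start <- match.arg(start)
  fast_axis <- match.arg(fast_axis)
  if (fast_axis == "row") {
    rows <- 0:(grid$n_rows - 1L)
    path <- do.call(rbind, lapply(rows, function(r) {
      cols <- 0:(grid$n_cols - 1L)
      if (r %% 2L == 1L) cols <- rev(cols)
      data.frame(row = r, col = cols)
    }))
  } else {
    cols <- 0:(grid$n_cols - 1L)
    path <- do.call(rbind, lapply(cols, function(cc) {
      rows <- 0:(grid$n_rows - 1L)
      if (cc %% 2L == 1L) rows <- rev(rows)
      data.frame(row = rows, col = cc)
    }))
  }
  if (start %in% c("top-right", "bottom-right"))
    path$col <- grid$n_cols - 1L - path$col
  if (start %in% c("bottom-left", "bottom-right"))
    path$row <- grid$n_rows - 1L - path$row
  data.frame(index = seq_len(nrow(path)), row = path$row, col = path$col,
             label = well_label(path$row, path$col), stringsAsFactors = FALSE)
}

#' Four-corner camera calibration
#'
#' Stores the planar coordinates of the four corner well centers, as recorded
#' when the camera is registered to the plate by centering a circular target
#' over each corner well.
#'
#' @param top_left,top_right,bottom_left,bottom_right numeric length-2
#'   coordinates (x, y), all in one unit.
#' @return an object of class `corner_calibration`.
#' @export
corner_calibration <- function(top_left, top_right, bottom_left, bottom_right) {
  pts <- list(top_left = top_left, top_right = top_right,
              bottom_left = bottom_left, bottom_right = bottom_right)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || anyNA(p))
      stop("corner '", nm, "' must be a finite numeric (x, y) pair")
    pts[[nm]] <- as.numeric(p)
  }
  m <- do.call(rbind, pts)
  if (anyDuplicated(m)) stop("degenerate calibration: corner points coincide")
  # shoelace area of the quadrilateral TL -> TR -> BR -> BL
  q <- m[c(1, 2, 4, 3), ]
  area <- 0.5 * abs(sum(q[, 1] * q[c(2:4, 1), 2] - q[c(2:4, 1), 1] * q[, 2]))
  if (area <= sqrt(.Machine$double.eps))
    stop("degenerate calibration: corner quadrilateral has zero area")
  structure(pts, class = "corner_calibration")
}

#' Interpolate all well centers from a four-corner calibration
#'
#' Bilinear interpolation over the fractional grid position: well (r, c) maps
#' to fr = r/(n_rows-1), fc = c/(n_cols-1) and its center is the bilinear
#' blend of the four corner points. The four corner wells reproduce the
#' calibration points exactly, and the map commutes with any affine transform
#' of the calibration.
#'
#' @param calib a [corner_calibration()].
#' @param grid a [plate_grid()].
#' @return data.frame with columns `row`, `col`, `label`, `x`, `y`, ordered
#'   row-major.
#' @export
interpolate_well_centers <- function(calib, grid) {
  stopifnot(inherits(calib, "corner_calibration"), inherits(grid, "plate_grid"))
  idx <- expand.grid(col = 0:(grid$n_cols - 1L), row = 0:(grid$n_rows - 1L))
  fr <- if (grid$n_rows > 1L) idx$row / (grid$n_rows - 1L) else rep(0, nrow(idx))
  fc <- if (grid$n_cols > 1L) idx$col / (grid$n_cols - 1L) else rep(0, nrow(idx))
  blend <- function(k) {
    (1 - fr) * (1 - fc) * calib$top_left[k] +
      (1 - fr) * fc * calib$top_right[k] +
      fr * (1 - fc) * calib$bottom_left[k] +
      fr * fc * calib$bottom_right[k]
  }
  data.frame(row = idx$row, col = idx$col,
             label = well_label(idx$row, idx$col),
             x = blend(1L), y = blend(2L), stringsAsFactors = FALSE)
}

#' Read and write corner calibrations as CSV
#'
#' The on-disk format is a three-column CSV (`corner`, `x`, `y`) with corner
#' labels `top_left`, `top_right`, `bottom_left`, `bottom_right`.
#'
#' @param calib a [corner_calibration()].
#' @param path CSV file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a [corner_calibration()].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "corner_calibration"))
  df <- data.frame(corner = names(calib),
                   x = vapply(calib, `[`, numeric(1), 1L),
                   y = vapply(calib, `[`, numeric(1), 2L))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("top_left", "top_right", "bottom_left", "bottom_right")
  if (!all(need %in% df$corner))
    stop("calibration CSV must contain corners: ", paste(need, collapse = ", "))
  g <- function(nm) unlist(df[df$corner == nm, c("x", "y")][1, ], use.names = FALSE)
  corner_calibration(g("top_left"), g("top_right"), g("bottom_left"),
                     g("bottom_right"))
}

#' Export a scan path with interpolated coordinates as CSV
#'
#' Combines [snake_path()] ordering with [interpolate_well_centers()]
#' coordinates into the CSV the acquisition side consumes
#' (`index`, `label`, `x`, `y`).
#'
#' @param grid a [plate_grid()].
#' @param calib a [corner_calibration()].
#' @param path CSV file path.
#' @inheritParams snake_path
#' @return the exported data.frame, invisibly.
#' @export
write_scan_path <- function(grid, calib, path, start = "top-left",
                            fast_axis = "row") {
  sp <- snake_path(grid, start = start, fast_axis = fast_axis)
  centers <- interpolate_well_centers(calib, grid)
  key <- match(sp$label, centers$label)
  out <- data.frame(index = sp$index, label = sp$label,
                    x = centers$x[key], y = centers$y[key])
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Well image filenames
#'
#' Image files are named `<plate_id>_<label>.<ext>` (e.g. `plate01_A1.png`),
#' encoding the plate and well so a directory of per-well images can be
#' mapped back onto the grid.
#'
#' @param plate_id plate identifier (no underscores).
#' @param label well label(s).
#' @param ext file extension, `"png"` or `"tif"`.
#' @return character vector of filenames.
#' @export
well_filename <- function(plate_id, label, ext = "png") {
  stopifnot(!grepl("_", plate_id))
  paste0(plate_id, "_", label, ".", ext)
}

#' @rdname well_filename
#' @param filename filenames (path components are dropped).
#' @return `parse_well_filename` returns a data.frame with `plate_id`,
#'   `label`, `filename`.
#' @export
parse_well_filename <- function(filename) {
  base <- basename(filename)
  stem <- sub("\\.[A-Za-z]+$", "", base)
  ok <- grepl("^[^_]+_[A-Z][0-9]+$", stem)
  if (!all(ok)) stop("unparseable well filename(s): ",
                     paste(base[!ok], collapse = ", "))
  data.frame(plate_id = sub("_[A-Z][0-9]+$", "", stem),
             label = sub("^[^_]+_", "", stem),
             filename = base, stringsAsFactors = FALSE)
}
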