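# 3x5 bitmap digits for the burned-in count caption (no text device needed,
# so overlays render identically on any machine)
.digit_font <- list(
  "0" = c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  "1" = c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  "2" = c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  "3" = c(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
  "4" = c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  "5" = c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  "6" = c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  "7" = c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  "8" = c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  "9" = c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1))

burn_digits <- function(rgb, text, row0 = 10L, col0 = 10L, scale = 4L,
                        color = c(1, 1, 0)) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  for (k in seq_len(nchar(text))) {
    ch <- substr(text, k, k)
    glyph <- .digit_font[[ch]]
    if (is.null(glyph)) next
    g <- matrix(glyph, nrow = 5, ncol = 3, byrow = TRUE)
    for (r in 1:5) for (c in 1:3) {
      if (g[r, c] == 1) {
        rr <- row0 + (r - 1L) * scale + seq_len(scale) - 1L
        cc <- col0 + (k - 1L) * 4L * scale + (c - 1L) * scale +
          seq_len(scale) - 1L
        rr <- rr[rr >= 1 & rr <= H]; cc <- cc[cc >= 1 & cc <= W]
        for (ch3 in 1:3) rgb[rr, cc, ch3] <- color[ch3]
      }
    }
  }
  rgb
}

draw_segments <- function(rgb, x0, y0, x1, y1, color) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  for (s in seq_along(x0)) {
    n <- max(2L, ceiling(max(abs(x1[s] - x0[s]), abs(y1[s] - y0[s]))) + 1L)
    xs <- round(seq(x0[s], x1[s], length.out = n))
    ys <- round(seq(y0[s], y1[s], length.out = n))
    ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
    for (ch in 1:3) {
      m <- rgb[, , ch]
      m[cbind(ys[ok], xs[ok])] <- color[ch]
      rgb[, , ch] <- m
    }
  }
  rgb
}

#' Save an annotated overlay image
#'
#' Writes the raw well image with each kept instance's star-convex polygon
#' outlined in red, the fitted well boundary drawn as a white circle, and the
#' final count burned into the top-left corner in yellow. Purely a side
#' effect: inputs are not modified.
#'
#' @param img raw grayscale matrix (0-255) as read from disk.
#' @param dets the filtered [detection_set()] to outline.
#' @param boundary the [well_boundary()] used for counting.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_overlay <- function(img, dets, boundary, path) {
  stopifnot(is.matrix(img), inherits(dets, "detection_set"),
            inherits(boundary, "well_boundary"))
  g <- pmin(pmax(img, 0), 255) / 255
  rgb <- array(g, dim = c(nrow(img), ncol(img), 3))
  th <- seq(0, 2 * pi, length.out = 721)
  bx <- boundary$center[1] + boundary$radius * cos(th)
  by <- boundary$center[2] + boundary$radius * sin(th)
  rgb <- draw_segments(rgb, head(bx, -1), head(by, -1), tail(bx, -1),
                       tail(by, -1), c(1, 1, 1))
  for (inst in dets$instances) {
    p <- inst$polygon
    nx <- c(p[, 1], p[1, 1]); ny <- c(p[, 2], p[1, 2])
    rgb <- draw_segments(rgb, head(nx, -1), head(ny, -1), tail(nx, -1),
                         tail(ny, -1), c(1, 0, 0))
  }
  rgb <- burn_digits(rgb, as.character(length(dets)))
  png::writePNG(rgb, path)
  invisible(path)
}
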