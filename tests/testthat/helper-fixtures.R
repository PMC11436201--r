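# shared fixture builders: hand-made detection sets, rectangle masks, and
# brute-force oracles kept independent of the package internals they check

# linear indices (H-row image) of an axis-aligned rectangle
rect_mask <- function(H, x0, x1, y0, y1) {
  g <- expand.grid(y = y0:y1, x = x0:x1)
  sort(g$y + (g$x - 1L) * H)
}

make_instance <- function(mask, score = 1, centroid = NULL, H = 100L) {
  xs <- (mask - 1L) %/% H + 1L
  ys <- (mask - 1L) %% H + 1L
  if (is.null(centroid)) centroid <- c(mean(xs), mean(ys))
  list(centroid = centroid,
       polygon = cbind(x = centroid[1], y = centroid[2]),
       mask = mask, area = length(mask), score = score)
}

make_detset <- function(..., H = 100L, W = 100L) {
  detection_set(list(...), dim = c(H, W))
}

# quadratic-time greedy NMS oracle, written directly from the definition
greedy_nms_oracle <- function(dets, thresh) {
  inst <- dets$instances
  if (length(inst) <= 1L) return(seq_along(inst))
  W <- dets$dim[2]
  key <- data.frame(
    score = sapply(inst, `[[`, "score"),
    area = sapply(inst, `[[`, "area"),
    raster = sapply(inst, function(i)
      round(i$centroid[2]) * W + round(i$centroid[1])))
  ord <- order(-key$score, -key$area, key$raster)
  kept <- integer(0)
  for (i in ord) {
    ious <- vapply(kept, function(j) {
      a <- inst[[i]]$mask; b <- inst[[j]]$mask
      inter <- length(intersect(a, b))
      inter / (length(a) + length(b) - inter)
    }, numeric(1))
    if (all(ious <= thresh)) kept <- c(kept, i)
  }
  sort(kept)
}

# brute-force maximum one-to-one matching count over all assignments
# (feasible for <= 6 instances a side)
brute_force_tp <- function(masks_p, masks_g, tau) {
  np <- length(masks_p); ng <- length(masks_g)
  if (np == 0 || ng == 0) return(0L)
  ok <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    a <- masks_p[[i]]; b <- masks_g[[j]]
    inter <- length(intersect(a, b))
    iou <- if (length(a) + length(b) - inter == 0) 0
    else inter / (length(a) + length(b) - inter)
    ok[i, j] <- iou >= tau
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1L) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    recurse(i + 1L, used, count)            # leave pred i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}

# seeded Poisson(10) egg-count draw for per-well fixtures
with_seed_draw <- function(seed, lambda = 10) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rpois(1, lambda)
}

# random blobs (small filled discs) for matching/NMS property tests
random_blob_masks <- function(n, H = 60L, W = 60L, r_range = c(3, 8)) {
  lapply(seq_len(n), function(i) {
    r <- runif(1, r_range[1], r_range[2])
    cx <- runif(1, r + 1, W - r - 1); cy <- runif(1, r + 1, H - r - 1)
    g <- expand.grid(y = 1:H, x = 1:W)
    keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
    sort(g$y[keep] + (g$x[keep] - 1L) * H)
  })
}
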