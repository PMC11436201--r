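#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline — grid, well-detection
#' estimate, detector, counting filter, and statistics options — plus the
#' single root seed, into one serializable object. All randomness in a run
#' flows from `seed` via [derive_seed()].
#'
#' @param seed root seed (default 1).
#' @param est_diameter estimated well diameter in px (default 520).
#' @param grid a [plate_grid()].
#' @param detector a [detector_config()].
#' @param filter a [filter_config()].
#' @param stats list with `welch` (logical) and `alpha`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, est_diameter = 520,
                            grid = plate_grid(),
                            detector = detector_config(),
                            filter = filter_config(),
                            stats = list(welch = TRUE, alpha = 0.05)) {
  stopifnot(inherits(grid, "plate_grid"),
            inherits(detector, "detector_config"),
            inherits(filter, "filter_config"),
            est_diameter > 0, is.list(stats))
  structure(list(seed = as.integer(seed), est_diameter = est_diameter,
                 grid = grid, detector = detector, filter = filter,
                 stats = stats),
            class = "pipeline_config")
}

#' Read and write pipeline configurations (YAML)
#'
#' The on-disk format is plain hierarchical YAML mirroring the
#' [pipeline_config()] structure. Reading validates strictly: unknown keys
#' at any level are rejected.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- list(
    seed = cfg$seed, est_diameter = cfg$est_diameter,
    grid = list(n_rows = cfg$grid$n_rows, n_cols = cfg$grid$n_cols,
                well_diameter = cfg$grid$well_diameter,
                unit = cfg$grid$unit),
    detector = unclass(cfg$detector),
    filter = unclass(cfg$filter),
    stats = cfg$stats)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  allowed <- list(
    top = c("seed", "est_diameter", "grid", "detector", "filter", "stats"),
    grid = c("n_rows", "n_cols", "well_diameter", "unit"),
    detector = c("prob_thresh", "nms_thresh", "n_rays", "smoothing_sigma",
                 "threshold_method", "split", "split_tolerance",
                 "open_radius"),
    filter = c("area_min", "area_max", "require_inside_well", "inside_rule",
               "erode_px"),
    stats = c("welch", "alpha"))
  check <- function(keys, where) {
    unknown <- setdiff(keys, allowed[[where]])
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check(names(lst), "top")
  for (sec in c("grid", "detector", "filter", "stats"))
    if (!is.null(lst[[sec]])) check(names(lst[[sec]]), sec)
  g <- lst$grid
  grid <- plate_grid(n_rows = g$n_rows %||% 6L, n_cols = g$n_cols %||% 8L,
                     well_diameter = g$well_diameter,
                     unit = g$unit %||% "px")
  d <- lst$detector %||% list()
  detector <- do.call(detector_config, d)
  f <- lst$filter %||% list()
  filter <- do.call(filter_config, f)
  pipeline_config(seed = lst$seed %||% 1L,
                  est_diameter = lst$est_diameter %||% 520,
                  grid = grid, detector = detector, filter = filter,
                  stats = lst$stats %||% list(welch = TRUE, alpha = 0.05))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest beside pipeline outputs
#'
#' Records the exact configuration (and its MD5 hash), package and R
#' versions, and a timestamp, so any output directory documents how to
#' reproduce itself.
#'
#' @param dir output directory.
#' @param cfg the [pipeline_config()] used.
#' @param extra optional named list merged into the manifest.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, cfg, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, "config.yaml")
  write_config(cfg, cfg_path)
  manifest <- c(list(
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    package = "eggquant",
    package_version = as.character(utils::packageVersion("eggquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
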