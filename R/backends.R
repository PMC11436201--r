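# Detector backend registry. The reference detector is registered at load;
# an externally trained star-convex model can be plugged in by registering a
# function with the same signature.

.backend_registry <- new.env(parent = emptyenv())

#' Register or list detector backends
#'
#' A backend is a function `function(img, cfg)` taking a preprocessed image
#' matrix and a [detector_config()] and returning a [detection_set()] of
#' final (thresholded, suppressed) instances. The built-in `"reference"`
#' backend runs [detect_candidates()], [apply_score_threshold()] and [nms()].
#'
#' @param name backend name.
#' @param fn backend function `function(img, cfg)`.
#' @return `register_backend` returns `name` invisibly; `list_backends`
#'   returns the registered names.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
list_backends <- function() sort(ls(.backend_registry))

#' Run a detector backend on a preprocessed image
#'
#' @param img preprocessed grayscale matrix.
#' @param backend registered backend name (default `"reference"`).
#' @param cfg a [detector_config()] passed to the backend.
#' @return the backend's [detection_set()], with its provenance set to the
#'   backend name.
#' @export
run_backend <- function(img, backend = "reference", cfg = detector_config()) {
  if (!exists(backend, envir = .backend_registry, inherits = FALSE))
    stop("unknown detector backend '", backend, "'; registered: ",
         paste(list_backends(), collapse = ", "))
  fn <- get(backend, envir = .backend_registry)
  dets <- fn(img, cfg)
  if (!inherits(dets, "detection_set"))
    stop("backend '", backend, "' did not return a detection_set")
  dets$provenance <- backend
  dets
}

reference_backend <- function(img, cfg) {
  nms(apply_score_threshold(detect_candidates(img, cfg), cfg$prob_thresh),
      cfg$nms_thresh)
}

.onLoad <- function(libname, pkgname) {
  register_backend("reference", reference_backend)
}
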