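# normalize predictions/ground truth to a list of pixel-index masks
as_mask_list <- function(x) {
  if (inherits(x, "detection_set"))
    return(lapply(x$instances, `[[`, "mask"))
  if (is.matrix(x)) {
    pos <- x > 0
    return(unname(split(which(pos), x[pos])))
  }
  if (is.list(x)) return(x)
  stop("expected a detection_set, a label-mask matrix, or a list of masks")
}

# maximum-cardinality bipartite matching (Kuhn's augmenting paths) on an
# adjacency list pred -> eligible gt
max_bipartite_match <- function(adj, n_gt) {
  match_gt <- rep(NA_integer_, n_gt)    # gt -> pred
  visited_env <- new.env()
  augment <- function(p) {
    for (g in adj[[p]]) {
      if (!visited_env$v[g]) {
        visited_env$v[g] <- TRUE
        if (is.na(match_gt[g]) || augment(match_gt[g])) {
          match_gt[g] <<- p
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (p in seq_along(adj)) {
    visited_env$v <- rep(FALSE, n_gt)
    augment(p)
  }
  match_gt
}

#' Match predicted instances to ground truth at an IoU threshold
#'
#' Builds the pairwise mask-IoU matrix, forbids pairs below `tau`, and finds
#' a one-to-one matching that maximizes the number of matched pairs
#' (maximum-cardinality bipartite matching; this is the matching convention
#' under which instance-segmentation metrics are reported at a threshold
#' `t`). Matched pairs are tp; unmatched predictions are fp; unmatched
#' ground-truth instances are fn.
#'
#' @param pred,gt predictions and ground truth: a [detection_set()], an
#'   integer label-mask matrix, or a list of pixel-index masks.
#' @param tau IoU threshold in (0, 1].
#' @param method `"optimal"` (default) or `"greedy"` (pairs matched in
#'   decreasing IoU order).
#' @return an object of class `match_result`: list with `tau`, `tp`, `fp`,
#'   `fn`, `n_pred`, `n_gt` and `pairs` (data.frame `pred`, `gt`, `iou`).
#' @export
match_instances <- function(pred, gt, tau = 0.5,
                            method = c("optimal", "greedy")) {
  stopifnot(tau > 0, tau <= 1)
  method <- match.arg(method)
  pm <- as_mask_list(pred); gm <- as_mask_list(gt)
  np <- length(pm); ng <- length(gm)
  iou <- matrix(0, np, ng)
  if (np > 0 && ng > 0)
    for (i in seq_len(np)) for (j in seq_len(ng))
      iou[i, j] <- as.numeric(instance_iou(pm[[i]], gm[[j]]))
  ok <- iou >= tau
  pairs <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  if (any(ok)) {
    if (method == "optimal") {
      adj <- lapply(seq_len(np), function(i) which(ok[i, ]))
      mg <- max_bipartite_match(adj, ng)
      hit <- which(!is.na(mg))
      pairs <- data.frame(pred = mg[hit], gt = hit,
                          iou = iou[cbind(mg[hit], hit)])
    } else {
      cand <- which(ok, arr.ind = TRUE)
      cand <- cand[order(-iou[cand]), , drop = FALSE]
      usedp <- rep(FALSE, np); usedg <- rep(FALSE, ng)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!usedp[i] && !usedg[j]) {
          usedp[i] <- TRUE; usedg[j] <- TRUE
          pairs <- rbind(pairs, data.frame(pred = i, gt = j,
                                           iou = iou[i, j]))
        }
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tau = tau, tp = tp, fp = np - tp, fn = ng - tp,
                 n_pred = np, n_gt = ng, pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tau %.2f: tp %d, fp %d, fn %d\n",
              x$tau, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Instance-detection metrics
#'
#' From matched counts: precision = tp/(tp+fp), recall = tp/(tp+fn),
#' accuracy = tp/(tp+fp+fn). A 0/0 ratio (nothing predicted and nothing to
#' find) is reported as 1 by convention with `degenerate = TRUE`.
#'
#' @param match a `match_result` from [match_instances()], or a list/vector
#'   with named elements `tp`, `fp`, `fn`.
#' @return an object of class `metric_set`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `accuracy`, `degenerate`.
#' @examples
#' m <- metrics(list(tp = 50, fp = 3, fn = 2))
#' round(c(m$precision, m$recall, m$accuracy), 4)  # 0.9434 0.9615 0.9091
#' @export
metrics <- function(match) {
  v <- if (inherits(match, "match_result")) match else as.list(match)
  tp <- v$tp; fp <- v$fp; fn <- v$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  ratio <- function(num, den) if (den == 0) 1 else num / den
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = ratio(tp, tp + fp),
                 recall = ratio(tp, tp + fn),
                 accuracy = ratio(tp, tp + fp + fn),
                 degenerate = degenerate),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  accuracy %.4f%s\n",
              x$precision, x$recall, x$accuracy,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Count-level agreement between automated and manual counts
#'
#' Ordinary least-squares fit (with intercept) of automated counts on manual
#' counts, summarized by the coefficient of determination R^2, plus per-well
#' signed errors (automated - manual).
#'
#' @param automated,manual paired numeric count vectors (>= 3 pairs; manual
#'   counts must have nonzero variance).
#' @return an object of class `count_agreement`: list with `r2`, `slope`,
#'   `intercept`, `errors` and the `pairs` data.frame.
#' @export
count_r2 <- function(automated, manual) {
  stopifnot(length(automated) == length(manual), length(manual) >= 3)
  if (var(manual) == 0) stop("manual counts have zero variance; R^2 undefined")
  fit <- lm(automated ~ manual)
  rss <- sum(fit$residuals^2)
  tss <- sum((automated - mean(automated))^2)
  structure(list(r2 = if (tss == 0) 1 else 1 - rss / tss,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 errors = automated - manual,
                 pairs = data.frame(automated = automated, manual = manual)),
            class = "count_agreement")
}

#' @export
print.count_agreement <- function(x, ...) {
  cat(sprintf("<count_agreement> R^2 = %.4f over %d wells (slope %.3f)\n",
              x$r2, nrow(x$pairs), x$slope))
  invisible(x)
}

#' Evaluate a prediction label mask against a ground-truth label mask
#'
#' Convenience wrapper: reads the two 16-bit label-mask TIFFs (or takes
#' matrices), matches instances at `tau` and returns the metrics together
#' with the match.
#'
#' @param pred_path,gt_path label-mask TIFF paths or integer matrices.
#' @param tau IoU threshold.
#' @return list with elements `match` and `metrics`.
#' @export
evaluate_masks <- function(pred_path, gt_path, tau = 0.5) {
  pred <- if (is.character(pred_path)) read_label_mask(pred_path) else pred_path
  gt <- if (is.character(gt_path)) read_label_mask(gt_path) else gt_path
  m <- match_instances(pred, gt, tau)
  list(match = m, metrics = metrics(m))
}
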