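#' Apply survival-based inclusion rules to egg counts
#'
#' Wells house two females (and one male); fecundity is only interpretable
#' where the females survived. The rules are applied per condition-day
#' group: if fewer than half the group's wells (strictly fewer than
#' `ceiling(n/2)`) still have both females alive, the whole condition-day is
#' excluded; otherwise exactly the wells with both females alive are kept.
#'
#' @param survival data.frame with columns `well_label`, `condition`, `day`,
#'   `n_females_alive` (0-2), and optionally `plate_id`, `n_males_alive`.
#' @param counts counts data.frame (schema of [count_plate()]); every counts
#'   row must have a matching survival row (hard error listing wells
#'   otherwise).
#' @return list with `counts` (the retained rows), `excluded_conditions`
#'   (data.frame `condition`, `day`, `n_wells`, `n_both_alive`) and
#'   `dropped_wells` (well labels dropped from retained groups).
#' @export
apply_inclusion_rules <- function(survival, counts) {
  stopifnot(all(c("well_label", "condition", "day", "n_females_alive") %in%
                  names(survival)))
  if (any(survival$n_females_alive < 0 | survival$n_females_alive > 2))
    stop("n_females_alive must be 0, 1 or 2")
  key_cols <- intersect(c("plate_id", "well_label", "condition", "day"),
                        intersect(names(survival), names(counts)))
  key <- function(df) do.call(paste, c(df[key_cols], sep = "\r"))
  sk <- key(survival); ck <- key(counts)
  miss <- !(ck %in% sk)
  if (any(miss))
    stop("counts rows without survival records: ",
         paste(unique(counts$well_label[miss]), collapse = ", "))
  counts$.females <- survival$n_females_alive[match(ck, sk)]
  grp <- interaction(counts$condition, counts$day, drop = TRUE)
  keep <- logical(nrow(counts))
  excl <- list(); dropped <- character(0)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    both <- counts$.females[rows] == 2
    if (sum(both) < ceiling(length(rows) / 2)) {
      excl[[g]] <- data.frame(condition = counts$condition[rows[1]],
                              day = counts$day[rows[1]],
                              n_wells = length(rows),
                              n_both_alive = sum(both))
    } else {
      keep[rows[both]] <- TRUE
      dropped <- c(dropped, counts$well_label[rows[!both]])
    }
  }
  out <- counts[keep, setdiff(names(counts), ".females"), drop = FALSE]
  rownames(out) <- NULL
  list(counts = out,
       excluded_conditions = if (length(excl)) do.call(rbind, excl)
       else data.frame(condition = character(0), day = integer(0),
                       n_wells = integer(0), n_both_alive = integer(0)),
       dropped_wells = dropped)
}

#' Summarize egg counts per condition-day
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (CV = sd/mean) per condition-day group. CV is NA (flagged) when
#' the group mean is 0.
#'
#' @param counts counts data.frame with `condition`, `day`, `count`.
#' @return data.frame with `condition`, `day`, `n_wells`, `mean`, `sd`,
#'   `cv`, `cv_undefined`.
#' @export
summarize_counts <- function(counts) {
  stopifnot(all(c("condition", "day", "count") %in% names(counts)))
  grp <- interaction(counts$condition, counts$day, drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    x <- counts$count[grp == g]
    i <- which(grp == g)[1]
    m <- mean(x); s <- if (length(x) > 1) sd(x) else NA_real_
    data.frame(condition = counts$condition[i], day = counts$day[i],
               n_wells = length(x), mean = m, sd = s,
               cv = if (m == 0) NA_real_ else s / m,
               cv_undefined = m == 0)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# two-sample t-test robust to zero-variance degenerate groups
safe_t_test <- function(x, y, welch = TRUE) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = NA_real_, p = 0))
  }
  tt <- t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Bonferroni-corrected pairwise t-tests between groups
#'
#' Runs a two-sample t-test (Welch by default; pooled-variance with
#' `welch = FALSE`) for each requested comparison and corrects for the
#' family of `m` comparisons requested in this call:
#' adjusted p = min(1, m * raw p). Significance stars are assigned on the
#' adjusted p at 0.05/0.01/0.001.
#'
#' @param data data.frame of well-level values.
#' @param group_col,value_col column names for group labels and values.
#' @param comparisons two-column matrix/data.frame of group-label pairs, or
#'   NULL for all pairwise comparisons.
#' @param welch use the unequal-variance test (default TRUE).
#' @return data.frame with `group1`, `group2`, `n1`, `n2`, `t`, `df`,
#'   `p_raw`, `p_adj`, `m`, `stars`, `flag`; comparisons involving a group
#'   of fewer than 2 wells are flagged `skipped_small_group` with NA
#'   statistics (they still count toward `m`).
#' @export
pairwise_tests <- function(data, group_col = "condition",
                           value_col = "count", comparisons = NULL,
                           welch = TRUE) {
  g <- as.character(data[[group_col]])
  v <- data[[value_col]]
  if (is.null(comparisons)) {
    lv <- unique(g)
    if (length(lv) < 2) stop("need at least two groups")
    comparisons <- t(combn(lv, 2))
  }
  comparisons <- as.matrix(comparisons)
  m <- nrow(comparisons)
  rows <- lapply(seq_len(m), function(i) {
    g1 <- comparisons[i, 1]; g2 <- comparisons[i, 2]
    x <- v[g == g1]; y <- v[g == g2]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(group1 = g1, group2 = g2, n1 = length(x),
                        n2 = length(y), t = NA_real_, df = NA_real_,
                        p_raw = NA_real_, p_adj = NA_real_, m = m,
                        stars = "", flag = "skipped_small_group"))
    }
    tt <- safe_t_test(x, y, welch)
    p_adj <- min(1, m * tt$p)
    stars <- if (p_adj < 0.001) "***" else if (p_adj < 0.01) "**"
    else if (p_adj < 0.05) "*" else "ns"
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               t = tt$t, df = tt$df, p_raw = tt$p, p_adj = p_adj, m = m,
               stars = stars, flag = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Downsampling power analysis
#'
#' Estimates how many replicate wells are needed to detect a fecundity
#' effect: in each of `n_iter` iterations, `k` wells are drawn without
#' replacement independently from the control and treated groups, a pairwise
#' t-test is run on the subsets, and the p-value recorded. The summary is
#' the fraction of iterations significant at `alpha`.
#'
#' @param control,treated numeric vectors of per-well egg counts.
#' @param k subset size per group (`k <= min(group sizes)`); typical choices
#'   are 4, 8, 16 or 24.
#' @param n_iter number of resampling iterations (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed; one root generator drives the whole run.
#' @param welch use the Welch test (default TRUE).
#' @return an object of class `downsample_result`: list with `k`, `n_iter`,
#'   `alpha`, `seed`, `p_values` (length `n_iter`) and `frac_significant`.
#' @export
downsample_power <- function(control, treated, k, n_iter = 100L,
                             alpha = 0.05, seed = 1L, welch = TRUE) {
  stopifnot(k >= 2, n_iter >= 1)
  if (k > min(length(control), length(treated)))
    stop("k = ", k, " exceeds a group size (",
         length(control), ", ", length(treated), ")")
  p <- with_local_seed(seed, vapply(seq_len(n_iter), function(i) {
    safe_t_test(sample(control, k), sample(treated, k), welch)$p
  }, numeric(1)))
  structure(list(k = k, n_iter = as.integer(n_iter), alpha = alpha,
                 seed = seed, p_values = p,
                 frac_significant = mean(p < alpha)),
            class = "downsample_result")
}

#' @export
print.downsample_result <- function(x, ...) {
  cat(sprintf(
    "<downsample_result> k = %d, %d iterations: %.1f%% significant at %.2g\n",
    x$k, x$n_iter, 100 * x$frac_significant, x$alpha))
  invisible(x)
}

#' Long-format export of downsampling p-values
#'
#' @param results list of [downsample_power()] results (e.g. one per k).
#' @param path CSV path.
#' @return the long data.frame (`k`, `iteration`, `p`), invisibly.
#' @export
export_downsample <- function(results, path) {
  if (inherits(results, "downsample_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(k = r$k, iteration = seq_len(r$n_iter), p = r$p_values)))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Synthetic egg-count model
#'
#' Generative stand-in for well-level fecundity data. Counts are negative
#' binomial by default: interwell variability in these assays is strongly
#' overdispersed relative to Poisson (the default `dispersion` of 2.7
#' reproduces a day-1 coefficient of variation of about 0.63 at a mean of
#' about 36 eggs/well, the variability level of a well-run assay). Each
#' female survives each day independently with probability `survival_p`, so
#' a well has both females alive on day d with probability
#' `survival_p^(2 d)`.
#'
#' @param family `"nbinom"` (default) or `"poisson"`.
#' @param dispersion negative-binomial size parameter (> 0).
#' @param survival_p per-female per-day survival probability in \[0, 1\].
#' @return an object of class `synthetic_count_model`.
#' @export
synthetic_count_model <- function(family = c("nbinom", "poisson"),
                                  dispersion = 2.7, survival_p = 0.98) {
  family <- match.arg(family)
  stopifnot(dispersion > 0, survival_p >= 0, survival_p <= 1)
  structure(list(family = family, dispersion = dispersion,
                 survival_p = survival_p),
            class = "synthetic_count_model")
}

#' Simulate survival and egg-count tables
#'
#' Draws per-well counts and female survival for a design of condition-day
#' groups, in the same CSV schemas the imaging pipeline produces, so the
#' statistics layer can be exercised end to end without images.
#'
#' @param model a [synthetic_count_model()].
#' @param design data.frame with columns `condition`, `day`, `n_wells`,
#'   `mean` (expected eggs/well for that group).
#' @param seed integer seed; tables are reproducible from it.
#' @return list with `counts` (counts schema: `plate_id`, `well_label`,
#'   `condition`, `day`, `count`, `n_prefilter`, `flags`) and `survival`
#'   (`well_label`, `condition`, `day`, `n_females_alive`, `n_males_alive`).
#' @export
simulate_counts <- function(model, design, seed = 1L) {
  stopifnot(inherits(model, "synthetic_count_model"),
            all(c("condition", "day", "n_wells", "mean") %in% names(design)),
            all(design$mean >= 0), all(design$n_wells >= 1))
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      n <- design$n_wells[i]
      mu <- design$mean[i]
      cnt <- if (mu == 0) rep(0L, n)
      else if (model$family == "nbinom")
        rnbinom(n, size = model$dispersion, mu = mu)
      else rpois(n, mu)
      p_day <- model$survival_p ^ design$day[i]
      data.frame(
        plate_id = "sim",
        well_label = sprintf("%s_d%s_w%03d", design$condition[i],
                             design$day[i], seq_len(n)),
        condition = design$condition[i], day = design$day[i],
        count = as.integer(cnt), n_prefilter = as.integer(cnt),
        flags = "",
        n_females_alive = rbinom(n, 2L, p_day),
        n_males_alive = rbinom(n, 1L, p_day),
        stringsAsFactors = FALSE)
    })
    all <- do.call(rbind, rows)
    list(counts = all[, c("plate_id", "well_label", "condition", "day",
                          "count", "n_prefilter", "flags")],
         survival = all[, c("well_label", "condition", "day",
                            "n_females_alive", "n_males_alive")])
  })
}
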