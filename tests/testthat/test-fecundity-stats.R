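make_group <- function(cond, day, n, females = 2L) {
  data.frame(well_label = sprintf("%s_d%d_w%03d", cond, day, seq_len(n)),
             condition = cond, day = day,
             n_females_alive = rep_len(females, n),
             n_males_alive = 1L, stringsAsFactors = FALSE)
}

counts_for <- function(survival, count = 10L) {
  data.frame(well_label = survival$well_label,
             condition = survival$condition, day = survival$day,
             count = rep_len(count, nrow(survival)),
             stringsAsFactors = FALSE)
}

test_that("a condition is excluded when both-alive wells fall below half", {
  surv <- make_group("doseA", 1, 16, females = c(rep(2L, 7), rep(1L, 9)))
  res <- apply_inclusion_rules(surv, counts_for(surv))
  expect_equal(nrow(res$counts), 0L)
  expect_equal(res$excluded_conditions$n_both_alive, 7L)
  expect_equal(res$excluded_conditions$n_wells, 16L)
})

test_that("a retained condition keeps exactly the both-alive wells", {
  surv <- make_group("doseB", 3, 16, females = c(rep(2L, 9), rep(1L, 7)))
  res <- apply_inclusion_rules(surv, counts_for(surv))
  expect_equal(nrow(res$counts), 9L)
  expect_length(res$dropped_wells, 7L)
  expect_equal(nrow(res$excluded_conditions), 0L)
  # all alive -> identity
  surv2 <- make_group("ctrl", 1, 12)
  res2 <- apply_inclusion_rules(surv2, counts_for(surv2))
  expect_equal(res2$counts$well_label, surv2$well_label)
  # idempotence: re-applying to the output changes nothing
  res3 <- apply_inclusion_rules(surv2, res2$counts)
  expect_equal(res3$counts, res2$counts)
})

test_that("counts without survival records are a hard error naming the wells", {
  surv <- make_group("ctrl", 1, 4)
  cnt <- counts_for(surv)
  cnt$well_label[2] <- "orphan_well"
  expect_error(apply_inclusion_rules(surv, cnt), "orphan_well")
})

test_that("condition summaries compute mean, sd and CV as defined", {
  df <- data.frame(condition = "c", day = 1,
                   count = c(10, 10, 10))
  s <- summarize_counts(df)
  expect_equal(s$mean, 10); expect_equal(s$cv, 0)
  df2 <- data.frame(condition = "c", day = 1, count = c(2, 4, 6))
  s2 <- summarize_counts(df2)
  expect_equal(c(s2$mean, s2$sd, s2$cv), c(4, 2, 0.5))
  z <- summarize_counts(data.frame(condition = "z", day = 1,
                                   count = c(0, 0)))
  expect_true(z$cv_undefined)
  expect_true(is.na(z$cv))
})

test_that("large negative-binomial samples recover the simulated mean", {
  model <- synthetic_count_model(dispersion = 5)
  design <- data.frame(condition = "c", day = 1, n_wells = 5000, mean = 36)
  sim <- simulate_counts(model, design, seed = 4)
  s <- summarize_counts(sim$counts)
  expect_lt(abs(s$mean - 36) / 36, 0.02)
  # overdispersion shows: CV well above the Poisson CV of 1/6
  expect_gt(s$cv, 0.3)
})

test_that("pairwise tests follow the Bonferroni contract", {
  df <- data.frame(condition = rep(c("a", "b"), each = 6),
                   count = rep(5, 12))
  res <- pairwise_tests(df)
  expect_equal(res$t, 0); expect_equal(res$p_raw, 1); expect_equal(res$p_adj, 1)
  # adjusted p is m * raw, capped at 1, and never below raw
  set.seed(12)
  df2 <- data.frame(condition = rep(c("a", "b", "c", "d"), each = 20),
                    count = c(rnorm(20, 30, 8), rnorm(20, 28, 8),
                              rnorm(20, 26, 8), rnorm(20, 10, 8)))
  res2 <- pairwise_tests(df2)
  expect_equal(res2$m, rep(6L, 6))
  expect_equal(res2$p_adj, pmin(1, 6 * res2$p_raw))
  expect_true(all(res2$p_adj >= res2$p_raw))
  # restricting the family reduces the correction
  res3 <- pairwise_tests(df2, comparisons = cbind("a", c("b", "c", "d")))
  expect_equal(res3$m, rep(3L, 3))
})

test_that("a strong effect at n = 60 is detected below adjusted 0.001", {
  set.seed(31)
  df <- data.frame(condition = rep(c("d1", "d7"), each = 60),
                   count = c(rnorm(60, 35, 15), rnorm(60, 20, 15)))
  res <- pairwise_tests(df)
  expect_lt(res$p_adj, 0.001)
  expect_equal(res$stars, "***")
})

test_that("undersized groups are skipped with a flag but count toward the family", {
  df <- data.frame(condition = c(rep("a", 5), "b", rep("c", 5)),
                   count = c(rnorm(5, 10), 4, rnorm(5, 12)))
  res <- pairwise_tests(df)
  skipped <- res[res$flag == "skipped_small_group", ]
  expect_equal(nrow(skipped), 2L)
  expect_true(all(is.na(skipped$p_adj)))
  expect_equal(unique(res$m), 3L)
})

test_that("downsampling identical constant groups never reaches significance", {
  r <- downsample_power(rep(20, 30), rep(20, 30), k = 8, n_iter = 50,
                        seed = 2)
  expect_true(all(r$p_values == 1))
  expect_equal(r$frac_significant, 0)
  expect_length(r$p_values, 50L)
})

test_that("downsampling is reproducible from its seed and validates k", {
  x <- rnbinom(40, size = 3, mu = 30); y <- rnbinom(40, size = 3, mu = 15)
  r1 <- downsample_power(x, y, k = 16, n_iter = 30, seed = 9)
  r2 <- downsample_power(x, y, k = 16, n_iter = 30, seed = 9)
  expect_identical(r1$p_values, r2$p_values)
  expect_error(downsample_power(x, y, k = 41), "exceeds")
})

test_that("a large separation yields near-total power at k = 8", {
  set.seed(6)
  ctrl <- rnorm(60, 36, 5); trt <- rnorm(60, 2, 5)
  r <- downsample_power(ctrl, trt, k = 8, n_iter = 200, seed = 3)
  expect_gte(r$frac_significant, 0.95)
})

test_that("downsampling p-vectors export in long format", {
  dir <- withr::local_tempdir()
  x <- rnorm(30, 30, 8); y <- rnorm(30, 20, 8)
  rs <- lapply(c(4, 8), function(k)
    downsample_power(x, y, k, n_iter = 10, seed = k))
  df <- export_downsample(rs, file.path(dir, "ds.csv"))
  expect_equal(nrow(df), 20L)
  expect_equal(unique(df$k), c(4, 8))
  expect_equal(read.csv(file.path(dir, "ds.csv"))$p, df$p)
})

test_that("simulated tables respect survival and zero-mean edge cases", {
  model <- synthetic_count_model(survival_p = 1)
  design <- data.frame(condition = c("c", "t"), day = 1, n_wells = 20,
                       mean = c(30, 0))
  sim <- simulate_counts(model, design, seed = 5)
  expect_true(all(sim$survival$n_females_alive == 2L))
  res <- apply_inclusion_rules(sim$survival, sim$counts)
  expect_equal(nrow(res$counts), 40L)       # no exclusions
  expect_true(all(sim$counts$count[sim$counts$condition == "t"] == 0L))
  # deterministic in the seed
  sim2 <- simulate_counts(model, design, seed = 5)
  expect_identical(sim$counts, sim2$counts)
})

test_that("dose-response ordering is recovered from simulated counts at n = 60", {
  model <- synthetic_count_model()
  design <- data.frame(condition = c("dmso", "low", "mid", "high"),
                       day = 3, n_wells = 60, mean = c(36, 25, 12, 3))
  ok <- 0L
  for (s in 1:100) {
    sim <- simulate_counts(model, design, seed = 10000 + s)
    m <- summarize_counts(sim$counts)
    m <- m[match(design$condition, m$condition), ]
    if (all(diff(m$mean) < 0)) ok <- ok + 1L
  }
  expect_gte(ok, 99L)
})
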