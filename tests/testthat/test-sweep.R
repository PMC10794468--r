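test_that("sweep bookkeeping: rows per cell, schema, aggregate consistency", {
  sw <- run_sweep(cohort_sizes = c(1, 4), conditions = c("cema", "no_nn"),
                  replicates = 3, seed = 1)
  rows <- tidy(sw)
  expect_equal(nrow(rows), 2 * 2 * 3)
  counts <- table(rows$condition, rows$n)
  expect_true(all(counts == 3))
  expect_named(glance(sw),
               c("condition", "n", "mean", "ci_low", "ci_high", "replicates"))
  agg <- merge(glance(sw), aggregate(survival ~ condition + n, rows, mean))
  expect_equal(agg$mean, agg$survival)
  expect_true(all(rows$survival >= 0 & rows$survival <= 1))
})

test_that("zero replicate variance gives a zero-width confidence interval", {
  # every embryo dies under maximal noise with full decrement
  cfg <- sim_config(p_noise = 1, n_dec = 1)
  sw <- run_sweep(cohort_sizes = 4, conditions = "cema", replicates = 3,
                  config = cfg, seed = 2)
  expect_equal(sd(tidy(sw)$survival), 0)
  expect_equal(glance(sw)$ci_high - glance(sw)$ci_low, 0)
})

test_that("rerunning with the same master seed reproduces every row", {
  a <- run_sweep(cohort_sizes = c(1, 9), conditions = "cema",
                 replicates = 3, seed = 7)
  b <- run_sweep(cohort_sizes = c(1, 9), conditions = "cema",
                 replicates = 3, seed = 7)
  expect_identical(tidy(a), tidy(b))
})

test_that("the nn ablation is a no-op for singletons", {
  cema <- simulate_cohort(sim_config(n = 1), seed = 31)
  nonn <- simulate_cohort(sim_config(n = 1, nn_enabled = FALSE), seed = 31)
  expect_identical(cema$embryos, nonn$embryos)
})

test_that("ablation sweep shares the full sweep's schema", {
  ab <- run_ablation_no_nn(cohort_sizes = 4, replicates = 2, seed = 3)
  sw <- run_sweep(cohort_sizes = 4, conditions = "cema", replicates = 2, seed = 3)
  expect_identical(names(tidy(ab)), names(tidy(sw)))
  expect_identical(names(glance(ab)), names(glance(sw)))
  expect_true(all(tidy(ab)$condition == "no_nn"))
})

test_that("noise sweep covers its grid and behaves at the endpoints", {
  ns <- run_noise_sweep(p_values = c(0, 1), n = 4, replicates = 3, seed = 9)
  s <- glance(ns)
  expect_equal(s$p_noise, c(0, 1))
  expect_gt(s$mean[s$p_noise == 0], 0.8) # no noise: near the noise-free rate
  expect_lt(s$mean[s$p_noise == 1], 0.2) # maximal noise in a 2x2
})

test_that("autoplot returns a ggplot for both sweep flavours", {
  sw <- run_sweep(cohort_sizes = 4, conditions = "cema", replicates = 2, seed = 1)
  ns <- run_noise_sweep(p_values = c(0, 0.5), n = 4, replicates = 2, seed = 1)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
  expect_s3_class(ggplot2::autoplot(ns), "ggplot")
})
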