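test_that("noise decrement arithmetic matches the model definition", {
  set.seed(1)
  expect_equal(apply_noise(1, p_noise = 1, n_dec = 0.7), 0.3)
  expect_equal(apply_noise(1, p_noise = 1, n_dec = 0.7,
                           decrement = "multiplicative"), 0.3)
  expect_equal(apply_noise(0, p_noise = 1, n_dec = 0.7), 0) # absorbing at zero
  expect_equal(apply_noise(c(0.4, 0.9), p_noise = 0, n_dec = 0.7), c(0.4, 0.9))
  # below 0.7 the two decrement modes differ
  expect_equal(apply_noise(0.5, p_noise = 1, n_dec = 0.7), 0)
  expect_equal(apply_noise(0.5, p_noise = 1, n_dec = 0.7,
                           decrement = "multiplicative"), 0.15)
})

test_that("health mixing is the normalized weighted average", {
  expect_equal(mix_health(0.3, rep(1, 8), rep(1, 16)), (0.3 + 8 + 4) / 13)
  expect_equal(mix_health(0.3), 0.3) # isolated embryo
  expect_equal(mix_health(0.6, rep(0.6, 5), rep(0.6, 3)), 0.6) # constant field
})

test_that("support integration follows h + h * (1 - h) * S", {
  expect_equal(support_update(0.3, self_signal = 0.3), 0.3 * (1 + 0.7 * 0.3))
  expect_equal(support_update(1, self_signal = 0.2, nb_signal = rep(1, 4)), 1)
  expect_equal(support_update(0.4), 0.4) # no participating senders
  expect_equal(support_update(0.5, self_signal = 0.5, scaling = "unscaled"), 0.75)
})

test_that("rule selection treats the threshold as impaired", {
  expect_equal(select_rule(c(0.5, 0.51, 1), theta = 0.5),
               c("random", "gkl", "gkl"))
})

test_that("the vectorised engine reproduces a per-agent helper loop", {
  cfg <- sim_config(n = 9, p_noise = 1, n_dec = 0.2, theta = 0.05)
  sim <- simulate_cohort(cfg, seed = 99, keep_trajectories = TRUE)
  ref <- reference_health_trajectory(cfg, seed = 99)
  expect_equal(sim$health_trajectories, ref, tolerance = 1e-12)
})

test_that("health stays within [0, 1] for every embryo at every timestep", {
  set.seed(4)
  for (cfg in list(sim_config(n = 16),
                   sim_config(n = 9, decrement = "multiplicative"),
                   sim_config(n = 12, locked_fraction = 0.5),
                   sim_config(n = 9, support_scaling = "unscaled"))) {
    sim <- simulate_cohort(cfg, keep_trajectories = TRUE)
    expect_true(all(sim$health_trajectories >= 0 & sim$health_trajectories <= 1))
  }
})

test_that("locked embryos stay at health one, unexposed, and develop under GKL", {
  sim <- simulate_cohort(sim_config(n = 16, locked_fraction = 0.5), seed = 8)
  d <- tidy(sim)
  expect_equal(sum(d$locked), 8)
  expect_true(all(d$health[d$locked] == 1))
  expect_false(any(d$ever_exposed[d$locked]))
  expect_gt(mean(d$success[d$locked]), 0.5) # near the noise-free rate
})

test_that("without noise the cohort reduces to noise-free GKL development", {
  sim <- simulate_cohort(sim_config(n = 25, p_noise = 0), seed = 12)
  d <- tidy(sim)
  expect_true(all(d$health == 1))
  expect_false(any(d$ever_exposed))
  expect_gt(sim$survival, 0.8)
})

test_that("identical seeds give bit-identical cohort results", {
  cfg <- sim_config(n = 9)
  a <- simulate_cohort(cfg, seed = 5, keep_trajectories = TRUE)
  b <- simulate_cohort(cfg, seed = 5, keep_trajectories = TRUE)
  expect_identical(a$embryos, b$embryos)
  expect_identical(a$health_trajectories, b$health_trajectories)
})

test_that("one-shot exposure without continuous support freezes health", {
  cfg <- sim_config(n = 1, p_noise = 1, exposure = "one_shot",
                    support_scope = "affected_only")
  sim <- simulate_cohort(cfg, seed = 2, keep_trajectories = TRUE)
  expect_equal(unname(sim$health_trajectories[, 1]),
               rep(0.3, cfg$eca$steps))
})

test_that("singleton cohorts at defaults almost never develop", {
  surv <- vapply(1:20, function(s) {
    simulate_cohort(sim_config(n = 1), seed = s)$survival
  }, numeric(1))
  expect_lt(mean(surv), 0.1)
})
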