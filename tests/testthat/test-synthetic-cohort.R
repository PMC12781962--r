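test_that("noiseless parametric shapes have the intended geometry", {
  # no response: flat at baseline
  s0 <- generate_trajectory(
    pattern_params(0, baseline_mfi = 2000),
    noise_cv = 0, seed = 1
  )
  expect_equal(s0$days, 1:50)
  expect_equal(s0$mfi, rep(2000, 50))
  expect_equal(s0$group, 0L)

  # fast modulation: gamma pulse peaking at peak_day with value b + A,
  # checked against the analytic curve evaluated directly here
  p1 <- pattern_params(1,
    baseline_mfi = 1000, peak_amplitude = 6000,
    peak_day = 12, rise_rate = 0.25
  )
  s1 <- generate_trajectory(p1, noise_cv = 0, seed = 1)
  k <- 0.25 * 12
  t <- 1:50
  expect_equal(s1$mfi, 1000 + 6000 * (t / 12)^k * exp(k * (1 - t / 12)))
  expect_equal(which.max(s1$mfi), 12L)
  expect_equal(max(s1$mfi), 7000)
  expect_lt(abs(s1$mfi[50] - 1000), 0.1 * 1000) # resolved by day 50

  # sustained: near-constant high, max/min ratio < 1.2
  s4 <- generate_trajectory(default_pattern_params(4), noise_cv = 0, seed = 1)
  expect_lt(max(s4$mfi) / min(s4$mfi), 1.2)
  expect_gt(min(s4$mfi), 10000)

  # rise to sustained starts low and ends high
  s3 <- generate_trajectory(default_pattern_params(3), noise_cv = 0, seed = 1)
  expect_lt(s3$mfi[1], 0.35 * s3$mfi[50])
  expect_true(all(diff(s3$mfi) > 0))
})

test_that("default scales are anchored to the reference group means", {
  anchors <- reference_group_mfi()
  for (g in 0:4) {
    s <- generate_trajectory(default_pattern_params(g), noise_cv = 0, seed = 1)
    expect_equal(mean(s$mfi), unname(anchors[as.character(g)]),
      tolerance = 1e-8
    )
  }
})

test_that("invalid pattern parameters are rejected with explicit messages", {
  expect_error(pattern_params(5), "pattern id")
  expect_error(pattern_params(1, peak_day = 60), "peak_day")
  expect_error(pattern_params(1, peak_day = 0), "peak_day")
  expect_error(pattern_params(1, rise_rate = 0), "rise_rate")
  expect_error(pattern_params(0, peak_amplitude = 5000), "no response")
  expect_error(
    pattern_params(3, baseline_mfi = 20000, plateau_level = 10000),
    "starts low"
  )
  expect_error(
    pattern_params(4, baseline_mfi = 5000, plateau_level = 10000),
    "starts high"
  )
  expect_error(
    generate_trajectory(default_pattern_params(1), noise_cv = -0.1),
    "noise_cv"
  )
})

test_that("trajectory noise is multiplicative, positive and seeded", {
  p <- default_pattern_params(2)
  a <- generate_trajectory(p, noise_cv = 0.3, seed = 5)
  b <- generate_trajectory(p, noise_cv = 0.3, seed = 5)
  c <- generate_trajectory(p, noise_cv = 0.3, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$mfi, c$mfi))
  expect_true(all(a$mfi > 0))
  # unit-mean noise: large-sample average stays near the noiseless curve
  curve <- generate_trajectory(p, noise_cv = 0, seed = 1)$mfi
  reps <- vapply(
    1:400,
    function(s) generate_trajectory(p, noise_cv = 0.3, seed = s)$mfi,
    numeric(50)
  )
  expect_equal(rowMeans(reps) / curve, rep(1, 50), tolerance = 0.05)
})

test_that("cohorts are reproducible and sized per group", {
  cfg <- cohort_config(n_per_group = 3, noise_cv = 0.15, groups = 1:4, seed = 9)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1, coh2)
  labels <- vapply(coh1, `[[`, integer(1), "group")
  expect_equal(unname(table(labels)), rep(3L, 4), ignore_attr = TRUE)
  expect_error(cohort_config(n_per_group = 0, seed = 1), "positive")
  expect_error(cohort_config(n_per_group = 2), "seed")
})

test_that("noiseless trajectories sit closest to their own centroid", {
  coh <- noiseless_cohort(n_per_group = 2)
  cen <- compute_centroids(coh)
  for (s in coh) {
    d <- vapply(cen, function(cc) dtw_distance(s$mfi, cc$mfi)$distance,
      numeric(1)
    )
    expect_equal(names(which.min(d)), as.character(s$group))
    expect_true(all(d[names(d) != as.character(s$group)] > d[[as.character(s$group)]]))
  }
})

test_that("band mixing reproduces the configured pattern frequencies", {
  cfg <- cohort_config(
    mfi_band_mixing = default_band_mixing(), n_total = 10000,
    noise_cv = 0, seed = 31
  )
  coh <- generate_cohort(cfg)
  bands <- vapply(coh, attr, character(1), "band")
  groups <- vapply(coh, `[[`, integer(1), "group")
  in_band <- groups[bands == "<2500"]
  n <- length(in_band)
  expected <- default_band_mixing()["<2500", ] # 64,24,21,2,3 out of 114
  emp <- as.numeric(table(factor(in_band, levels = 0:4))) / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(emp - expected) <= 3.5 * pmax(se, 1e-4)))
  # and the configured row matches the published percentages once rounded
  expect_equal(unname(floor(expected * 100 + 0.5)), c(56, 21, 18, 2, 3))
})

test_that("mixing tables are validated", {
  bad <- default_band_mixing()
  bad[1, 1] <- bad[1, 1] + 0.2
  expect_error(
    cohort_config(mfi_band_mixing = bad, n_total = 10, seed = 1),
    "sum to 1"
  )
  expect_error(
    cohort_config(mfi_band_mixing = default_band_mixing(), seed = 1),
    "n_total"
  )
  # percentage-style rows are accepted and renormalised
  pct <- default_band_mixing() * 100
  attr(pct, "bounds") <- attr(default_band_mixing(), "bounds")
  cfg <- cohort_config(mfi_band_mixing = pct, n_total = 5, seed = 1)
  expect_equal(rowSums(cfg$mfi_band_mixing), rep(1, 4), ignore_attr = TRUE)
})

test_that("sampling schedules subset trajectories without changing values", {
  s <- generate_trajectory(default_pattern_params(2), noise_cv = 0.2, seed = 3)
  expect_identical(apply_sampling_schedule(s, 1:50), s)
  sub <- apply_sampling_schedule(s, c(1, 10, 26, 34))
  expect_equal(sub$days, c(1L, 10L, 26L, 34L))
  expect_equal(sub$mfi, s$mfi[c(1, 10, 26, 34)])
  expect_error(apply_sampling_schedule(s, integer(0)), "non-empty")
  expect_error(apply_sampling_schedule(s, 0), "1-based")
  # config-level schedules must anchor both endpoints
  expect_error(
    cohort_config(n_per_group = 2, sampling_schedule = c(1, 10), seed = 1),
    "days 1 and 50"
  )
  sched <- default_sampling_schedule()
  expect_true(all(c(1L, 50L) %in% sched))
  expect_true(all(sched %in% 1:50))
})
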