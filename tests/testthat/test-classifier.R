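test_that("centroids are per-day arithmetic means of their group", {
  two_equal <- list(
    flat_series("a", 1, 100), flat_series("b", 1, 100),
    flat_series("c", 2, 50), flat_series("d", 2, 300)
  )
  cen <- compute_centroids(two_equal)
  expect_equal(names(cen), c("1", "2"))
  expect_equal(cen[["1"]]$mfi, rep(100, 50)) # mean of equals
  expect_equal(cen[["2"]]$mfi, rep(175, 50)) # arithmetic mean
  # singleton group: centroid equals the single member
  single <- compute_centroids(list(flat_series("e", 3, 42)))
  expect_equal(single[["3"]]$mfi, rep(42, 50))

  expect_error(
    compute_centroids(list(flat_series("a", NA, 1))),
    "group label"
  )
  sparse <- trajectory_series("p", "total", c(1, 50), c(1, 2), group = 1)
  expect_error(compute_centroids(list(sparse)), "daily")
  expect_error(compute_centroids(two_equal, groups = 4), "no series")
})

test_that("reduction keeps exactly the requested days in order", {
  s <- generate_trajectory(default_pattern_params(3), noise_cv = 0, seed = 1)
  expect_identical(reduce_to_days(s, 1:50), s)
  r <- reduce_to_days(s, c(1, 10, 26, 34))
  expect_equal(r$days, c(1L, 10L, 26L, 34L))
  expect_equal(r$mfi, s$mfi[c(1, 10, 26, 34)])
  # unsorted input days are canonicalised
  r2 <- reduce_to_days(s, c(26, 1, 10))
  expect_equal(r2$days, c(1L, 10L, 26L))
  expect_error(reduce_to_days(s, c(1, 51)), "\\[1, 50\\]")
})

test_that("classification picks the nearest centroid, ties to smaller id", {
  coh <- noiseless_cohort(n_per_group = 2)
  cen <- compute_centroids(coh)
  # a series equal to a centroid lands in that group at any day subset
  for (days in list(1:50, c(1, 10, 26, 34), c(1, 26))) {
    expect_equal(classify(cen[["2"]], cen, days = days), 2L)
  }
  # exactly equidistant between groups 1 and 3: the declared tie rule
  cen_tie <- compute_centroids(list(
    flat_series("a", 1, 0), flat_series("b", 3, 10)
  ))
  expect_equal(classify(flat_series("x", NA, 5), cen_tie, days = 1:50), 1L)
  # centroid order does not matter
  reordered <- structure(rev(unclass(cen_tie)), class = "centroid_set")
  expect_equal(classify(flat_series("x", NA, 5), reordered, days = 1:50), 1L)
})

test_that("noiseless cohorts classify perfectly at full resolution", {
  for (seed in c(1, 2)) {
    coh <- noiseless_cohort(n_per_group = 3, seed = seed)
    out <- classify_cohort(coh)
    expect_equal(out$C, 100)
    expect_equal(out$Ncp, out$Np)
    expect_equal(out$predictions, out$truths)
  }
})

test_that("leave-one-out mode recomputes centroids without the test series", {
  coh <- noisy_cohort(n_per_group = 4, seed = 5)
  loo <- classify_cohort(coh, days = c(1, 10, 26, 34), mode = "loo")
  expect_equal(loo$Np, 16L)
  expect_true(loo$C >= 0 && loo$C <= 100)
})

test_that("accuracy implements C = Ncp / Np x 100", {
  all_right <- accuracy(rep(1:4, 16), rep(1:4, 16))
  expect_equal(all_right$Np, 64L)
  expect_equal(all_right$C, 100)
  expect_equal(accuracy(c(1, 2, 3, 3), c(1, 2, 3, 4))$C, 75)
  expect_equal(accuracy(c(2, 2), c(3, 4))$C, 0)
  # invariant under any common permutation
  set.seed(3)
  pred <- sample(1:4, 30, replace = TRUE)
  truth <- sample(1:4, 30, replace = TRUE)
  perm <- sample(30)
  expect_equal(accuracy(pred[perm], truth[perm])$C, accuracy(pred, truth)$C)
  expect_error(accuracy(1:3, 1:4), "equal length")
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
})

test_that("band summaries reproduce the published percentage rows", {
  out <- summarize_bands(reference_band_counts())
  expect_equal(out$band, c("<2500", "2500-5000", "5000-10000", ">10000"))
  expect_equal(out$total, c(114L, 37L, 48L, 10L))
  pct <- as.matrix(out[, c("pct_0", "pct_1", "pct_2", "pct_3", "pct_4")])
  expect_equal(unname(pct), rbind(
    c(56, 21, 18, 2, 3),
    c(14, 19, 38, 16, 14),
    c(6, 21, 13, 40, 21),
    c(0, 0, 20, 10, 70)
  ))
  broad <- as.matrix(
    out[, c("pct_no_response", "pct_modulated", "pct_sustained")]
  )
  expect_equal(unname(broad), rbind(
    c(56, 39, 4),
    c(14, 57, 30),
    c(6, 33, 60),
    c(0, 20, 80)
  ))
  # integer rounding keeps every row within 1 of 100
  expect_true(all(abs(rowSums(pct) - 100) <= 1))
})

test_that("band summary edge cases are handled", {
  single <- matrix(c(0, 0, 5, 0, 0),
    nrow = 1,
    dimnames = list("only", as.character(0:4))
  )
  out <- summarize_bands(single)
  expect_equal(out$pct_2, 100)
  expect_equal(out$pct_modulated, 100)

  with_empty <- rbind(single, empty = rep(0L, 5))
  expect_warning(out2 <- summarize_bands(with_empty), "zero total")
  expect_true(out2$empty[2])
  expect_true(is.na(out2$pct_0[2]))

  expect_error(summarize_bands(matrix(-1, 1, 5)), "non-negative")
})
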