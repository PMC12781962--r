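test_that("section splitting follows the floor rule for every N", {
  s2 <- split_sections(2)
  expect_equal(s2$boundaries$start, c(1L, 26L))
  expect_equal(s2$boundaries$end, c(25L, 50L))

  # the uneven N = 26 split: 25 single-day sections then one 25-day tail
  s26 <- split_sections(26)
  expect_equal(nrow(s26$boundaries), 26L)
  expect_equal(s26$boundaries$start[1:25], 1:25)
  expect_equal(s26$boundaries$end[1:25], 1:25)
  expect_equal(s26$boundaries$start[26], 26L)
  expect_equal(s26$boundaries$end[26], 50L)

  s50 <- split_sections(50)
  expect_equal(s50$boundaries$start, 1:50)
  expect_equal(s50$boundaries$end, 1:50)

  # partition invariants across the whole range
  for (N in 2:50) {
    b <- split_sections(N)$boundaries
    expect_equal(nrow(b), N)
    covered <- unlist(mapply(seq, b$start, b$end, SIMPLIFY = FALSE))
    expect_equal(covered, 1:50) # ordered, disjoint, exhaustive
    lens <- b$end - b$start + 1L
    expect_true(all(lens[-N] == 50 %/% N))
  }

  expect_error(split_sections(1), "\\[2, 50\\]")
  expect_error(split_sections(51), "\\[2, 50\\]")
})

test_that("day selection strategies pick one day per section", {
  s2 <- split_sections(2)
  expect_equal(select_days(s2, "first"), c(1L, 26L))
  expect_equal(select_days(s2, "middle"), c(13L, 38L))
  s50 <- split_sections(50)
  for (strat in c("first", "middle")) {
    expect_equal(select_days(s50, strat), 1:50)
  }
  expect_equal(select_days(s50, "random", seed = 1), 1:50)

  # random: seeded, reproducible, one day inside each section
  for (N in c(3, 7, 26)) {
    sch <- split_sections(N)
    d1 <- select_days(sch, "random", seed = 42)
    expect_identical(d1, select_days(sch, "random", seed = 42))
    expect_equal(length(d1), N)
    expect_true(all(d1 >= sch$boundaries$start & d1 <= sch$boundaries$end))
  }
  expect_error(select_days(s2, "random"), "seed")
  expect_error(select_days(s2, "nearest"), "'arg'")
})

test_that("section sweeps reach 100% at N = 50 and are reproducible", {
  coh <- noiseless_cohort(n_per_group = 2)
  for (strat in c("first", "middle", "random")) {
    sw <- sweep_sections(coh,
      strategy = strat, N_range = c(2, 25, 50),
      repeats = 3, seed = 7
    )
    expect_equal(sw$N, c(2, 25, 50))
    expect_equal(sw$C[sw$N == 50], 100)
    expect_true(all(sw$C >= 0 & sw$C <= 100))
    # deterministic strategies are forced to a single repeat
    if (strat != "random") expect_equal(unique(sw$repeats), 1L)
    expect_identical(sw, sweep_sections(coh,
      strategy = strat,
      N_range = c(2, 25, 50), repeats = 3, seed = 7
    ))
  }
  # refinement on the separable noiseless cohort (first-point strategy)
  sw_first <- sweep_sections(coh, strategy = "first", N_range = c(2, 25))
  expect_gte(sw_first$C[sw_first$N == 25], sw_first$C[sw_first$N == 2])
})

test_that("fixed day subsets are scored by reduce-then-classify", {
  coh <- noiseless_cohort(n_per_group = 3)
  expect_equal(evaluate_subset(coh, 1:50)$C, 100)
  expect_equal(evaluate_subset(coh, c(1, 10, 26, 34))$C, 100)

  # groups that coincide on the probed day cannot be separated by it
  twins <- list(
    flat_series("a", 1, 100, spots = c("10" = 500)),
    flat_series("b", 2, 100, spots = c("30" = 500))
  )
  out <- evaluate_subset(twins, 2, groups = 1:2)
  expect_lt(out$C, 100)
})

test_that("greedy augmentation adds the most informative day first", {
  # built so only day 10 separates group 1 from group 2
  coh <- list(
    flat_series("a", 1, 100, spots = c("10" = 600)),
    flat_series("b", 1, 100, spots = c("10" = 620)),
    flat_series("c", 2, 100),
    flat_series("d", 2, 100)
  )
  res <- greedy_augment(coh,
    base = 1, candidate_days = c(5, 10, 20),
    max_size = 2, groups = 1:2
  )
  expect_equal(res$days, c(1L, 10L))
  first_step <- res$steps[res$steps$step == 1, ]
  expect_equal(first_step$day[first_step$chosen], 10L)
  expect_equal(res$best$C, 100)
  # replacement scan covers every (kept day, unused candidate) pair
  expect_equal(nrow(res$replacements), 2 * 2)

  # candidates already inside base: nothing to add, same accuracy
  same <- greedy_augment(coh,
    base = c(1, 10), candidate_days = c(1, 10),
    max_size = 5, groups = 1:2
  )
  expect_equal(same$days, c(1L, 10L))
  expect_equal(same$best$C, 100)
  expect_equal(nrow(same$steps), 0L)

  # max_size equal to the base size returns the base untouched
  stay <- greedy_augment(coh,
    base = c(1, 10), candidate_days = c(5, 20),
    max_size = 2, groups = 1:2
  )
  expect_equal(stay$days, c(1L, 10L))

  expect_error(
    greedy_augment(coh, base = c(1, 10), candidate_days = c(5), max_size = 1),
    "max_size"
  )
  expect_error(
    greedy_augment(coh, base = 1, candidate_days = integer(0)),
    "non-empty"
  )
})

test_that("the regimen catalogue carries the published day lists", {
  regs <- builtin_regimens()
  expect_equal(regs[["A"]]$days, sort(c(1:14, 17, 18, 20, 22, 27, 30)))
  expect_equal(regs[["B"]]$days, c(1L, 8L, 15L, 22L))
  expect_equal(regs[["C"]]$days, c(1L, 7L, 30L))
  expect_equal(regs[["D"]]$days, c(4L, 7L, 14L, 30L))
  expect_equal(regs[["E"]]$days, sort(c(1:3, 7, 14, 21, 28)))
  expect_equal(regs[["F"]]$days, c(1L, 10L, 26L))
  expect_equal(regs[["F_alt"]]$days, c(1L, 10L, 34L))
  expect_equal(regs[["G"]]$days, c(1L, 10L, 26L, 34L))
})

test_that("regimen comparison scores and ranks schedules", {
  coh <- noiseless_cohort(n_per_group = 2)
  tab <- compare_regimens(coh)
  expect_equal(nrow(tab), 8L)
  expect_true(all(diff(tab$C) <= 0)) # sorted by C descending
  # the separable noiseless cohort: every day-1 regimen classifies perfectly
  day1 <- vapply(
    builtin_regimens(), function(r) 1L %in% r$days, logical(1)
  )
  expect_true(all(tab$C[tab$name %in% names(day1)[day1]] == 100))

  full <- compare_regimens(coh, list(regimen("all", 1:50)))
  expect_equal(full$C, evaluate_subset(coh, 1:50)$C)

  expect_warning(
    compare_regimens(coh, list(regimen("X", 1), regimen("X", 2))),
    "duplicate"
  )
  expect_error(regimen("late", c(30, 60)), "late")
})
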