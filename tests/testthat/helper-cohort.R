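# Shared fixtures, built in code.

noiseless_cohort <- function(n_per_group = 2, groups = 1:4, seed = 1) {
  generate_cohort(cohort_config(
    n_per_group = n_per_group, noise_cv = 0, groups = groups, seed = seed
  ))
}

noisy_cohort <- function(n_per_group = 25, noise_cv = 0.15, groups = 1:4,
                         seed = 42) {
  generate_cohort(cohort_config(
    n_per_group = n_per_group, noise_cv = noise_cv, groups = groups,
    seed = seed
  ))
}

# a flat series with chosen spot values, for hand-constructed cohorts
flat_series <- function(id, group, level = 100, spots = NULL) {
  mfi <- rep(level, 50)
  if (!is.null(spots)) mfi[as.integer(names(spots))] <- spots
  trajectory_series(id, "total", 1:50, mfi, group = group)
}

random_short_pair <- function() {
  n <- sample(2:6, 1)
  m <- sample(2:6, 1)
  list(a = sample(0:9, n, replace = TRUE), b = sample(0:9, m, replace = TRUE))
}
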