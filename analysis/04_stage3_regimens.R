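#!/usr/bin/env Rscript
# Stage 3: comparison against published clinical monitoring regimens.
#
# Scores the built-in catalogue of centre-reported DSA monitoring schedules
# (A-E) alongside the minimal schedules from stage 2 (F: days 1, 10, 26 or
# its day-34 variant; G: days 1, 10, 26, 34) on the simulated cohort.

suppressPackageStartupMessages(library(dsamonitor))

cohort <- read_trajectories("results/cohort_daily.csv")
labels <- vapply(cohort, `[[`, integer(1), "group")
universe <- cohort[labels %in% 1:4]

tab <- compare_regimens(universe)
write.csv(tab, "results/stage3_regimens.csv", row.names = FALSE)

message("regimen comparison (sorted by accuracy):")
for (i in seq_len(nrow(tab))) {
  message(sprintf(
    "  %-6s %-40s (%2d days)  C = %5.1f%%",
    tab$name[i], paste0("{", tab$days[i], "}"), tab$n_days[i], tab$C[i]
  ))
}
message("wrote results/stage3_regimens.csv")
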