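#!/usr/bin/env Rscript
# Stage 2: greedy search for additional monitoring days.
#
# Starting from the 2-day schedule found in stage 1 (days 1 and 26 under the
# first-point strategy), each remaining day is tried as an addition and the
# best performer kept, up to five monitoring days in total. A replacement
# scan then swaps each kept day against every unused candidate to check
# whether any selected day is redundant.

suppressPackageStartupMessages(library(dsamonitor))

cohort <- read_trajectories("results/cohort_daily.csv")
labels <- vapply(cohort, `[[`, integer(1), "group")
universe <- cohort[labels %in% 1:4]

base <- c(1, 26)
res <- greedy_augment(universe,
  base = base,
  candidate_days = setdiff(1:50, base), max_size = 5
)
write.csv(res$steps, "results/stage2_steps.csv", row.names = FALSE)
write.csv(res$replacements, "results/stage2_replacements.csv",
  row.names = FALSE
)

message(sprintf(
  "base {%s}: C = %.1f%%",
  paste(base, collapse = ", "),
  evaluate_subset(universe, base)$C
))
for (st in unique(res$steps$step)) {
  chosen <- res$steps[res$steps$step == st & res$steps$chosen, ]
  message(sprintf(
    "step %d: added day %d -> {%s}, C = %.1f%%",
    st, chosen$day, chosen$days, chosen$C
  ))
}
message(sprintf(
  "final schedule {%s}: C = %.1f%% (Ncp = %d / Np = %d)",
  paste(res$days, collapse = ", "), res$best$C, res$best$Ncp, res$best$Np
))
best_swap <- res$replacements[1, ]
message(sprintf(
  "best replacement (%d -> %d) reaches C = %.1f%%",
  best_swap$removed, best_swap$added, best_swap$C
))
message("wrote results/stage2_steps.csv and results/stage2_replacements.csv")
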