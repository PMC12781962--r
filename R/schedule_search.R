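#' Split the 50-day window into N contiguous sections
#'
#' The first `N - 1` sections have length `floor(50 / N)`; the last section
#' absorbs the remainder. This rule makes the split exactly reproducible for
#' every `N`: e.g. `N = 26` yields 25 single-day sections (days 1-25)
#' followed by one 25-day section (days 26-50) — the uneven coverage that
#' causes the known accuracy dip just above `N = 25` in section-based day
#' reduction.
#'
#' @param N Number of sections, `2 <= N <= 50`.
#' @param total_days Length of the window (fixed at 50).
#' @return An object of class `section_scheme`: list with `N` and
#'   `boundaries`, a data frame of `start`/`end` days (inclusive) covering
#'   `1:50` without gaps or overlap.
#' @export
split_sections <- function(N, total_days = DAY_MAX) {
  if (length(N) != 1L || !is.finite(N) || N != round(N)) {
    stop("`N` must be a single integer", call. = FALSE)
  }
  N <- as.integer(N)
  if (N < 2L || N > total_days) {
    stop("`N` must lie in [2, ", total_days, "]", call. = FALSE)
  }
  len <- total_days %/% N
  start <- 1L + (seq_len(N) - 1L) * len
  end <- c(start[-1L] - 1L, total_days)
  structure(
    list(N = N, boundaries = data.frame(start = start, end = end)),
    class = "section_scheme"
  )
}

#' @export
print.section_scheme <- function(x, ...) {
  cat(sprintf(
    "<section_scheme> N = %d sections: %s\n",
    x$N,
    paste(sprintf("[%d-%d]", x$boundaries$start, x$boundaries$end),
      collapse = " "
    )
  ))
  invisible(x)
}

#' Select one monitoring day per section
#'
#' Strategies: `"first"` takes each section's first day; `"middle"` the day
#' at index `ceiling(length / 2)` within the section (so a 25-day section
#' contributes its 13th day); `"random"` draws uniformly within each
#' section, seeded.
#'
#' @param scheme A [split_sections()] result (or its `boundaries` data
#'   frame).
#' @param strategy One of `"random"`, `"middle"`, `"first"`.
#' @param seed Integer seed, required for the `"random"` strategy.
#' @return Sorted integer vector of days, one per section.
#' @export
select_days <- function(scheme, strategy = c("random", "middle", "first"),
                        seed = NULL) {
  strategy <- match.arg(strategy)
  b <- if (inherits(scheme, "section_scheme")) scheme$boundaries else scheme
  stopifnot(is.data.frame(b), all(c("start", "end") %in% names(b)))
  days <- switch(strategy,
    first = b$start,
    middle = b$start + ceiling((b$end - b$start + 1L) / 2) - 1L,
    random = {
      if (is.null(seed)) {
        stop("the random strategy requires a `seed`", call. = FALSE)
      }
      with_seed(seed, {
        mapply(function(s, e) if (s == e) s else sample(s:e, 1L),
          b$start, b$end
        )
      })
    }
  )
  sort(as.integer(days))
}

#' Accuracy of classification on a fixed day subset
#'
#' Reduces every cohort series and every centroid to the given monitoring
#' days, classifies by nearest DTW centroid, and scores against the true
#' labels.
#'
#' @param cohort List of daily, labelled [trajectory_series()].
#' @param days Non-empty monitoring-day subset of `1:50`.
#' @param centroids Optional precomputed `centroid_set` (resubstitution
#'   centroids from `cohort` if `NULL`).
#' @param groups Classification universe (default `1:4`).
#' @param ... Passed to [classify_cohort()].
#' @return A `classification_outcome` with the day subset attached.
#' @export
evaluate_subset <- function(cohort, days, centroids = NULL, groups = 1:4,
                            ...) {
  classify_cohort(cohort,
    centroids = centroids, days = days,
    groups = groups, ...
  )
}

#' Accuracy as a function of the number of sections N
#'
#' For each `N` in `N_range`: split days 1-50 into `N` sections, select one
#' day per section with the given strategy, reduce and classify the cohort,
#' and record the accuracy `C`. The random strategy is repeated `repeats`
#' times with per-repeat seeds drawn from the master seed and averaged;
#' deterministic strategies are forced to a single repeat.
#'
#' @param cohort List of daily, labelled [trajectory_series()].
#' @param strategy `"random"`, `"middle"` or `"first"`.
#' @param N_range Integer vector of section counts (default `2:50`).
#' @param repeats Number of random repeats (default 100).
#' @param seed Master seed for the random strategy.
#' @param centroids Optional precomputed `centroid_set`.
#' @param groups Classification universe (default `1:4`).
#' @param ... Passed to [classify_cohort()].
#' @return Data frame with one row per `N`: `N`, `strategy`, `C` (mean over
#'   repeats), `C_sd` (NA for deterministic strategies) and `repeats`.
#' @export
sweep_sections <- function(cohort, strategy = c("random", "middle", "first"),
                           N_range = 2:50, repeats = 100L, seed = 1L,
                           centroids = NULL, groups = 1:4, ...) {
  strategy <- match.arg(strategy)
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  if (strategy != "random") repeats <- 1L
  if (is.null(centroids)) {
    labels <- vapply(cohort, `[[`, integer(1), "group")
    centroids <- compute_centroids(cohort[labels %in% groups], groups = groups)
  }
  repeat_seeds <- with_seed(seed, sample.int(.Machine$integer.max, repeats))
  rows <- lapply(N_range, function(N) {
    scheme <- split_sections(N)
    cs <- vapply(seq_len(repeats), function(r) {
      days <- select_days(scheme, strategy, seed = repeat_seeds[r])
      evaluate_subset(cohort, days,
        centroids = centroids, groups = groups, ...
      )$C
    }, numeric(1))
    data.frame(
      N = N, strategy = strategy, C = mean(cs),
      C_sd = if (repeats > 1L) stats::sd(cs) else NA_real_,
      repeats = repeats
    )
  })
  do.call(rbind, rows)
}

#' Greedy augmentation of a monitoring-day subset
#'
#' Starting from `base`, repeatedly evaluates `base U {d}` for every
#' remaining candidate day `d`, adds the day with the highest accuracy
#' (ties broken toward the smaller day), and stops at `max_size` days or
#' when no candidate remains. Also reports a replacement scan of the final
#' subset: each selected day swapped in turn for each unused candidate.
#'
#' @param cohort List of daily, labelled [trajectory_series()].
#' @param base Non-empty starting day subset (e.g. `c(1, 26)`).
#' @param candidate_days Candidate days to draw additions from.
#' @param max_size Maximum total number of monitoring days (default 5).
#' @param centroids Optional precomputed `centroid_set`.
#' @param groups Classification universe (default `1:4`).
#' @param ... Passed to [classify_cohort()].
#' @return List with `steps` (per-iteration ranking of every candidate
#'   addition: `step`, `day`, `days`, `C`, `chosen`), `best` (the final
#'   `classification_outcome`), `days` (the final subset) and
#'   `replacements` (data frame `removed`, `added`, `days`, `C`).
#' @export
greedy_augment <- function(cohort, base, candidate_days, max_size = 5L,
                           centroids = NULL, groups = 1:4, ...) {
  base <- check_days_subset(base, arg = "base")
  candidate_days <- check_days_subset(candidate_days, arg = "candidate_days")
  if (max_size < length(base)) {
    stop("`max_size` must be at least the size of `base`", call. = FALSE)
  }
  if (is.null(centroids)) {
    labels <- vapply(cohort, `[[`, integer(1), "group")
    centroids <- compute_centroids(cohort[labels %in% groups], groups = groups)
  }
  score <- function(days) {
    evaluate_subset(cohort, days, centroids = centroids, groups = groups, ...)$C
  }
  current <- base
  steps <- list()
  step <- 0L
  while (length(current) < max_size) {
    pool <- setdiff(candidate_days, current)
    if (length(pool) == 0L) break
    step <- step + 1L
    cs <- vapply(pool, function(d) score(sort(c(current, d))), numeric(1))
    ranking <- data.frame(
      step = step, day = pool, C = cs
    )[order(-cs, pool), ]
    best_day <- ranking$day[1L]
    # no candidate improves: still record the scan, then stop
    ranking$days <- vapply(ranking$day, function(d) {
      paste(sort(c(current, d)), collapse = ",")
    }, character(1))
    ranking$chosen <- ranking$day == best_day
    steps[[step]] <- ranking
    current <- sort(c(current, best_day))
  }
  replacements <- NULL
  pool <- setdiff(candidate_days, current)
  if (length(pool) > 0L && length(current) > 0L) {
    grid <- expand.grid(removed = current, added = pool)
    grid$C <- vapply(seq_len(nrow(grid)), function(i) {
      score(sort(c(setdiff(current, grid$removed[i]), grid$added[i])))
    }, numeric(1))
    grid$days <- vapply(seq_len(nrow(grid)), function(i) {
      paste(sort(c(setdiff(current, grid$removed[i]), grid$added[i])),
        collapse = ","
      )
    }, character(1))
    replacements <- grid[order(-grid$C), ]
    rownames(replacements) <- NULL
  }
  steps_df <- if (length(steps) > 0L) {
    out <- do.call(rbind, steps)
    rownames(out) <- NULL
    out[, c("step", "day", "days", "C", "chosen")]
  } else {
    data.frame(
      step = integer(), day = integer(), days = character(),
      C = numeric(), chosen = logical()
    )
  }
  best <- evaluate_subset(cohort, current,
    centroids = centroids,
    groups = groups, ...
  )
  list(steps = steps_df, best = best, days = current,
    replacements = replacements)
}

#' A named clinical monitoring regimen
#'
#' @param name Regimen label.
#' @param days Monitoring days, all within `[1, 50]` (regimens extending
#'   beyond day 50 fall outside the analysis window).
#' @param source Citation tag or free-text provenance.
#' @return An object of class `regimen`.
#' @export
regimen <- function(name, days, source = "") {
  days <- tryCatch(
    check_days_subset(days, arg = "days"),
    error = function(e) {
      stop("regimen \"", name, "\": ", conditionMessage(e), call. = FALSE)
    }
  )
  structure(
    list(name = as.character(name), days = days, source = as.character(source)),
    class = "regimen"
  )
}

#' Built-in catalogue of published DSA monitoring regimens
#'
#' Monitoring-day schedules reported by different transplant centres
#' (regimens A-E), restricted to schedules that fit within the first 50
#' post-transplant days, plus the proposed minimal schedules: F = days
#' 1, 10, 26 (variant F_alt = days 1, 10, 34) and G = days 1, 10, 26, 34.
#'
#' @return Named list of [regimen()] objects.
#' @export
builtin_regimens <- function() {
  regs <- list(
    regimen("A", c(1:14, 17, 18, 20, 22, 27, 30), "published protocol A"),
    regimen("B", c(1, 8, 15, 22), "published protocol B"),
    regimen("C", c(1, 7, 30), "published protocol C"),
    regimen("D", c(4, 7, 14, 30), "published protocol D"),
    regimen("E", c(1:3, 7, 14, 21, 28), "published protocol E"),
    regimen("F", c(1, 10, 26), "proposed minimal schedule"),
    regimen("F_alt", c(1, 10, 34), "proposed minimal schedule (variant)"),
    regimen("G", c(1, 10, 26, 34), "proposed four-day schedule")
  )
  names(regs) <- vapply(regs, `[[`, character(1), "name")
  regs
}

#' Score monitoring regimens on a cohort
#'
#' Evaluates each regimen's day list with [evaluate_subset()] and tabulates
#' the accuracies, sorted from best to worst.
#'
#' @param cohort List of daily, labelled [trajectory_series()].
#' @param regimens List of [regimen()] objects (default the built-in
#'   catalogue).
#' @param centroids Optional precomputed `centroid_set`.
#' @param groups Classification universe (default `1:4`).
#' @param ... Passed to [classify_cohort()].
#' @return Data frame with columns `name`, `days` (comma-separated),
#'   `n_days`, `C`, sorted by `C` descending.
#' @export
compare_regimens <- function(cohort, regimens = builtin_regimens(),
                             centroids = NULL, groups = 1:4, ...) {
  stopifnot(is.list(regimens), length(regimens) > 0L)
  regimens <- lapply(regimens, function(r) {
    if (inherits(r, "regimen")) r else do.call(regimen, r)
  })
  nms <- vapply(regimens, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    warning("duplicate regimen name(s): ",
      paste(unique(nms[duplicated(nms)]), collapse = ", "),
      "; all are scored",
      call. = FALSE
    )
  }
  if (is.null(centroids)) {
    labels <- vapply(cohort, `[[`, integer(1), "group")
    centroids <- compute_centroids(cohort[labels %in% groups], groups = groups)
  }
  out <- do.call(rbind, lapply(regimens, function(r) {
    res <- evaluate_subset(cohort, r$days,
      centroids = centroids,
      groups = groups, ...
    )
    data.frame(
      name = r$name,
      days = paste(r$days, collapse = ","),
      n_days = length(r$days),
      C = res$C,
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(-out$C, out$name), ]
  rownames(out) <- NULL
  out
}
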