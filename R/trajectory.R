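#' DSA trajectory series
#'
#' A `trajectory_series` holds one DSA (or total-DSA) time course for one
#' patient: integer observation days in `[1, 50]`, the matching MFI values,
#' and an optional dynamic-pattern label (`0` = no response, `1` = fast
#' modulation, `2` = slow modulation, `3` = rise to sustained,
#' `4` = sustained).
#'
#' Days are sorted at construction; repeated measurements on the same day are
#' averaged (the only symmetric, order-independent resolution). MFI values
#' must be finite and non-negative.
#'
#' @param patient_id Patient identifier (coerced to character).
#' @param dsa_label DSA identifier, or `"total"` for a summed total-DSA
#'   series.
#' @param days Integer vector of observation days in `[1, 50]`.
#' @param mfi Numeric vector of MFI values, same length as `days`, finite
#'   and `>= 0`.
#' @param group Optional pattern label in `0:4`, or `NA` if unlabelled.
#'
#' @return An object of class `trajectory_series`: a list with elements
#'   `patient_id`, `dsa_label`, `days`, `mfi`, `group`.
#' @export
trajectory_series <- function(patient_id, dsa_label, days, mfi, group = NA) {
  if (length(days) != length(mfi)) {
    stop("`days` and `mfi` must have the same length", call. = FALSE)
  }
  if (length(days) == 0L) {
    stop("a trajectory needs at least one observation", call. = FALSE)
  }
  if (anyNA(days) || any(days != round(days))) {
    stop("`days` must be whole numbers", call. = FALSE)
  }
  days <- as.integer(days)
  if (any(days < 1L | days > DAY_MAX)) {
    stop("`days` must lie in [1, ", DAY_MAX, "]", call. = FALSE)
  }
  mfi <- as.numeric(mfi)
  if (any(!is.finite(mfi))) {
    stop("`mfi` must be finite", call. = FALSE)
  }
  if (any(mfi < 0)) {
    stop("`mfi` must be non-negative", call. = FALSE)
  }
  if (!is.na(group)) {
    group <- check_group(group)
  } else {
    group <- NA_integer_
  }
  if (anyDuplicated(days)) {
    mfi <- as.numeric(tapply(mfi, days, mean))
    days <- sort(unique(days))
  } else {
    ord <- order(days)
    days <- days[ord]
    mfi <- mfi[ord]
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      dsa_label = as.character(dsa_label),
      days = days,
      mfi = mfi,
      group = group
    ),
    class = "trajectory_series"
  )
}

# inclusive day range of the analysis window
DAY_MAX <- 50L

#' @export
print.trajectory_series <- function(x, ...) {
  lab <- if (is.na(x$group)) "unlabelled" else paste("group", x$group)
  cat(sprintf(
    "<trajectory_series> patient %s, DSA %s, %d days (%d-%d), %s\n",
    x$patient_id, x$dsa_label, length(x$days),
    min(x$days), max(x$days), lab
  ))
  invisible(x)
}

#' Test whether a series is on the full daily grid
#'
#' A "daily" series has exactly days `1, 2, ..., 50`.
#'
#' @param series A [trajectory_series()].
#' @return `TRUE` if the series covers every day from 1 to 50.
#' @export
is_daily <- function(series) {
  stopifnot(inherits(series, "trajectory_series"))
  identical(series$days, seq_len(DAY_MAX))
}

check_group <- function(group) {
  if (length(group) != 1L || is.na(group) || !(group %in% 0:4)) {
    stop("`group` must be a single pattern id in 0, 1, 2, 3, 4", call. = FALSE)
  }
  as.integer(group)
}

check_days_subset <- function(days, arg = "days") {
  if (length(days) == 0L) {
    stop("`", arg, "` must be non-empty", call. = FALSE)
  }
  if (anyNA(days) || any(days != round(days))) {
    stop("`", arg, "` must be whole numbers", call. = FALSE)
  }
  days <- as.integer(days)
  if (any(days < 1L | days > DAY_MAX)) {
    stop("`", arg, "` must lie in [1, ", DAY_MAX, "] (days are 1-based)",
      call. = FALSE
    )
  }
  sort(unique(days))
}

#' Convert a list of trajectories to a long-format data frame
#'
#' @param cohort A list of [trajectory_series()].
#' @return A data frame with columns `patient_id`, `dsa_label`, `group`,
#'   `day`, `mfi` (one row per observation).
#' @export
cohort_to_df <- function(cohort) {
  stopifnot(is.list(cohort), length(cohort) > 0L)
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(
      patient_id = s$patient_id,
      dsa_label = s$dsa_label,
      group = if (is.na(s$group)) NA_integer_ else s$group,
      day = s$days,
      mfi = s$mfi,
      stringsAsFactors = FALSE
    )
  }))
}

# run code under a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(code)
}
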