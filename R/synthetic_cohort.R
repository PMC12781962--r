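#' Reference per-group average total-DSA levels
#'
#' Average total-DSA MFI per dynamic group in the reference HLA-incompatible
#' transplant cohort, used to anchor the scale of the synthetic trajectory
#' generator. Groups: 0 = no response, 1 = fast modulation, 2 = slow
#' modulation, 3 = rise to sustained, 4 = sustained.
#'
#' @return Named numeric vector of MFI values, names `"0"` to `"4"`.
#' @export
reference_group_mfi <- function() {
  c("0" = 2062, "1" = 7023, "2" = 7105, "3" = 14813, "4" = 12674)
}

#' Reference band-by-pattern DSA counts
#'
#' Number of DSAs in each dynamic group, split by the baseline
#' (pre-desensitisation) MFI band, as observed in the reference cohort.
#' These counts drive the default band/pattern mixing of the synthetic
#' cohort generator and are the worked input for [summarize_bands()].
#'
#' @return Integer matrix, one row per MFI band (`"<2500"`, `"2500-5000"`,
#'   `"5000-10000"`, `">10000"`), one column per group (`"0"` to `"4"`).
#'   Attribute `bounds` holds the numeric band edges used when drawing
#'   baseline MFI values.
#' @export
reference_band_counts <- function() {
  counts <- matrix(
    c(
      64L, 24L, 21L, 2L, 3L,
      5L, 7L, 14L, 6L, 5L,
      3L, 10L, 6L, 19L, 10L,
      0L, 0L, 2L, 1L, 7L
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(
      c("<2500", "2500-5000", "5000-10000", ">10000"),
      c("0", "1", "2", "3", "4")
    )
  )
  attr(counts, "bounds") <- c(500, 2500, 5000, 10000, 20000)
  counts
}

#' Default baseline-band / pattern mixing table
#'
#' Row-normalised probabilities of each dynamic pattern conditional on the
#' baseline MFI band, derived from [reference_band_counts()]. Each row sums
#' to exactly 1, so the generator's band mixing is exact rather than subject
#' to the rounding of percentage summaries.
#'
#' @return Numeric matrix of probabilities with the same dimnames and
#'   `bounds` attribute as [reference_band_counts()].
#' @export
default_band_mixing <- function() {
  counts <- reference_band_counts()
  probs <- sweep(counts, 1, rowSums(counts), "/")
  attr(probs, "bounds") <- attr(counts, "bounds")
  probs
}

#' Default observation schedule
#'
#' The simulated sampling schedule: daily for the first two weeks, alternate
#' days for the following two weeks, then sparser sampling up to day 50.
#' Days 1 and 50 are always present so interpolation is anchored at both
#' ends of the window.
#'
#' @return Sorted integer vector of observation days.
#' @export
default_sampling_schedule <- function() {
  as.integer(c(1:14, seq(16L, 28L, by = 2L), 31L, 34L, 38L, 42L, 46L, 50L))
}

#' Parameters of one dynamic-pattern trajectory
#'
#' Describes the noiseless shape of a DSA trajectory for one of the five
#' dynamic groups:
#'
#' * group 0 (no response): flat at `baseline_mfi`.
#' * groups 1-2 (fast/slow modulation): a gamma pulse
#'   `b + A * (t/tp)^k * exp(k * (1 - t/tp))` with shape
#'   `k = rise_rate * peak_day`, peaking at `peak_day` with value
#'   `b + A` and returning toward baseline within the 50-day window.
#' * group 3 (rise to sustained): saturating exponential rise
#'   `b + (P - b) * (1 - exp(-rise_rate * t))` from a low baseline to a
#'   high plateau `P`.
#' * group 4 (sustained): starts high and settles mildly,
#'   `P + (b - P) * exp(-decay_rate * t)` with `b > P`.
#'
#' Unspecified fields are filled from the per-group defaults (see
#' [default_pattern_params()]).
#'
#' @param group Pattern id in `0:4`.
#' @param baseline_mfi Baseline MFI level (units: MFI, `>= 0`).
#' @param peak_amplitude Pulse height above baseline for modulated groups
#'   (MFI, `>= 0`).
#' @param peak_day Day of the pulse maximum, in `[1, 50]`.
#' @param rise_rate Rise rate (1/day, `> 0`).
#' @param decay_rate Decay/settling rate (1/day, `>= 0`).
#' @param plateau_level Sustained plateau level (MFI, `>= 0`).
#' @return An object of class `pattern_params`.
#' @export
pattern_params <- function(group, baseline_mfi = NULL, peak_amplitude = NULL,
                           peak_day = NULL, rise_rate = NULL,
                           decay_rate = NULL, plateau_level = NULL) {
  group <- check_group(group)
  defaults <- default_pattern_params(group)
  p <- list(
    group = group,
    baseline_mfi = baseline_mfi %||% defaults$baseline_mfi,
    peak_amplitude = peak_amplitude %||% defaults$peak_amplitude,
    peak_day = peak_day %||% defaults$peak_day,
    rise_rate = rise_rate %||% defaults$rise_rate,
    decay_rate = decay_rate %||% defaults$decay_rate,
    plateau_level = plateau_level %||% defaults$plateau_level
  )
  validate_pattern_params(p)
  structure(p, class = "pattern_params")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_pattern_params <- function(p) {
  num1 <- function(x, nm, lo = 0, strict = FALSE) {
    if (length(x) != 1L || !is.finite(x)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    if (strict && x <= lo) stop("`", nm, "` must be > ", lo, call. = FALSE)
    if (!strict && x < lo) stop("`", nm, "` must be >= ", lo, call. = FALSE)
    invisible(x)
  }
  num1(p$baseline_mfi, "baseline_mfi")
  num1(p$peak_amplitude, "peak_amplitude")
  num1(p$rise_rate, "rise_rate", strict = TRUE)
  num1(p$decay_rate, "decay_rate")
  num1(p$plateau_level, "plateau_level")
  if (p$peak_day < 1 || p$peak_day > DAY_MAX) {
    stop("`peak_day` must lie in [1, ", DAY_MAX, "]", call. = FALSE)
  }
  if (p$group == 0L && p$peak_amplitude > 0.05 * max(p$baseline_mfi, 1)) {
    stop("group 0 (no response) requires a negligible `peak_amplitude`",
      call. = FALSE
    )
  }
  if (p$group %in% 1:2 && p$decay_rate <= 0) {
    stop("modulated groups (1-2) require `decay_rate` > 0", call. = FALSE)
  }
  if (p$group == 3L && p$baseline_mfi >= p$plateau_level) {
    stop("group 3 (rise to sustained) starts low: `baseline_mfi` must be ",
      "below `plateau_level`",
      call. = FALSE
    )
  }
  if (p$group == 4L && p$baseline_mfi < p$plateau_level) {
    stop("group 4 (sustained) starts high: `baseline_mfi` must be at least ",
      "`plateau_level`",
      call. = FALSE
    )
  }
  invisible(p)
}

#' Default trajectory parameters per dynamic group
#'
#' Shapes follow the canonical qualitative patterns; amplitudes and plateaus
#' are solved so that the noiseless curve's mean over days 1-50 equals the
#' per-group average total-DSA of the reference cohort
#' ([reference_group_mfi()]). Peak days default to day 12 (fast modulation)
#' and day 18 (slow modulation), consistent with observed DSA peaks within
#' 10-15 days post-transplant, slower for group 2.
#'
#' @param group Pattern id in `0:4`.
#' @return A `pattern_params` object.
#' @export
default_pattern_params <- function(group) {
  group <- check_group(group)
  anchor <- unname(reference_group_mfi()[as.character(group)])
  t <- seq_len(DAY_MAX)
  p <- switch(as.character(group),
    "0" = list(
      group = 0L, baseline_mfi = anchor, peak_amplitude = 0,
      peak_day = 12, rise_rate = 0.25, decay_rate = 0,
      plateau_level = anchor
    ),
    "1" = {
      b <- 1500
      tp <- 12
      r <- 0.25 # k = 3
      shape <- mean((t / tp)^(r * tp) * exp(r * tp * (1 - t / tp)))
      list(
        group = 1L, baseline_mfi = b,
        peak_amplitude = (anchor - b) / shape,
        peak_day = tp, rise_rate = r, decay_rate = r,
        plateau_level = 0
      )
    },
    "2" = {
      b <- 1500
      tp <- 18
      r <- 3 / tp # k = 3
      shape <- mean((t / tp)^(r * tp) * exp(r * tp * (1 - t / tp)))
      list(
        group = 2L, baseline_mfi = b,
        peak_amplitude = (anchor - b) / shape,
        peak_day = tp, rise_rate = r, decay_rate = r,
        plateau_level = 0
      )
    },
    "3" = {
      b <- 2000
      r <- 0.15
      m <- mean(exp(-r * t))
      list(
        group = 3L, baseline_mfi = b, peak_amplitude = 0,
        peak_day = DAY_MAX, rise_rate = r, decay_rate = 0,
        plateau_level = (anchor - b * m) / (1 - m)
      )
    },
    "4" = {
      d <- 0.05
      m <- mean(exp(-d * t))
      plateau <- anchor / (1 + 0.1 * m)
      list(
        group = 4L, baseline_mfi = 1.1 * plateau, peak_amplitude = 0,
        peak_day = 1, rise_rate = 0.25, decay_rate = d,
        plateau_level = plateau
      )
    }
  )
  structure(p, class = "pattern_params")
}

# noiseless parametric curve on the daily grid 1..50
noiseless_curve <- function(params) {
  t <- seq_len(DAY_MAX)
  with(params, switch(as.character(group),
    "0" = rep(baseline_mfi, DAY_MAX),
    "1" = ,
    "2" = {
      k <- rise_rate * peak_day
      baseline_mfi + peak_amplitude * (t / peak_day)^k * exp(k * (1 - t / peak_day))
    },
    "3" = baseline_mfi + (plateau_level - baseline_mfi) * (1 - exp(-rise_rate * t)),
    "4" = plateau_level + (baseline_mfi - plateau_level) * exp(-decay_rate * t)
  ))
}

#' Generate one synthetic DSA trajectory
#'
#' Evaluates the noiseless parametric curve for `params` on the daily grid
#' (days 1-50) and applies multiplicative lognormal measurement noise with
#' the given coefficient of variation. The noise has unit mean, so the
#' expected trajectory is the parametric curve; with `noise_cv = 0` the
#' noiseless curve is returned exactly.
#'
#' @param params A [pattern_params()] object.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (fraction, `>= 0`).
#' @param seed Integer seed; the result is deterministic given
#'   `(params, noise_cv, seed)`.
#' @param patient_id,dsa_label Identifiers attached to the series.
#' @return A daily [trajectory_series()] labelled with `params$group`.
#' @export
generate_trajectory <- function(params, noise_cv = 0.15, seed = 1L,
                                patient_id = "sim", dsa_label = "total") {
  if (!inherits(params, "pattern_params")) {
    params <- do.call(pattern_params, as.list(params))
  }
  validate_pattern_params(params)
  if (!is.finite(noise_cv) || noise_cv < 0) {
    stop("`noise_cv` must be >= 0", call. = FALSE)
  }
  curve <- noiseless_curve(params)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    noise <- with_seed(
      seed,
      stats::rlnorm(DAY_MAX, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    )
    curve <- curve * noise
  }
  trajectory_series(patient_id, dsa_label, seq_len(DAY_MAX), curve,
    group = params$group
  )
}

#' Configuration of a synthetic cohort
#'
#' @param n_per_group Number of trajectories per pattern group (used when
#'   `mfi_band_mixing` is `NULL`).
#' @param noise_cv Coefficient of variation of the per-time-point
#'   multiplicative lognormal noise (default 0.15).
#' @param groups Pattern groups to simulate (default all of `0:4`).
#' @param mfi_band_mixing Optional band/pattern mixing matrix (rows = MFI
#'   bands, columns = groups `0:4`, row sums 1; see
#'   [default_band_mixing()]). When supplied, baseline MFI bands are drawn
#'   first and patterns drawn conditional on the band.
#' @param n_total Total number of trajectories in mixing mode.
#' @param sampling_schedule Optional set of observed days (subset of
#'   `1:50`, must contain days 1 and 50); `NULL` keeps the full daily grid.
#' @param seed Master seed (mandatory); all trajectory-level seeds are
#'   derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 25L, noise_cv = 0.15, groups = 0:4,
                          mfi_band_mixing = NULL, n_total = NULL,
                          sampling_schedule = NULL, seed) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  }
  if (is.null(mfi_band_mixing)) {
    if (length(n_per_group) != 1L || !is.finite(n_per_group) ||
      n_per_group < 1) {
      stop("`n_per_group` must be a positive integer", call. = FALSE)
    }
    groups <- sort(unique(vapply(groups, check_group, integer(1))))
  } else {
    if (!is.matrix(mfi_band_mixing) ||
      ncol(mfi_band_mixing) != 5L || is.null(rownames(mfi_band_mixing))) {
      stop("`mfi_band_mixing` must be a matrix with one row per MFI band ",
        "and one column per group 0-4",
        call. = FALSE
      )
    }
    sums <- rowSums(mfi_band_mixing)
    # rows may be given as probabilities or percentages
    if (all(abs(sums - 100) <= 0.5)) {
      mfi_band_mixing <- mfi_band_mixing / 100
      sums <- sums / 100
    }
    if (any(abs(sums - 1) > 0.005) || any(mfi_band_mixing < 0)) {
      stop("each `mfi_band_mixing` row must be non-negative and sum to 1 ",
        "(or 100%)",
        call. = FALSE
      )
    }
    if (is.null(attr(mfi_band_mixing, "bounds"))) {
      stop("`mfi_band_mixing` needs a `bounds` attribute with the numeric ",
        "band edges",
        call. = FALSE
      )
    }
    if (is.null(n_total) || n_total < 1) {
      stop("`n_total` must be a positive integer in mixing mode",
        call. = FALSE
      )
    }
  }
  if (!is.null(sampling_schedule)) {
    sampling_schedule <- check_days_subset(sampling_schedule,
      arg = "sampling_schedule"
    )
    if (!all(c(1L, DAY_MAX) %in% sampling_schedule)) {
      stop("`sampling_schedule` must contain days 1 and ", DAY_MAX,
        " to anchor interpolation",
        call. = FALSE
      )
    }
  }
  if (!is.finite(noise_cv) || noise_cv < 0) {
    stop("`noise_cv` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      noise_cv = noise_cv,
      groups = if (is.null(mfi_band_mixing)) groups else 0:4,
      mfi_band_mixing = mfi_band_mixing,
      n_total = if (is.null(n_total)) NULL else as.integer(n_total),
      sampling_schedule = sampling_schedule,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a labelled synthetic cohort
#'
#' Without band mixing, generates `n_per_group` trajectories for each
#' requested group using the per-group default parameters. With
#' `mfi_band_mixing`, draws a baseline MFI band for each trajectory (band
#' marginals proportional to the reference band totals), draws the pattern
#' from the band's mixing row, draws a baseline MFI uniformly within the
#' band, and rescales the group's default curve to that baseline.
#'
#' Reproducible: identical configs (including seed) give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A list of daily (or schedule-sampled) [trajectory_series()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- if (is.null(config$mfi_band_mixing)) {
    specs <- data.frame(
      group = rep(config$groups, each = config$n_per_group)
    )
    specs$scale <- 1
    make_cohort(specs, config)
  } else {
    probs <- config$mfi_band_mixing
    bounds <- attr(probs, "bounds")
    n <- config$n_total
    band_marginal <- rowSums(reference_band_counts())
    band_marginal <- band_marginal / sum(band_marginal)
    specs <- with_seed(config$seed + 1L, {
      band <- sample.int(nrow(probs), n, replace = TRUE, prob = band_marginal)
      group <- vapply(band, function(b) {
        sample(0:4, 1L, prob = probs[b, ])
      }, integer(1))
      baseline <- stats::runif(n, bounds[band], bounds[band + 1L])
      data.frame(band = rownames(probs)[band], group = group,
        baseline = baseline)
    })
    specs$scale <- specs$baseline /
      vapply(specs$group, function(g) {
        default_pattern_params(g)$baseline_mfi
      }, numeric(1))
    make_cohort(specs, config)
  }
  cohort
}

make_cohort <- function(specs, config) {
  n <- nrow(specs)
  traj_seeds <- with_seed(
    config$seed,
    sample.int(.Machine$integer.max, n)
  )
  lapply(seq_len(n), function(i) {
    params <- scale_params(
      default_pattern_params(specs$group[i]),
      specs$scale[i]
    )
    s <- generate_trajectory(params,
      noise_cv = config$noise_cv, seed = traj_seeds[i],
      patient_id = sprintf("P%03d", i), dsa_label = "total"
    )
    if (!is.null(config$sampling_schedule)) {
      s <- apply_sampling_schedule(s, config$sampling_schedule)
    }
    if (!is.null(specs$band)) attr(s, "band") <- specs$band[i]
    s
  })
}

# multiply all MFI-scale fields by a common factor; preserves the shape and
# the group invariants (which are scale-free)
scale_params <- function(params, factor) {
  if (identical(factor, 1)) {
    return(params)
  }
  params$baseline_mfi <- params$baseline_mfi * factor
  params$peak_amplitude <- params$peak_amplitude * factor
  params$plateau_level <- params$plateau_level * factor
  params
}

#' Restrict a trajectory to a sampling schedule
#'
#' Keeps exactly the scheduled observation days; values at retained days are
#' unchanged. All scheduled days must be present in the series.
#'
#' @param series A [trajectory_series()].
#' @param schedule Non-empty set of days within `[1, 50]`.
#' @return The sparse [trajectory_series()].
#' @export
apply_sampling_schedule <- function(series, schedule) {
  stopifnot(inherits(series, "trajectory_series"))
  schedule <- check_days_subset(schedule, arg = "schedule")
  missing_days <- setdiff(schedule, series$days)
  if (length(missing_days) > 0L) {
    stop("schedule days not observed in the series: ",
      paste(missing_days, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- series$days %in% schedule
  trajectory_series(series$patient_id, series$dsa_label,
    series$days[keep], series$mfi[keep],
    group = series$group
  )
}
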