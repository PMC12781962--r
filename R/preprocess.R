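#' Interpolate a sparse trajectory onto the daily grid
#'
#' Fills every day from 1 to 50: observed days keep their exact values,
#' interior gaps are filled by linear interpolation, and days before the
#' first (after the last) observation are filled by constant extension of
#' the nearest observed value. Constant extension, rather than linear
#' extrapolation, guarantees the output never leaves the observed MFI range
#' (and in particular never goes negative).
#'
#' Idempotent: an already-daily series is returned unchanged.
#'
#' @param series A [trajectory_series()] with at least 2 observed days.
#' @return A daily [trajectory_series()].
#' @export
interpolate_daily <- function(series) {
  stopifnot(inherits(series, "trajectory_series"))
  if (length(series$days) < 2L) {
    stop("interpolation needs at least 2 observed days", call. = FALSE)
  }
  if (is_daily(series)) {
    return(series)
  }
  daily <- stats::approx(series$days, series$mfi,
    xout = seq_len(DAY_MAX),
    method = "linear", rule = 2
  )$y
  trajectory_series(series$patient_id, series$dsa_label,
    seq_len(DAY_MAX), daily,
    group = series$group
  )
}

#' Sum a patient's individual DSA series into a total-DSA series
#'
#' At each day observed in any input series, the total is the sum over DSAs
#' of that day's value; a DSA missing that day contributes its linearly
#' interpolated value (constant extension outside its observed range,
#' matching [interpolate_daily()]). The result carries `dsa_label "total"`.
#'
#' The group label is kept only if all inputs agree on it.
#'
#' @param series_list Non-empty list of [trajectory_series()] sharing one
#'   `patient_id`. Patients typically carry 1-7 DSAs.
#' @return A [trajectory_series()] with `dsa_label = "total"` on the union
#'   of observed days.
#' @export
sum_dsa <- function(series_list) {
  if (!is.list(series_list) || length(series_list) == 0L) {
    stop("`series_list` must be a non-empty list of trajectories",
      call. = FALSE
    )
  }
  stopifnot(all(vapply(series_list, inherits, logical(1), "trajectory_series")))
  ids <- unique(vapply(series_list, `[[`, character(1), "patient_id"))
  if (length(ids) != 1L) {
    stop("all series must share one patient_id; got: ",
      paste(ids, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(series_list) > 7L) {
    warning("more than 7 DSAs for patient ", ids,
      "; expected between 1 and 7",
      call. = FALSE
    )
  }
  days <- sort(unique(unlist(lapply(series_list, `[[`, "days"))))
  per_dsa <- vapply(series_list, function(s) {
    if (length(s$days) == 1L) {
      # single observation: constant extension everywhere
      rep(s$mfi, length(days))
    } else {
      stats::approx(s$days, s$mfi, xout = days, method = "linear", rule = 2)$y
    }
  }, numeric(length(days)))
  total <- rowSums(matrix(per_dsa, nrow = length(days)))
  groups <- unique(vapply(series_list, `[[`, integer(1), "group"))
  group <- if (length(groups) == 1L && !is.na(groups)) groups else NA
  trajectory_series(ids, "total", days, total, group = group)
}
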