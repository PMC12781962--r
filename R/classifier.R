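#' Per-group mean trajectories (centroids)
#'
#' The classification reference: for each group present in the cohort, the
#' centroid is the arithmetic per-day mean of that group's daily series.
#'
#' @param cohort List of daily, labelled [trajectory_series()].
#' @param groups Optional subset of groups to build centroids for; default
#'   every label present in the cohort.
#' @return An object of class `centroid_set`: a named list (names = group
#'   ids) of daily `trajectory_series`, one centroid per group.
#' @export
compute_centroids <- function(cohort, groups = NULL) {
  stopifnot(is.list(cohort), length(cohort) > 0L)
  labels <- vapply(cohort, `[[`, integer(1), "group")
  if (anyNA(labels)) {
    stop("every series must carry a group label to build centroids",
      call. = FALSE
    )
  }
  if (!all(vapply(cohort, is_daily, logical(1)))) {
    stop("centroids require daily series (days 1-50); interpolate first",
      call. = FALSE
    )
  }
  if (is.null(groups)) {
    groups <- sort(unique(labels))
  } else {
    groups <- sort(unique(vapply(groups, check_group, integer(1))))
    missing_g <- setdiff(groups, labels)
    if (length(missing_g) > 0L) {
      stop("no series labelled with group(s): ",
        paste(missing_g, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (length(groups) == 0L) {
    stop("at least one group is required", call. = FALSE)
  }
  centroids <- lapply(groups, function(g) {
    members <- cohort[labels == g]
    mat <- vapply(members, `[[`, numeric(DAY_MAX), "mfi")
    trajectory_series(
      patient_id = "centroid", dsa_label = "total",
      days = seq_len(DAY_MAX), mfi = rowMeans(as.matrix(mat)),
      group = g
    )
  })
  names(centroids) <- as.character(groups)
  structure(centroids, class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf(
    "<centroid_set> groups: %s\n",
    paste(names(x), collapse = ", ")
  ))
  invisible(x)
}

#' Restrict a daily series to a subset of monitoring days
#'
#' @param series A [trajectory_series()] containing all requested days.
#' @param days Non-empty set of days within `[1, 50]`; duplicates removed,
#'   output always in increasing day order.
#' @return The reduced [trajectory_series()].
#' @export
reduce_to_days <- function(series, days) {
  stopifnot(inherits(series, "trajectory_series"))
  days <- check_days_subset(days)
  missing_days <- setdiff(days, series$days)
  if (length(missing_days) > 0L) {
    stop("series does not contain day(s): ",
      paste(missing_days, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- series$days %in% days
  trajectory_series(series$patient_id, series$dsa_label,
    series$days[keep], series$mfi[keep],
    group = series$group
  )
}

#' Nearest-centroid classification of one trajectory
#'
#' Reduces the series and every centroid to the same monitoring days,
#' computes the DTW distance to each centroid, and returns the group of the
#' nearest one. Exact distance ties are broken toward the smallest group id.
#'
#' @param series A [trajectory_series()] (daily, or already reduced to
#'   `days`).
#' @param centroids A [compute_centroids()] result.
#' @param days Monitoring days to classify on; default the full daily grid.
#' @param ... Passed to [dtw_distance()] (e.g. `cost`, `normalize`).
#' @return The predicted group id (integer).
#' @export
classify <- function(series, centroids, days = seq_len(DAY_MAX), ...) {
  stopifnot(inherits(centroids, "centroid_set"))
  days <- check_days_subset(days)
  reduced <- if (identical(series$days, days)) {
    series
  } else {
    reduce_to_days(series, days)
  }
  group_ids <- as.integer(names(centroids))
  ord <- order(group_ids) # tie rule: smallest group id wins
  group_ids <- group_ids[ord]
  dists <- vapply(centroids[ord], function(cen) {
    dtw_distance(reduced$mfi, reduce_to_days(cen, days)$mfi, ...)$distance
  }, numeric(1))
  group_ids[which.min(dists)]
}

#' Classify every series in a cohort
#'
#' Applies [classify()] to each series and scores the predictions against
#' the true labels. In `"resubstitution"` mode (the default) the supplied
#' centroids are used for every series; in `"loo"` (leave-one-out) mode the
#' centroids are recomputed for each series with that series excluded,
#' giving an honest generalisation estimate.
#'
#' @param cohort List of daily, labelled [trajectory_series()].
#' @param centroids A `centroid_set`; if `NULL`, computed from `cohort`
#'   (restricted to `groups`).
#' @param days Monitoring days used for classification.
#' @param groups Classification universe; default `1:4` (the four dynamic
#'   patterns — the flat no-response group 0 is assumed known from its low,
#'   flat MFI and excluded unless requested).
#' @param mode `"resubstitution"` or `"loo"`.
#' @param ... Passed to [dtw_distance()].
#' @return A `classification_outcome` (see [accuracy()]) with the series
#'   ids, truths, predictions and the monitoring days attached.
#' @export
classify_cohort <- function(cohort, centroids = NULL, days = seq_len(DAY_MAX),
                            groups = 1:4,
                            mode = c("resubstitution", "loo"), ...) {
  mode <- match.arg(mode)
  days <- check_days_subset(days)
  groups <- sort(unique(vapply(groups, check_group, integer(1))))
  labels <- vapply(cohort, `[[`, integer(1), "group")
  keep <- which(labels %in% groups)
  if (length(keep) == 0L) {
    stop("no series labelled with the requested groups", call. = FALSE)
  }
  subset <- cohort[keep]
  truths <- labels[keep]
  # the default local cost takes a distance-only fast path; any non-default
  # DTW option falls back to the general classify() route
  fast <- length(list(...)) == 0L
  predictions <- if (mode == "resubstitution") {
    if (is.null(centroids)) {
      centroids <- compute_centroids(subset, groups = groups)
    }
    if (fast && all(vapply(subset, is_daily, logical(1)))) {
      classify_fast(subset, centroids, days)
    } else {
      vapply(subset, classify, integer(1),
        centroids = centroids, days = days, ...
      )
    }
  } else {
    vapply(seq_along(subset), function(i) {
      cen <- compute_centroids(subset[-i], groups = groups)
      classify(subset[[i]], cen, days = days, ...)
    }, integer(1))
  }
  out <- accuracy(predictions, truths)
  out$patient_id <- vapply(subset, `[[`, character(1), "patient_id")
  out$days <- days
  out$mode <- mode
  out
}

# inner loop shared by the sweep/search stages: daily series, absolute-cost
# unnormalised DTW, centroids reduced once per day subset
classify_fast <- function(subset, centroids, days) {
  group_ids <- sort(as.integer(names(centroids)))
  cen_red <- lapply(as.character(group_ids), function(g) {
    centroids[[g]]$mfi[days] # daily grid: day d sits at index d
  })
  vapply(subset, function(s) {
    v <- s$mfi[days]
    d <- vapply(cen_red, function(w) .dtw_dist_cpp(v, w, FALSE), numeric(1))
    group_ids[which.min(d)]
  }, integer(1))
}

#' Classification accuracy
#'
#' The accuracy metric `C = Ncp / Np * 100`, where `Ncp` is the number of
#' correct predictions and `Np` the number of all predictions.
#'
#' @param predictions,truths Equal-length, non-empty vectors of group ids.
#' @return An object of class `classification_outcome`: list with
#'   `predictions`, `truths`, `Ncp`, `Np` and `C` (percent).
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) == 0L) {
    stop("`predictions` must be non-empty", call. = FALSE)
  }
  if (length(predictions) != length(truths)) {
    stop("`predictions` and `truths` must have equal length", call. = FALSE)
  }
  ncp <- sum(predictions == truths)
  np <- length(predictions)
  structure(
    list(
      predictions = as.integer(predictions),
      truths = as.integer(truths),
      Ncp = ncp, Np = np, C = ncp / np * 100
    ),
    class = "classification_outcome"
  )
}

#' @export
print.classification_outcome <- function(x, ...) {
  cat(sprintf(
    "<classification_outcome> C = %.1f%% (Ncp = %d / Np = %d)%s\n",
    x$C, x$Ncp, x$Np,
    if (!is.null(x$days)) {
      paste0(" on days {", paste(x$days, collapse = ", "), "}")
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Band-level summary of pattern counts
#'
#' Converts a table of per-MFI-band, per-group DSA counts into per-band
#' group percentages (rounded to integers) and broader-category percentages:
#' no response (group 0), modulated (groups 1 + 2) and sustained (groups
#' 3 + 4). Broader percentages are computed from the summed counts before
#' rounding, so they are not sums of the rounded per-group columns.
#'
#' @param counts Matrix or data frame of non-negative integer counts; one
#'   row per band (rownames = band labels), columns named `"0"` to `"4"`.
#' @return A data frame with one row per band: `band`, `total`, `pct_0` ..
#'   `pct_4`, `pct_no_response`, `pct_modulated`, `pct_sustained`, and
#'   `empty` flagging bands with zero total (percentages `NA`).
#' @export
summarize_bands <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- as.character(seq_len(ncol(counts)) - 1L)
  }
  if (!identical(colnames(counts), as.character(0:4))) {
    stop("`counts` must have one column per group, named \"0\" to \"4\"",
      call. = FALSE
    )
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  bands <- rownames(counts) %||% paste0("band", seq_len(nrow(counts)))
  totals <- rowSums(counts)
  # half-up rounding, the convention of reported percentage tables
  # (base round() is half-to-even: round(12.5) == 12)
  pct <- function(x, tot) ifelse(tot > 0, floor(x / tot * 100 + 0.5), NA_real_)
  out <- data.frame(
    band = bands,
    total = as.integer(totals),
    pct_0 = pct(counts[, "0"], totals),
    pct_1 = pct(counts[, "1"], totals),
    pct_2 = pct(counts[, "2"], totals),
    pct_3 = pct(counts[, "3"], totals),
    pct_4 = pct(counts[, "4"], totals),
    pct_no_response = pct(counts[, "0"], totals),
    pct_modulated = pct(counts[, "1"] + counts[, "2"], totals),
    pct_sustained = pct(counts[, "3"] + counts[, "4"], totals),
    empty = totals == 0,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  if (any(out$empty)) {
    warning("band(s) with zero total: ",
      paste(out$band[out$empty], collapse = ", "),
      "; percentages undefined",
      call. = FALSE
    )
  }
  out
}
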