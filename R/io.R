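#' Write trajectories as long-format CSV
#'
#' One row per observation, columns `patient_id`, `dsa_label`, `group`,
#' `day`, `mfi`. MFI is written with at most 2 fractional digits (Luminex
#' MFI precision beyond that carries no clinical meaning).
#'
#' @param cohort List of [trajectory_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(cohort, path) {
  df <- cohort_to_df(cohort)
  df$mfi <- round(df$mfi, 2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from long-format CSV
#'
#' Expects the header `patient_id, dsa_label, group, day, mfi` (`group` may
#' be empty for unlabelled data). Rows are validated — non-numeric MFI,
#' days outside `[1, 50]`, or inconsistent group labels within one series
#' are rejected with the offending row number. Observations are grouped
#' into one series per `(patient_id, dsa_label)` pair; repeated
#' measurements on one day are averaged.
#'
#' @param path CSV file path.
#' @return List of [trajectory_series()] (empty list for a header-only
#'   file).
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "dsa_label", "group", "day", "mfi")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(df) == 0L) {
    return(list())
  }
  df$patient_id <- as.character(df$patient_id)
  df$dsa_label <- as.character(df$dsa_label)
  # data row i of the file is line i + 1 (header)
  check_rows <- function(bad, what) {
    if (any(bad)) {
      stop(what, " in row(s): ",
        paste(utils::head(which(bad), 5L) + 1L, collapse = ", "),
        call. = FALSE
      )
    }
  }
  day_num <- suppressWarnings(as.numeric(df$day))
  check_rows(is.na(day_num) | day_num != round(day_num), "non-integer day")
  check_rows(day_num < 1 | day_num > DAY_MAX,
    paste0("day outside [1, ", DAY_MAX, "]")
  )
  mfi_num <- suppressWarnings(as.numeric(df$mfi))
  check_rows(is.na(mfi_num), "non-numeric mfi")
  check_rows(mfi_num < 0, "negative mfi")
  group_num <- suppressWarnings(as.integer(df$group))
  check_rows(
    !is.na(df$group) & df$group != "" & is.na(group_num),
    "non-integer group"
  )
  check_rows(!is.na(group_num) & !(group_num %in% 0:4),
    "group outside 0-4"
  )
  key <- paste(df$patient_id, df$dsa_label, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
    function(idx) {
      g <- unique(group_num[idx])
      g <- g[!is.na(g)]
      if (length(g) > 1L) {
        stop("inconsistent group labels for patient ",
          df$patient_id[idx[1L]], " DSA ", df$dsa_label[idx[1L]],
          call. = FALSE
        )
      }
      trajectory_series(
        df$patient_id[idx[1L]], df$dsa_label[idx[1L]],
        day_num[idx], mfi_num[idx],
        group = if (length(g) == 1L) g else NA
      )
    }
  )
  names(out) <- NULL
  out
}

#' Daily total-DSA series for one patient
#'
#' Combines a patient's per-DSA measurements into one daily total-DSA
#' series. Two orders of operations are available:
#' `"interpolate_then_sum"` (default) interpolates each DSA onto the union
#' of observed days before summing ([sum_dsa()]) and then fills the daily
#' grid; `"sum_then_interpolate"` first sums over DSAs at the days common
#' to all of them, then interpolates the total. The two agree exactly when
#' all DSAs share the same observation days.
#'
#' @param series_list Non-empty list of one patient's per-DSA
#'   [trajectory_series()].
#' @param order Order of summation and interpolation.
#' @return A daily [trajectory_series()] with `dsa_label = "total"`.
#' @export
patient_total_daily <- function(series_list,
                                order = c(
                                  "interpolate_then_sum",
                                  "sum_then_interpolate"
                                )) {
  order <- match.arg(order)
  if (order == "interpolate_then_sum") {
    total <- sum_dsa(series_list)
  } else {
    common <- Reduce(intersect, lapply(series_list, `[[`, "days"))
    if (length(common) < 2L) {
      stop("sum_then_interpolate needs at least 2 days common to all DSAs",
        call. = FALSE
      )
    }
    total <- sum_dsa(lapply(series_list, reduce_to_days, days = common))
  }
  interpolate_daily(total)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with the fields accepted by
#'   [run_full_experiment()]'s `config` argument.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  yaml::read_yaml(path)
}

#' Run the full three-stage monitoring-day experiment
#'
#' Replays the complete analysis on one cohort: (1) a section-based sweep
#' of the number of monitoring days `N` under all three day-selection
#' strategies; (2) greedy augmentation from the best deterministic 2-day
#' subset; (3) comparison against the built-in clinical regimen catalogue.
#' All tables, the configuration and every derived seed are written to
#' `out_dir`, and the run is byte-identical given the same configuration.
#'
#' @param config A list (or path to a YAML file, see [read_run_config()])
#'   with entries:
#'   * `cohort`: either `synthetic` (arguments for [cohort_config()],
#'     seed defaulting to the master seed) or `csv` (path to long-format
#'     per-DSA measurements, combined per patient with
#'     [patient_total_daily()]).
#'   * `classification`: optional; `groups` (default `1:4`), `mode`
#'     (`"resubstitution"` or `"loo"`).
#'   * `search`: optional; `strategies`, `repeats` (default 100), `N_min`,
#'     `N_max`, `base` (default: best deterministic 2-day subset),
#'     `candidates`, `max_size` (default 5).
#'   * `seed`: master seed (mandatory).
#'   * `out_dir`: output directory (created if needed).
#' @return Invisibly, a list with the cohort and the three stage tables.
#' @export
run_full_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) {
    stop("`config$seed` (master seed) is mandatory", call. = FALSE)
  }
  if (is.null(config$out_dir)) {
    stop("`config$out_dir` is required", call. = FALSE)
  }
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cls <- config$classification %||% list()
  groups <- as.integer(cls$groups %||% 1:4)
  mode <- cls$mode %||% "resubstitution"
  search <- config$search %||% list()
  strategies <- search$strategies %||% c("random", "middle", "first")
  repeats <- as.integer(search$repeats %||% 100L)
  N_range <- seq(
    as.integer(search$N_min %||% 2L),
    as.integer(search$N_max %||% 50L)
  )
  max_size <- as.integer(search$max_size %||% 5L)

  # --- cohort ------------------------------------------------------------
  if (!is.null(config$cohort$synthetic)) {
    args <- config$cohort$synthetic
    args$seed <- args$seed %||% seed
    cc <- do.call(cohort_config, args)
    cohort <- generate_cohort(cc)
  } else if (!is.null(config$cohort$csv)) {
    raw <- read_trajectories(config$cohort$csv)
    by_patient <- split(
      raw,
      vapply(raw, `[[`, character(1), "patient_id")
    )
    cohort <- lapply(by_patient, patient_total_daily)
    names(cohort) <- NULL
  } else {
    stop("config$cohort must provide exactly one of `synthetic` or `csv`",
      call. = FALSE
    )
  }
  cohort <- lapply(cohort, function(s) {
    if (is_daily(s)) s else interpolate_daily(s)
  })
  write_trajectories(cohort, file.path(out_dir, "cohort.csv"))

  labels <- vapply(cohort, `[[`, integer(1), "group")
  universe <- cohort[labels %in% groups]
  centroids <- compute_centroids(universe, groups = groups)

  # --- stage 1: section sweep -------------------------------------------
  stage1 <- do.call(rbind, lapply(strategies, function(strat) {
    sweep_sections(universe,
      strategy = strat, N_range = N_range,
      repeats = repeats, seed = seed + 1L,
      centroids = centroids, groups = groups, mode = mode
    )
  }))
  utils::write.csv(stage1, file.path(out_dir, "stage1_accuracy_by_N.csv"),
    row.names = FALSE
  )

  # --- stage 2: greedy augmentation from the best 2-day subset ----------
  base <- search$base
  if (is.null(base)) {
    scheme2 <- split_sections(2L)
    two_day <- lapply(c("first", "middle"), function(strat) {
      days <- select_days(scheme2, strat)
      list(
        strategy = strat, days = days,
        C = evaluate_subset(universe, days,
          centroids = centroids,
          groups = groups, mode = mode
        )$C
      )
    })
    # ties resolved toward the first-point strategy
    base <- two_day[[which.max(vapply(two_day, `[[`, numeric(1), "C"))]]$days
  }
  base <- check_days_subset(base, arg = "base")
  candidates <- search$candidates %||% setdiff(seq_len(DAY_MAX), base)
  stage2 <- greedy_augment(universe,
    base = base, candidate_days = candidates,
    max_size = max_size, centroids = centroids, groups = groups, mode = mode
  )
  utils::write.csv(stage2$steps, file.path(out_dir, "stage2_steps.csv"),
    row.names = FALSE
  )
  if (!is.null(stage2$replacements)) {
    utils::write.csv(stage2$replacements,
      file.path(out_dir, "stage2_replacements.csv"),
      row.names = FALSE
    )
  }

  # --- stage 3: regimen comparison --------------------------------------
  stage3 <- compare_regimens(universe,
    centroids = centroids, groups = groups,
    mode = mode
  )
  utils::write.csv(stage3, file.path(out_dir, "stage3_regimens.csv"),
    row.names = FALSE
  )

  # the report's location is the out_dir; dropping it from the embedded
  # config keeps two runs of one configuration byte-identical
  report <- list(
    config = config[setdiff(names(config), "out_dir")],
    seed = seed,
    n_series = length(cohort),
    n_classified = length(universe),
    groups = groups,
    stage2_base = base,
    stage2_days = stage2$days,
    stage2_C = round(stage2$best$C, 1),
    stage3_best = stage3$name[1L],
    full_series_C = round(
      evaluate_subset(universe, seq_len(DAY_MAX),
        centroids = centroids,
        groups = groups, mode = mode
      )$C, 1
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    cohort = cohort, stage1 = stage1, stage2 = stage2,
    stage3 = stage3, report = report
  ))
}
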