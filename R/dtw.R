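#' Dynamic time warping distance
#'
#' Minimal accumulated local cost over all monotone warping paths aligning
#' two numeric sequences, computed by full dynamic programming (no warping
#' window; sequences here are at most 50 points). The local cost is the
#' absolute difference by default; squared difference is available via
#' `cost = "squared"`. The distance is not normalised by path length by
#' default — reduced series and centroids are always compared at equal
#' length, where normalisation cannot change rankings — but
#' `normalize = TRUE` divides by the path length.
#'
#' @param a,b Non-empty numeric vectors of finite values.
#' @param cost Local cost: `"abs"` (default) or `"squared"`.
#' @param normalize Divide the accumulated cost by the path length?
#' @return An object of class `dtw_result`: list with `distance` (the
#'   accumulated cost) and `path` (two-column matrix of 1-based index pairs
#'   from `(1, 1)` to `(length(a), length(b))`, steps in
#'   `{(+1,0), (0,+1), (+1,+1)}`; ties between equal-cost paths resolved
#'   toward the diagonal step).
#' @export
dtw_distance <- function(a, b, cost = c("abs", "squared"), normalize = FALSE) {
  cost <- match.arg(cost)
  check_sequence(a, "a")
  check_sequence(b, "b")
  res <- .dtw_cpp(as.numeric(a), as.numeric(b),
    squared = (cost == "squared"), normalize = normalize
  )
  structure(
    list(
      distance = res$distance, path = res$path,
      cost = cost, normalized = normalize
    ),
    class = "dtw_result"
  )
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf(
    "<dtw_result> distance %.6g (%s cost%s), path length %d\n",
    x$distance, x$cost, if (x$normalized) ", normalized" else "",
    nrow(x$path)
  ))
  invisible(x)
}

check_sequence <- function(x, nm) {
  if (length(x) == 0L) {
    stop("`", nm, "` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`", nm, "` must contain only finite numeric values", call. = FALSE)
  }
  invisible(x)
}

#' Brute-force DTW by exhaustive path enumeration
#'
#' Test oracle: recursively enumerates every admissible warping path from
#' `(1, 1)` to `(n, m)` and returns the minimum accumulated cost. No
#' memoisation is used, so the computation shares nothing with the dynamic
#' programming in [dtw_distance()] beyond the cost definition. Refuses
#' sequences longer than 8 points (the path count grows exponentially).
#'
#' @inheritParams dtw_distance
#' @return A `dtw_result` (path = one cost-minimal path, found with the
#'   diagonal step explored first).
#' @export
dtw_brute_force <- function(a, b, cost = c("abs", "squared"),
                            normalize = FALSE) {
  cost <- match.arg(cost)
  check_sequence(a, "a")
  check_sequence(b, "b")
  n <- length(a)
  m <- length(b)
  if (n > 8L || m > 8L) {
    stop("brute-force enumeration is limited to sequences of length <= 8",
      call. = FALSE
    )
  }
  local_cost <- if (cost == "squared") {
    function(i, j) (a[i] - b[j])^2
  } else {
    function(i, j) abs(a[i] - b[j])
  }
  best <- Inf
  best_path <- NULL
  recurse <- function(i, j, acc, path) {
    acc <- acc + local_cost(i, j)
    path[[length(path) + 1L]] <- c(i, j)
    if (i == n && j == m) {
      if (acc < best) {
        best <<- acc
        best_path <<- path
      }
      return(invisible(NULL))
    }
    # diagonal first so the first minimal path found prefers diagonal steps
    if (i < n && j < m) recurse(i + 1L, j + 1L, acc, path)
    if (i < n) recurse(i + 1L, j, acc, path)
    if (j < m) recurse(i, j + 1L, acc, path)
    invisible(NULL)
  }
  recurse(1L, 1L, 0, list())
  path <- do.call(rbind, best_path)
  structure(
    list(
      distance = if (normalize) best / nrow(path) else best,
      path = path, cost = cost, normalized = normalize
    ),
    class = "dtw_result"
  )
}
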