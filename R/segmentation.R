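#' Segmentation parameters
#'
#' @param window smoothing window in frames (>= 2); also the minimum spacing
#'   between kept minima and between shared boundary points.
#' @param min_prominence_sd minimum amplitude excursion, in units of the
#'   smoothed signal's SD, required between two consecutive minima for both
#'   to count as genuine stopping points (default 0.1).
#' @param max_pair_gap largest frame distance at which one member's minimum
#'   can be matched to the other's (default = `window`).
#' @return An object of class `"segmentation_params"`.
#' @export
segmentation_params <- function(window, min_prominence_sd = 0.1,
                                max_pair_gap = window) {
  window <- as.integer(window)
  if (!is.finite(window) || window < 2L)
    stop("`window` must be an integer >= 2", call. = FALSE)
  if (!is.finite(min_prominence_sd) || min_prominence_sd <= 0)
    stop("`min_prominence_sd` must be > 0", call. = FALSE)
  max_pair_gap <- as.integer(max_pair_gap)
  if (!is.finite(max_pair_gap) || max_pair_gap < 1L)
    stop("`max_pair_gap` must be a positive integer", call. = FALSE)
  structure(list(window = window, min_prominence_sd = min_prominence_sd,
                 max_pair_gap = max_pair_gap),
            class = "segmentation_params")
}

#' Moving-average smoothing
#'
#' Centered moving average that eliminates short-term trends before minima
#' detection. Windows shrink symmetrically at the signal edges, so the output
#' has the same length as the input.
#'
#' @param signal a [motion_signal()].
#' @param window window length in frames, `2 <= window <= length(signal)`.
#' @return A smoothed `motion_signal` (no longer flagged as z-scored: the
#'   moving average shrinks the SD).
#' @export
smooth_signal <- function(signal, window) {
  stopifnot(inherits(signal, "motion_signal"))
  window <- as.integer(window)
  if (window < 2L) stop("`window` must be >= 2", call. = FALSE)
  if (window > length(signal$values))
    stop("`window` exceeds signal length", call. = FALSE)
  motion_signal(moving_avg(signal$values, window), fps = signal$fps,
                member_id = signal$member_id, dyad_id = signal$dyad_id)
}

#' Data-adaptive smoothing window
#'
#' Chooses the moving-average window from the signals' own time scale: the
#' smallest lag at which the mean of the two members' autocorrelation
#' functions falls below 1/e, clamped to `[0.25 s, 2 s]` (in frames). White
#' noise therefore gets the floor and very slow signals the ceiling. The rule
#' is deterministic and replaces opaque smoothing-factor heuristics found in
#' closed-source toolboxes.
#'
#' @param a,b z-scored [motion_signal()]s of the two members.
#' @return Window length in frames (integer).
#' @export
choose_window <- function(a, b) {
  stopifnot(inherits(a, "motion_signal"), inherits(b, "motion_signal"))
  fps <- a$fps
  if (abs(fps - b$fps) > 1e-9) stop("members differ in fps", call. = FALSE)
  lo <- max(2L, as.integer(round(0.25 * fps)))
  hi <- max(lo, as.integer(round(2 * fps)))
  if (pop_sd(a$values) < 1e-12 || pop_sd(b$values) < 1e-12)
    stop("degenerate signal: zero variance", call. = FALSE)
  lag_max <- min(hi + 1L, length(a$values) - 1L)
  acf1 <- stats::acf(a$values, lag.max = lag_max, plot = FALSE,
                     demean = TRUE)$acf[-1]
  acf2 <- stats::acf(b$values, lag.max = lag_max, plot = FALSE,
                     demean = TRUE)$acf[-1]
  m <- (acf1 + acf2) / 2
  below <- which(m < exp(-1))
  lag0 <- if (length(below)) below[1] else Inf
  as.integer(min(max(lag0, lo), hi))
}

#' Per-member stopping-point detection
#'
#' Finds the local minima of a smoothed, z-scored motion signal that qualify
#' as stopping/deceleration points: (1) the minimum's value is below zero
#' (slower than the member's average motion); (2) kept minima are at least
#' `window` frames apart -- when two candidates are closer, the deeper one is
#' kept; (3) between two consecutive kept minima the signal must rise by at
#' least `min_prominence_sd` SDs above the shallower of the two, otherwise
#' the shallower one is discarded as a fluctuation.
#'
#' @param smoothed a smoothed `motion_signal` (see [smooth_signal()]).
#' @param params a [segmentation_params()].
#' @return Integer vector of frame indices (possibly empty), sorted.
#' @export
find_member_minima <- function(smoothed, params) {
  stopifnot(inherits(smoothed, "motion_signal"),
            inherits(params, "segmentation_params"))
  v <- smoothed$values
  n <- length(v)
  w <- params$window
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[v[i] < v[i - 1L] & v[i] <= v[i + 1L]]
  cand <- cand[v[cand] < 0]
  if (!length(cand)) return(integer(0))
  # spacing: greedily keep the deepest minima first (ties: earlier frame)
  ord <- cand[order(v[cand], cand)]
  keep <- integer(0)
  for (m in ord) if (!length(keep) || all(abs(m - keep) >= w))
    keep <- c(keep, m)
  keep <- sort(keep)
  # prominence: require a rise of >= min_prominence_sd SDs between neighbours
  thr <- params$min_prominence_sd * stats::sd(v)
  while (length(keep) >= 2L) {
    exc <- vapply(seq_len(length(keep) - 1L), function(k) {
      seg <- v[keep[k]:keep[k + 1L]]
      max(seg) - max(v[keep[k]], v[keep[k + 1L]])
    }, numeric(1))
    bad <- which(exc < thr)
    if (!length(bad)) break
    k <- bad[1]
    # drop the shallower (higher-valued) of the offending pair; tie: later
    drop_idx <- if (v[keep[k]] > v[keep[k + 1L]]) k else k + 1L
    keep <- keep[-drop_idx]
  }
  keep
}

#' Match the two members' minima into shared boundaries
#'
#' Pairs the members' stopping points by mutual nearest neighbours, keeping
#' pairs whose frame distance is at most `max_pair_gap` (each minimum used at
#' most once). Consecutive shared boundaries must be at least `window` frames
#' apart; on conflict the pair with the smaller within-pair gap wins. Each
#' boundary is the rounded mean of the paired indices; segments are the
#' half-open frame intervals `[start, end)` delimited by the boundaries and
#' the recording endpoints.
#'
#' @param min_a,min_b sorted integer frame indices from
#'   [find_member_minima()].
#' @param params a [segmentation_params()].
#' @param n_frames recording length in frames.
#' @param fps sampling rate (stored for time conversion).
#' @return An object of class `"segmentation_result"` with elements
#'   `boundaries` (interior frame indices), `segments` (data frame with
#'   half-open `start`/`end` plus `start_s`/`end_s` in seconds), `window`,
#'   `n_frames`, `fps`, `minima_a`, `minima_b`. With no shared minima a
#'   single-segment result is returned with a warning.
#' @export
match_shared_minima <- function(min_a, min_b, params, n_frames, fps = 29.97) {
  stopifnot(inherits(params, "segmentation_params"))
  min_a <- sort(as.integer(min_a)); min_b <- sort(as.integer(min_b))
  pairs <- NULL
  if (length(min_a) && length(min_b)) {
    nn_ab <- vapply(min_a, function(x) which.min(abs(min_b - x)), integer(1))
    nn_ba <- vapply(min_b, function(x) which.min(abs(min_a - x)), integer(1))
    mutual <- which(nn_ba[nn_ab] == seq_along(min_a))
    if (length(mutual)) {
      ta <- min_a[mutual]; tb <- min_b[nn_ab[mutual]]
      gap <- abs(ta - tb)
      ok <- gap <= params$max_pair_gap
      pairs <- data.frame(ta = ta[ok], tb = tb[ok], gap = gap[ok])
    }
  }
  boundaries <- integer(0)
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[order(pairs$gap, pairs$ta), , drop = FALSE]
    kept_b <- numeric(0)
    kept_rows <- integer(0)
    for (r in seq_len(nrow(pairs))) {
      bnd <- (pairs$ta[r] + pairs$tb[r]) / 2
      if (!length(kept_b) || all(abs(bnd - kept_b) >= params$window)) {
        kept_b <- c(kept_b, bnd)
        kept_rows <- c(kept_rows, r)
      }
    }
    boundaries <- sort(unique(as.integer(round(kept_b))))
    boundaries <- boundaries[boundaries > 1L & boundaries <= n_frames]
  }
  if (!length(boundaries))
    warning("no shared minima: returning a single-segment result",
            call. = FALSE)
  starts <- c(1L, boundaries)
  ends <- c(boundaries, n_frames + 1L)
  segments <- data.frame(segment = seq_along(starts), start = starts,
                         end = ends,
                         start_s = (starts - 1L) / fps,
                         end_s = (ends - 1L) / fps)
  structure(list(boundaries = boundaries, segments = segments,
                 window = params$window, n_frames = as.integer(n_frames),
                 fps = fps, minima_a = min_a, minima_b = min_b),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d segments over %d frames (window %d frames)\n",
    nrow(x$segments), x$n_frames, x$window))
  invisible(x)
}

#' Segment a dyad's recording into shared movements
#'
#' Full segmentation pipeline for one dyad: choose the smoothing window from
#' the signals (unless given), smooth both members, detect each member's
#' stopping points, and match them into shared movement boundaries.
#'
#' @param a,b z-scored [motion_signal()]s of the two members (equal length).
#' @param params optional [segmentation_params()]; when `NULL` the window
#'   comes from [choose_window()] with default prominence and pairing
#'   tolerances.
#' @return A `"segmentation_result"` (see [match_shared_minima()]).
#' @export
segment_dyad <- function(a, b, params = NULL) {
  stopifnot(inherits(a, "motion_signal"), inherits(b, "motion_signal"))
  if (length(a$values) != length(b$values))
    stop("members' signals differ in length", call. = FALSE)
  if (is.null(params)) params <- segmentation_params(choose_window(a, b))
  sa <- smooth_signal(a, params$window)
  sb <- smooth_signal(b, params$window)
  ma <- find_member_minima(sa, params)
  mb <- find_member_minima(sb, params)
  match_shared_minima(ma, mb, params, n_frames = length(a$values),
                      fps = a$fps)
}
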