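#' Motion-energy signal
#'
#' Container for one member's motion-energy (MEA) time series: one value per
#' video frame, typically the count of pixels whose intensity changed by more
#' than a noise threshold between consecutive frames. Signals are Z-scored
#' before analysis so that dyad members with different body size contribute on
#' a common scale.
#'
#' @param values numeric vector, one value per frame (length >= 2, finite).
#' @param fps sampling rate in frames per second (default 29.97, NTSC video).
#' @param is_zscored logical; if `TRUE` the values must already have mean 0
#'   and SD 1 (checked to 1e-6 under either the population or the sample SD
#'   convention).
#' @param member_id,dyad_id optional identifiers carried through the pipeline.
#' @return An object of class `"motion_signal"`.
#' @seealso [zscore()], [compute_mea()], [read_mea_table()]
#' @export
motion_signal <- function(values, fps = 29.97, is_zscored = FALSE,
                          member_id = NA_character_, dyad_id = NA_character_) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  if (!all(is.finite(values)))
    stop("motion signal contains non-finite values", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  if (isTRUE(is_zscored)) {
    m <- mean(values)
    s0 <- pop_sd(values)
    s1 <- stats::sd(values)
    if (abs(m) > 1e-6 || min(abs(s0 - 1), abs(s1 - 1)) > 1e-6)
      stop("`is_zscored = TRUE` but values are not standardized", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), fps = as.numeric(fps),
         is_zscored = isTRUE(is_zscored),
         member_id = member_id, dyad_id = dyad_id),
    class = "motion_signal")
}

#' @export
print.motion_signal <- function(x, ...) {
  cat(sprintf("<motion_signal> %s/%s: %d frames @ %.2f fps (%.1f s)%s\n",
              x$dyad_id, x$member_id, length(x$values), x$fps,
              duration_s(x), if (x$is_zscored) ", z-scored" else ""))
  invisible(x)
}

#' @export
length.motion_signal <- function(x) length(x$values)

#' Signal duration in seconds
#' @param signal a [motion_signal()].
#' @return number of frames divided by the sampling rate.
#' @export
duration_s <- function(signal) length(signal$values) / signal$fps

# population (ddof = 0) or sample (ddof = 1) standard deviation
pop_sd <- function(x, ddof = 0) {
  sqrt(sum((x - mean(x))^2) / (length(x) - ddof))
}

#' Z-score a motion signal
#'
#' Centers and scales the signal to mean 0 and SD 1. The population SD
#' (divide by N) is the default convention; downstream correlations are
#' invariant to this choice, and `ddof = 1` gives the sample-SD convention.
#'
#' @param signal a [motion_signal()].
#' @param ddof degrees-of-freedom correction for the SD (0 = population,
#'   1 = sample).
#' @return A z-scored `motion_signal`. A constant signal (no movement) is a
#'   degenerate input and raises an error, mirroring the exclusion of
#'   non-moving recordings from analysis.
#' @export
zscore <- function(signal, ddof = 0) {
  stopifnot(inherits(signal, "motion_signal"))
  v <- signal$values
  s <- pop_sd(v, ddof)
  if (!is.finite(s) || s < 1e-12 * (1 + abs(mean(v))))
    stop("degenerate signal: zero variance (no movement)", call. = FALSE)
  motion_signal((v - mean(v)) / s, fps = signal$fps, is_zscored = TRUE,
                member_id = signal$member_id, dyad_id = signal$dyad_id)
}

#' Dyad record
#'
#' Bundles the two members' motion signals with their post-game liking
#' ratings (0-100 visual-analogue scale) and identifiers.
#'
#' @param a,b [motion_signal()]s of the two members; equal length and fps.
#' @param liking_a,liking_b liking each member reported for the other, 0-100.
#' @param dyad_id,session_id identifiers.
#' @return An object of class `"dyad_record"`.
#' @export
dyad_record <- function(a, b, liking_a = NA_real_, liking_b = NA_real_,
                        dyad_id = NA_character_, session_id = NA_character_) {
  stopifnot(inherits(a, "motion_signal"), inherits(b, "motion_signal"))
  if (length(a$values) != length(b$values))
    stop("members' signals differ in length; trim before constructing",
         call. = FALSE)
  if (abs(a$fps - b$fps) > 1e-9)
    stop("members' signals differ in sampling rate", call. = FALSE)
  for (l in c(liking_a, liking_b))
    if (!is.na(l) && (l < 0 || l > 100))
      stop("liking ratings must lie in [0, 100]", call. = FALSE)
  structure(list(a = a, b = b, liking_a = liking_a, liking_b = liking_b,
                 dyad_id = dyad_id, session_id = session_id),
            class = "dyad_record")
}

#' @export
print.dyad_record <- function(x, ...) {
  cat(sprintf("<dyad_record> %s: %d frames @ %.2f fps, liking (%.0f, %.0f)\n",
              x$dyad_id, length(x$a$values), x$a$fps, x$liking_a, x$liking_b))
  invisible(x)
}

# centered moving average with shrinking windows at the edges; O(n)
moving_avg <- function(v, w) {
  n <- length(v)
  w <- as.integer(w)
  if (w < 1L || w > n) stop("window must lie in [1, length]", call. = FALSE)
  hl <- (w - 1L) %/% 2L
  hr <- w %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(1L, i - hl)
  hi <- pmin(n, i + hr)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# moving average that skips NAs (windows that are all-NA stay NA)
moving_avg_na <- function(v, w) {
  n <- length(v)
  w <- as.integer(w)
  if (w < 1L) stop("window must be >= 1", call. = FALSE)
  ok <- !is.na(v)
  vv <- ifelse(ok, v, 0)
  hl <- (w - 1L) %/% 2L
  hr <- w %/% 2L
  cs <- cumsum(c(0, vv))
  cn <- cumsum(c(0L, as.integer(ok)))
  i <- seq_len(n)
  lo <- pmax(1L, i - hl)
  hi <- pmin(n, i + hr)
  cnt <- cn[hi + 1L] - cn[lo]
  out <- (cs[hi + 1L] - cs[lo]) / cnt
  out[cnt == 0L] <- NA_real_
  out
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's stream
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# fold a base seed and an index into a single 32-bit seed, deterministically
fold_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 7919
  as.integer(s %% 2147483647)
}
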