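#' Zero-lag synchronization (Pearson correlation)
#'
#' Synchronization of a dyad is the Pearson correlation between the two
#' members' z-scored motion-energy signals at zero lag: the degree to which
#' the members accelerate and decelerate at the same time.
#'
#' @param a,b [motion_signal()]s (or numeric vectors) of equal length >= 3.
#' @return Pearson r in `[-1, 1]`.
#' @export
sync_pearson <- function(a, b) {
  x <- signal_values(a); y <- signal_values(b)
  if (length(x) != length(y) || length(x) < 3L)
    stop("signals must have equal length >= 3", call. = FALSE)
  if (pop_sd(x) < 1e-12 || pop_sd(y) < 1e-12)
    stop("constant signal: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

signal_values <- function(x) {
  if (inherits(x, "motion_signal")) x$values else as.numeric(x)
}

#' Maximal lagged cross-correlation
#'
#' Pearson correlation over the overlapping region at every lag in
#' `[-max_lag_s, max_lag_s]` (in frames); returns the maximum and the lag at
#' which it occurs. A positive lag means member b's signal trails member a's
#' by that many frames. Ties are broken toward the smaller absolute lag, then
#' toward the negative lag; lags leaving fewer than 3 overlapping samples are
#' skipped.
#'
#' @param a,b [motion_signal()]s of equal length.
#' @param max_lag_s maximal absolute lag in seconds (default 5).
#' @return A list with `r` (max correlation) and `lag` (frames).
#' @export
sync_maxxcorr <- function(a, b, max_lag_s = 5) {
  x <- signal_values(a); y <- signal_values(b)
  if (length(x) != length(y)) stop("signals must have equal length",
                                   call. = FALSE)
  fps <- if (inherits(a, "motion_signal")) a$fps else 29.97
  if (max_lag_s < 0) stop("`max_lag_s` must be >= 0", call. = FALSE)
  n <- length(x)
  L <- as.integer(round(max_lag_s * fps))
  lags <- seq.int(-L, L)
  r <- rep(NA_real_, length(lags))
  for (k in seq_along(lags)) {
    l <- lags[k]
    if (l >= 0) { xi <- x[seq_len(n - l)]; yi <- y[seq_len(n - l) + l] }
    else { xi <- x[seq_len(n + l) - l]; yi <- y[seq_len(n + l)] }
    if (length(xi) < 3L) next
    if (pop_sd(xi) < 1e-12 || pop_sd(yi) < 1e-12) next
    r[k] <- stats::cor(xi, yi)
  }
  if (all(is.na(r))) stop("no lag with a computable correlation",
                          call. = FALSE)
  best <- max(r, na.rm = TRUE)
  cand <- lags[!is.na(r) & r == best]
  cand <- cand[order(abs(cand), cand)]
  list(r = best, lag = cand[1])
}

#' Movement complexity: Shannon entropy of the value distribution
#'
#' Complexity of a member's movement is the Shannon entropy (in bits) of the
#' empirical distribution of its motion-energy values:
#' `H(X) = -sum p(x) log2 p(x)` over the frequencies of each unique value.
#' Because MEA values derive from integer pixel counts, z-scored signals
#' remain discrete; `quantization` rounds values to that many decimals before
#' counting, which also makes the measure usable on continuous inputs.
#'
#' @param signal a [motion_signal()] or numeric vector (length >= 1).
#' @param quantization decimals kept before counting unique values
#'   (default 6).
#' @return Entropy in bits, `0 <= H <= log2(number of unique values)`.
#' @export
complexity_entropy <- function(signal, quantization = 6) {
  x <- signal_values(signal)
  if (!length(x)) stop("empty signal", call. = FALSE)
  x <- round(x, quantization)
  p <- tabulate(match(x, unique(x)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Dyadic complexity
#'
#' The two members' entropies are averaged into one dyadic complexity score;
#' within-dyad entropy differences are typically small relative to
#' between-dyad differences.
#'
#' @param a,b the members' [motion_signal()]s.
#' @param quantization passed to [complexity_entropy()].
#' @return Mean of the member entropies, in bits.
#' @export
complexity_dyad <- function(a, b, quantization = 6) {
  (complexity_entropy(a, quantization) +
     complexity_entropy(b, quantization)) / 2
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum of the absolute difference between the two samples' empirical
#' cumulative distribution functions: 0 for identical samples, 1 for samples
#' with disjoint supports. Sensitive to differences in both location and
#' shape, which makes it suitable for comparing movement segments.
#'
#' @param x,y non-empty numeric samples.
#' @return D in `[0, 1]`.
#' @export
ks_distance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples contain NA", call. = FALSE)
  sx <- sort(x); sy <- sort(y)
  z <- sort(unique(c(sx, sy)))
  fx <- findInterval(z, sx) / length(sx)
  fy <- findInterval(z, sy) / length(sy)
  max(abs(fx - fy))
}

segment_values <- function(signal, seg) {
  v <- signal_values(signal)
  lapply(seq_len(nrow(seg$segments)), function(k)
    v[seg$segments$start[k]:(seg$segments$end[k] - 1L)])
}

#' Segment-wise novelty scores
#'
#' Novelty quantifies how non-repetitive the movement is. For each member and
#' each segment `k >= 2`, the score is the mean K-S distance between the
#' distribution of the member's (raw z-scored, unsmoothed) values in segment
#' `k` and each earlier segment `j < k`. The two members' scores are averaged
#' into a dyadic score per segment; the first segment, having no
#' predecessors, inherits the second segment's score by convention. The
#' dyad-level novelty is the mean of the scores of segments `2..N` (the
#' duplicated first score is not counted twice).
#'
#' @param a,b the members' z-scored [motion_signal()]s.
#' @param seg a `"segmentation_result"` for the dyad.
#' @return A list of class `"novelty_series"`: `segment_scores` (dyadic score
#'   per segment), `member_scores` (segments x 2 matrix), and `dyad_novelty`
#'   (scalar; `NA` with a warning when there are fewer than 2 segments).
#' @export
novelty_series <- function(a, b, seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  n_seg <- nrow(seg$segments)
  if (n_seg < 2L) {
    warning("fewer than 2 segments: novelty undefined", call. = FALSE)
    scores <- rep(NA_real_, n_seg)
    return(structure(list(segment_scores = scores,
                          member_scores = cbind(a = scores, b = scores),
                          dyad_novelty = NA_real_),
                     class = "novelty_series"))
  }
  va <- segment_values(a, seg)
  vb <- segment_values(b, seg)
  score_one <- function(vals) {
    s <- rep(NA_real_, n_seg)
    for (k in 2:n_seg)
      s[k] <- mean(vapply(seq_len(k - 1L),
                          function(j) ks_distance(vals[[k]], vals[[j]]),
                          numeric(1)))
    s[1] <- s[2]
    s
  }
  ms <- cbind(a = score_one(va), b = score_one(vb))
  scores <- rowMeans(ms)
  structure(list(segment_scores = scores, member_scores = ms,
                 dyad_novelty = mean(scores[-1])),
            class = "novelty_series")
}

#' Segment-wise synchronization and complexity
#'
#' Per segment: the Pearson correlation between the members within the
#' segment (NA for segments shorter than 3 frames or with a constant member)
#' and the mean of the members' entropies within the segment.
#'
#' @inheritParams novelty_series
#' @param quantization passed to [complexity_entropy()].
#' @return A data frame with one row per segment: `segment`, `start_s`,
#'   `end_s`, `sync`, `complexity`.
#' @export
sync_complexity_series <- function(a, b, seg, quantization = 6) {
  stopifnot(inherits(seg, "segmentation_result"))
  va <- segment_values(a, seg)
  vb <- segment_values(b, seg)
  n_seg <- nrow(seg$segments)
  sync <- vapply(seq_len(n_seg), function(k) {
    x <- va[[k]]; y <- vb[[k]]
    if (length(x) < 3L || pop_sd(x) < 1e-12 || pop_sd(y) < 1e-12)
      return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  cx <- vapply(seq_len(n_seg), function(k)
    (complexity_entropy(va[[k]], quantization) +
       complexity_entropy(vb[[k]], quantization)) / 2, numeric(1))
  data.frame(segment = seq_len(n_seg),
             start_s = seg$segments$start_s, end_s = seg$segments$end_s,
             sync = sync, complexity = cx)
}

#' Per-segment measure series for one dyad
#'
#' Combines [sync_complexity_series()] and [novelty_series()] into one table
#' used by the time-course analysis.
#'
#' @inheritParams sync_complexity_series
#' @return A data frame of class `"segment_measure_series"` with columns
#'   `segment`, `start_s`, `end_s`, `sync`, `complexity`, `novelty`, and
#'   attributes `duration_s`, `dyad_id` and `dyad_novelty`.
#' @export
segment_measure_series <- function(a, b, seg, quantization = 6) {
  sc <- sync_complexity_series(a, b, seg, quantization)
  nv <- novelty_series(a, b, seg)
  sc$novelty <- nv$segment_scores
  attr(sc, "duration_s") <- seg$n_frames / seg$fps
  attr(sc, "dyad_id") <- if (inherits(a, "motion_signal")) a$dyad_id else NA
  attr(sc, "dyad_novelty") <- nv$dyad_novelty
  class(sc) <- c("segment_measure_series", "data.frame")
  sc
}

#' Whole-game dyadic measures
#'
#' @inheritParams sync_complexity_series
#' @param max_lag_s maximal lag for [sync_maxxcorr()] (default 5 s).
#' @return A one-row data frame: `dyad_id`, `n_segments`, `sync` (zero-lag
#'   Pearson), `sync_max`, `sync_max_lag` (frames), `complexity` (bits),
#'   `novelty` (mean K-S distance; `NA` if fewer than 2 segments).
#' @export
dyad_measures <- function(a, b, seg, max_lag_s = 5, quantization = 6) {
  mx <- sync_maxxcorr(a, b, max_lag_s)
  nv <- novelty_series(a, b, seg)
  data.frame(
    dyad_id = if (inherits(a, "motion_signal")) a$dyad_id else NA_character_,
    n_segments = nrow(seg$segments),
    sync = sync_pearson(a, b),
    sync_max = mx$r, sync_max_lag = mx$lag,
    complexity = complexity_dyad(a, b, quantization),
    novelty = nv$dyad_novelty,
    stringsAsFactors = FALSE)
}

#' Novelty of a single-person reference recording
#'
#' Reference recordings (e.g. deliberately repetitive vs deliberately varied
#' movement) involve one mover; their novelty is computed by the dyadic
#' pipeline with the signal standing in for both members, so segmentation and
#' scoring are identical to the dyad case.
#'
#' @param signal a raw or z-scored [motion_signal()].
#' @param params optional [segmentation_params()].
#' @return The scalar novelty score.
#' @export
signal_novelty <- function(signal, params = NULL) {
  z <- if (signal$is_zscored) signal else zscore(signal)
  seg <- segment_dyad(z, z, params)
  novelty_series(z, z, seg)$dyad_novelty
}
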