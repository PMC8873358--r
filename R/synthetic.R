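#' Configuration for the synthetic dyad generator
#'
#' The generator emulates the statistical shape of motion-energy recordings
#' from a two-minute dyadic mirroring game: nonnegative, quantized
#' "pixel-count-like" signals at NTSC video rate, built from movement
#' segments separated by brief pauses, with tunable inter-member coupling,
#' value-distribution entropy, and segment-to-segment distributional drift.
#' Liking ratings are generated from a linear model in the dyad's realized
#' synchronization and complexity plus Gaussian rater noise, clipped to the
#' 0-100 rating scale.
#'
#' @param n_dyads number of dyads (default 100).
#' @param fps sampling rate (default 29.97 frames/s).
#' @param duration_range_s game duration drawn uniformly from this range
#'   (default 109.81-130.56 s).
#' @param coupling inter-member coupling in `[0, 1]`: the weight of the
#'   shared movement component. Either a single value used for every dyad or
#'   a length-2 range from which each dyad's coupling is drawn uniformly
#'   (the default, `c(0.4, 0.95)`, yields the between-dyad synchronization
#'   spread a round-robin study shows). Realized zero-lag correlation grows
#'   with coupling and reaches 1 at `coupling = 1` with `noise_sd = 0`.
#' @param pause_rate pauses per second (default 0.25, giving ~4 s mean
#'   movement segments).
#' @param n_levels distinct quantized motion levels (default 128); controls
#'   the attainable value-distribution entropy.
#' @param drift per-segment distributional drift (>= 0, default 1): scales
#'   the between-segment spread of each segment's amplitude level and
#'   waveshape template. 0 makes all segment templates equal (minimal
#'   novelty); larger values make segments more distinguishable.
#' @param liking_coefs `(intercept, beta_sync, beta_complexity)` of the
#'   generative liking model (default `c(-59.33, 64.73, 8.38)`).
#' @param liking_noise_sd SD of each member's rating noise (default 10; the
#'   ratings' within-dyad disagreement is not pinned down by data, so this
#'   is a free parameter).
#' @param noise_sd multiplicative within-segment jitter SD on each member's
#'   envelope (default 0.25).
#' @param lag_max_s upper bound of the per-segment lead/lag between members
#'   in seconds (default 0.5). The drawn lag is scaled by `1 - coupling` and
#'   its sign alternates from segment to segment, so coupled dyads trade
#'   small leads in both directions (bidirectional influence) and a
#'   perfectly coupled dyad has none.
#' @param pause_dur_s pause duration in seconds (default 0.35).
#' @param min_segment_s minimum movement-segment length in seconds
#'   (default 1.5).
#' @param seed integer base seed; every generated object is a deterministic
#'   function of `(seed, dyad_index)`.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_dyads = 100L, fps = 29.97,
                         duration_range_s = c(109.81, 130.56),
                         coupling = c(0.4, 0.95), pause_rate = 0.25,
                         n_levels = 128L, drift = 1,
                         liking_coefs = c(-59.33, 64.73, 8.38),
                         liking_noise_sd = 10, noise_sd = 0.25,
                         lag_max_s = 0.5, pause_dur_s = 0.35,
                         min_segment_s = 1.5, seed = 1L) {
  num <- c(n_dyads = n_dyads, fps = fps, coupling,
           pause_rate = pause_rate, n_levels = n_levels, drift = drift,
           liking_noise_sd = liking_noise_sd, noise_sd = noise_sd,
           lag_max_s = lag_max_s, pause_dur_s = pause_dur_s,
           min_segment_s = min_segment_s, seed = seed,
           duration_range_s, liking_coefs)
  if (any(!is.finite(num)))
    stop("non-finite value in synthetic configuration", call. = FALSE)
  if (n_dyads < 1L || fps <= 0 || n_levels < 2L)
    stop("n_dyads >= 1, fps > 0 and n_levels >= 2 required", call. = FALSE)
  if (!length(coupling) %in% 1:2 || any(coupling < 0) || any(coupling > 1) ||
      (length(coupling) == 2L && diff(coupling) < 0))
    stop("`coupling` must be a value or nondecreasing range within [0, 1]",
         call. = FALSE)
  if (drift < 0 || pause_rate <= 0 || liking_noise_sd < 0 || noise_sd < 0)
    stop("drift, liking_noise_sd, noise_sd must be >= 0 and pause_rate > 0",
         call. = FALSE)
  if (diff(duration_range_s) < 0 || duration_range_s[1] <= 0)
    stop("invalid `duration_range_s`", call. = FALSE)
  if (min_segment_s * pause_rate >= 1)
    stop("`min_segment_s` must be below the mean pause spacing 1/pause_rate",
         call. = FALSE)
  structure(list(
    n_dyads = as.integer(n_dyads), fps = fps,
    duration_range_s = duration_range_s, coupling = coupling,
    pause_rate = pause_rate, n_levels = as.integer(n_levels), drift = drift,
    liking_coefs = liking_coefs, liking_noise_sd = liking_noise_sd,
    noise_sd = noise_sd, lag_max_s = lag_max_s, pause_dur_s = pause_dur_s,
    min_segment_s = min_segment_s, seed = as.integer(seed)),
    class = "synth_config")
}

# unit-SD smooth noise: white noise moving-averaged over ~0.4 s
smooth_noise <- function(n, fps) {
  w <- max(2L, as.integer(round(0.4 * fps)))
  v <- moving_avg(stats::rnorm(n), w)
  v / stats::sd(v)
}

# pause centers: minimum-separated renewal process with mean gap
# 1/pause_rate, kept away from the recording edges
draw_pause_centers <- function(dur, pause_rate, min_segment_s) {
  mean_gap <- 1 / pause_rate
  centers <- numeric(0)
  t0 <- stats::runif(1, min_segment_s, mean_gap)
  while (t0 < dur - min_segment_s) {
    centers <- c(centers, t0)
    t0 <- t0 + min_segment_s +
      stats::rexp(1, rate = 1 / (mean_gap - min_segment_s))
  }
  centers
}

# smooth gate dipping to near zero around each pause center
pause_gate <- function(tt, centers, pause_dur_s) {
  gate <- rep(1, length(tt))
  hw <- pause_dur_s / 2
  for (cen in centers) {
    u <- pmin(abs(tt - cen) / hw, 1)
    gate <- pmin(gate, 0.02 + 0.98 * (3 * u^2 - 2 * u^3))
  }
  gate
}

# per-segment amplitude/waveshape templates; spread scales with drift
draw_templates <- function(n_seg, drift) {
  list(level = exp(drift * stats::rnorm(n_seg, 0, 0.25)),
       shape = exp(drift * stats::rnorm(n_seg, 0, 0.4)))
}

# relative position (0..1) of each frame within its segment
seg_position <- function(n, seg_of) {
  starts <- c(1L, which(diff(seg_of) == 1L) + 1L)
  ends <- c(starts[-1] - 1L, n)
  (seq_len(n) - starts[seg_of]) / pmax(ends[seg_of] - starts[seg_of], 1L)
}

# shared movement component: one single-peaked burst arc per segment (the
# movement swells after a stop and decays toward the next one), following
# the per-segment templates, with mild multiplicative jitter; its only
# interior minima are at the segment boundaries themselves
draw_component_shared <- function(tt, seg_of, tmpl, fps) {
  n <- length(tt)
  u <- seg_position(n, seg_of)
  base <- sin(pi * u)^tmpl$shape[seg_of]
  tmpl$level[seg_of] * (0.12 + 0.88 * base) *
    (1 + 0.06 * smooth_noise(n, fps))
}

# idiosyncratic component: member-specific rectified-sinusoid oscillation
# whose dips are shallow and independently timed between members
draw_component_idio <- function(tt, seg_of, tmpl, noise_sd, fps) {
  n_seg <- length(tmpl$level)
  freq <- stats::runif(n_seg, 0.9, 1.9)
  phase <- stats::runif(n_seg, 0, 2 * pi)
  base <- abs(sin(pi * freq[seg_of] * tt + phase[seg_of]))^tmpl$shape[seg_of]
  tmpl$level[seg_of] * (0.4 + 0.6 * base) *
    (1 + noise_sd * smooth_noise(length(tt), fps))
}

quantize_counts <- function(x, n_levels) {
  x <- pmax(x, 0)
  as.integer(round(x / max(x) * (n_levels - 1L)))
}

#' Generate one synthetic dyad
#'
#' Draws a game duration, places pauses at (minimum-separated) Poisson-like
#' times, and builds both members' signals as a mixture of a shared movement
#' component (weight = the dyad's coupling) and an idiosyncratic one
#' (weight `1 - coupling`). All components follow per-segment amplitude and
#' waveshape templates whose between-segment spread scales with `drift`.
#' Within each segment member b leads or lags member a by a random lag of at
#' most `lag_max_s * (1 - coupling)` seconds, the sign alternating between
#' segments. Signals are gated to near zero during pauses and quantized to
#' `n_levels` nonnegative integer levels (pixel-count-like values). Liking
#' ratings are generated from the dyad's realized synchronization and
#' complexity via [generate_liking()]. The output is a deterministic
#' function of `(cfg$seed, dyad_index)`.
#'
#' @param cfg a [synth_config()].
#' @param dyad_index positive integer distinguishing dyads under one seed.
#' @return A list with `record` (a [dyad_record()], raw quantized counts)
#'   and `truth` (ground truth: the dyad's coupling, pause centers in frames
#'   and seconds, per-segment template levels and shapes, per-segment lags,
#'   realized sync and complexity, and pre-clip liking).
#' @export
generate_dyad <- function(cfg, dyad_index = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(fold_seed(cfg$seed, dyad_index), {
    fps <- cfg$fps
    dur <- stats::runif(1, cfg$duration_range_s[1], cfg$duration_range_s[2])
    n <- as.integer(round(dur * fps))
    tt <- (seq_len(n) - 1L) / fps
    coupling <- if (length(cfg$coupling) == 2L)
      stats::runif(1, cfg$coupling[1], cfg$coupling[2]) else cfg$coupling

    centers <- draw_pause_centers(dur, cfg$pause_rate, cfg$min_segment_s)
    bounds_f <- as.integer(round(centers * fps))
    n_seg <- length(centers) + 1L
    seg_of <- findInterval(seq_len(n), bounds_f + 1L) + 1L

    tmpl <- draw_templates(n_seg, cfg$drift)
    lag_sign <- (if (stats::runif(1) < 0.5) 1 else -1) * (-1)^seq_len(n_seg)
    lag_f <- as.integer(round(
      stats::runif(n_seg, 0.3, 1) * cfg$lag_max_s * (1 - coupling) *
        fps)) * lag_sign

    s_shared <- draw_component_shared(tt, seg_of, tmpl, fps)
    e_a <- draw_component_idio(tt, seg_of, draw_templates(n_seg, cfg$drift),
                               cfg$noise_sd, fps)
    e_b <- draw_component_idio(tt, seg_of, draw_templates(n_seg, cfg$drift),
                               cfg$noise_sd, fps)

    shift_by_segment <- function(v, d_by_seg) {
      idx <- seq_len(n) - d_by_seg[seg_of]
      v[pmin(pmax(idx, 1L), n)]
    }
    gate <- pause_gate(tt, centers, cfg$pause_dur_s)
    x_a <- (coupling * s_shared + (1 - coupling) * e_a) * gate
    x_b <- (coupling * shift_by_segment(s_shared, lag_f) +
              (1 - coupling) * e_b) * gate

    id <- sprintf("dyad%03d", dyad_index)
    a <- motion_signal(quantize_counts(x_a, cfg$n_levels), fps = fps,
                       member_id = "a", dyad_id = id)
    b <- motion_signal(quantize_counts(x_b, cfg$n_levels), fps = fps,
                       member_id = "b", dyad_id = id)
    sync_true <- sync_pearson(a, b)
    cx_true <- complexity_dyad(zscore(a), zscore(b))
    lik <- generate_liking(sync_true, cx_true, cfg)
    record <- dyad_record(a, b, liking_a = lik[1], liking_b = lik[2],
                          dyad_id = id)
    truth <- list(
      dyad_id = id, coupling = coupling, duration_s = dur,
      pause_centers_s = centers, pause_centers_f = bounds_f,
      segment_levels = tmpl$level, segment_shapes = tmpl$shape,
      segment_lags_f = lag_f,
      sync = sync_true, complexity = cx_true,
      liking_pre_clip = attr(lik, "pre_clip"),
      liking_mu = attr(lik, "mu"))
    list(record = record, truth = truth)
  })
}

#' Generate liking ratings from synchronization and complexity
#'
#' The generative mean is `intercept + beta_sync * sync +
#' beta_complexity * complexity`; each member's rating adds independent
#' Gaussian noise and is clipped to the 0-100 rating scale. Uses the current
#' RNG stream (seed it, or call from [generate_dyad()] which seeds it).
#'
#' @param sync dyadic synchronization (Pearson r).
#' @param complexity dyadic complexity in bits (>= 0).
#' @param cfg a [synth_config()] supplying `liking_coefs` and
#'   `liking_noise_sd`.
#' @return Numeric vector `c(liking_a, liking_b)` with attributes
#'   `"pre_clip"` (ratings before clipping) and `"mu"` (the noiseless mean).
#' @export
generate_liking <- function(sync, complexity, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.finite(sync) || !is.finite(complexity) || complexity < 0)
    stop("`sync` must be finite and `complexity` >= 0", call. = FALSE)
  cf <- cfg$liking_coefs
  mu <- cf[1] + cf[2] * sync + cf[3] * complexity
  pre <- mu + stats::rnorm(2, 0, cfg$liking_noise_sd)
  out <- pmin(100, pmax(0, pre))
  attr(out, "pre_clip") <- pre
  attr(out, "mu") <- mu
  out
}

#' Low- and high-novelty single-person reference signals
#'
#' Emulates the two anchor recordings used to calibrate the novelty scale:
#' `ln`, a strictly periodic signal (fixed frequency and amplitude,
#' repetitive up-and-down hand movement), and `hn`, a deliberately varied
#' signal whose frequency, amplitude, and waveshape are re-randomized every
#' segment. Both are two minutes long at `cfg$fps` and quantized like the
#' dyadic signals. Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return A list with [motion_signal()]s `ln` and `hn`.
#' @export
generate_ln_hn_references <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(fold_seed(cfg$seed, 499979L), {
    fps <- cfg$fps
    n <- as.integer(round(120 * fps))
    tt <- (seq_len(n) - 1L) / fps
    # LN: one fixed-frequency rectified sinusoid, no noise, no pauses;
    # the periodic dips are the stopping points
    ln_vals <- 0.3 + 0.7 * abs(sin(pi * 0.8 * tt))
    ln <- motion_signal(quantize_counts(ln_vals, cfg$n_levels), fps = fps,
                        member_id = "LN", dyad_id = "reference")

    # HN: per-segment randomized frequency, amplitude and waveshape
    centers <- draw_pause_centers(120, cfg$pause_rate, cfg$min_segment_s)
    bounds_f <- as.integer(round(centers * fps))
    n_seg <- length(centers) + 1L
    seg_of <- findInterval(seq_len(n), bounds_f + 1L) + 1L
    # templates are stratified (permuted quantile grids), not iid draws: a
    # mover who deliberately varies every movement spans the whole range of
    # amplitudes and waveshapes within one game. The amplitude spread is
    # kept moderate: extreme levels would compress the other segments into
    # few quantization levels and mute their contrast.
    strat <- function(spread) {
      q <- (sample(n_seg) - 0.5) / n_seg
      exp(stats::qnorm(q) * spread)
    }
    level <- strat(0.6)
    shape <- strat(0.55)
    freq <- stats::runif(n_seg, 0.3, 2.2)
    phase <- stats::runif(n_seg, 0, 2 * pi)
    base <- abs(sin(pi * freq[seg_of] * tt + phase[seg_of]))^shape[seg_of]
    hn_vals <- level[seg_of] * (0.15 + 0.85 * base) *
      pause_gate(tt, centers, cfg$pause_dur_s)
    hn <- motion_signal(quantize_counts(hn_vals, cfg$n_levels), fps = fps,
                        member_id = "HN", dyad_id = "reference")
    list(ln = ln, hn = hn)
  })
}

#' Simulate a full synthetic study
#'
#' Generates `cfg$n_dyads` dyads plus the liking table used downstream.
#'
#' @param cfg a [synth_config()].
#' @return A list with `records` (named list of [dyad_record()]s), `truths`
#'   (named list of ground truths), and `liking` (data frame `dyad_id`,
#'   `rating_a`, `rating_b`).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  out <- lapply(seq_len(cfg$n_dyads), function(i) generate_dyad(cfg, i))
  ids <- vapply(out, function(o) o$record$dyad_id, character(1))
  records <- stats::setNames(lapply(out, `[[`, "record"), ids)
  truths <- stats::setNames(lapply(out, `[[`, "truth"), ids)
  liking <- data.frame(
    dyad_id = ids,
    rating_a = vapply(records, function(r) r$liking_a, numeric(1)),
    rating_b = vapply(records, function(r) r$liking_b, numeric(1)),
    stringsAsFactors = FALSE)
  list(records = records, truths = truths, liking = liking)
}
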