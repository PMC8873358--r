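# hand-built per-segment series for timecourse tests
toy_series <- function(values, duration_s, id = "d1",
                       starts = NULL, ends = NULL) {
  k <- length(values)
  if (k == 0L) starts <- ends <- numeric(0)
  if (is.null(starts)) starts <- seq(0, duration_s, length.out = k + 1)[-(k + 1)]
  if (is.null(ends)) ends <- c(starts[-1], duration_s)
  df <- data.frame(segment = seq_len(k), start_s = starts, end_s = ends,
                   sync = values, complexity = values, novelty = values)
  attr(df, "duration_s") <- duration_s
  attr(df, "dyad_id") <- id
  class(df) <- c("segment_measure_series", "data.frame")
  df
}

test_that("median_split halves the table with deterministic tie handling", {
  tab <- data.frame(dyad_id = c("a", "b", "c", "d"),
                    liking_mean = c(1, 2, 3, 4))
  sp <- median_split(tab)
  expect_setequal(sp$low, c("a", "b"))
  expect_setequal(sp$high, c("c", "d"))

  # 100 dyads -> two groups of 50
  tab2 <- data.frame(dyad_id = sprintf("d%03d", 1:100),
                     liking_mean = rnorm(100))
  sp2 <- median_split(tab2)
  expect_equal(length(sp2$low), 50)
  expect_equal(length(sp2$high), 50)
  expect_setequal(c(sp2$low, sp2$high), tab2$dyad_id)

  # all values equal: the tie rule still balances the groups
  tab3 <- data.frame(dyad_id = sprintf("d%03d", 1:100),
                     liking_mean = rep(7, 100))
  sp3 <- median_split(tab3)
  expect_equal(abs(length(sp3$low) - length(sp3$high)), 0)
})

test_that("build_timecourse resamples step functions onto a relative grid", {
  # a single-segment dyad yields a constant curve
  tc <- build_timecourse(list(d1 = toy_series(0.7, 120)), G = 100)
  expect_equal(unname(tc$measures$sync["d1", ]), rep(0.7, 100))

  # identical series with different durations give identical curves
  tc2 <- build_timecourse(list(d1 = toy_series(c(1, 2, 3), 110),
                               d2 = toy_series(c(1, 2, 3), 130)),
                          G = 200, smooth_s = 0)
  expect_equal(unname(tc2$measures$sync["d1", ]),
               unname(tc2$measures$sync["d2", ]))

  # a boundary at mid-game lands at the middle grid index before smoothing
  tc3 <- build_timecourse(list(d1 = toy_series(c(0, 1), 120)),
                          G = 1000, smooth_s = 0)
  v <- unname(tc3$measures$sync["d1", ])
  expect_equal(which(diff(v) != 0), 500, tolerance = 1)
  expect_equal(v[1], 0)
  expect_equal(v[1000], 1)

  # dyads with no segments are excluded with a warning
  empty <- toy_series(numeric(0), 120)
  expect_warning(
    tc4 <- build_timecourse(list(d1 = toy_series(1, 120), d2 = empty),
                            G = 50),
    "no segments")
  expect_equal(tc4$dyad_ids, "d1")
})

test_that("compare_groups counts grid points and runs the sign test", {
  set.seed(21)
  mk <- function(id, base) toy_series(base + rnorm(12, 0, 0.05), 120, id)
  lows <- lapply(1:6, function(i) mk(paste0("L", i), 0.4))
  highs <- lapply(1:6, function(i) mk(paste0("H", i), 0.4))
  names(lows) <- paste0("L", 1:6); names(highs) <- paste0("H", 1:6)
  tc <- build_timecourse(c(lows, highs), G = 200)

  # statistically identical groups: fraction near 1/2, sign test quiet
  gc <- compare_groups(tc, low = names(lows), high = names(highs), "sync")
  expect_gt(gc$fraction_high_gt_low, 0.1)
  expect_lt(gc$fraction_high_gt_low, 0.9)
  expect_gt(gc$binomial_p, 1e-4)

  # a constant offset makes the high group win everywhere
  highs2 <- lapply(1:6, function(i)
    toy_series(1 + lows[[i]]$sync, 120, paste0("H", i)))
  names(highs2) <- paste0("H", 1:6)
  tc2 <- build_timecourse(c(lows, highs2), G = 200)
  gc2 <- compare_groups(tc2, low = names(lows), high = names(highs2), "sync")
  expect_equal(gc2$fraction_high_gt_low, 1)
  expect_lt(gc2$binomial_p, 1e-8)

  # relabeling the groups flips the fraction exactly
  gc3 <- compare_groups(tc2, low = names(highs2), high = names(lows), "sync")
  expect_equal(gc3$fraction_high_gt_low, 1 - gc2$fraction_high_gt_low)

  expect_error(compare_groups(tc, low = "L1", high = names(highs)),
               "at least 2")
  expect_match(gc$caveat, "autocorrelated")
})

test_that("the binomial sign test matches the exact closed form", {
  # 559 of 1000 grid points above chance
  expect_equal(binom.test(559, 1000, 0.5)$p.value, 2.2e-4,
               tolerance = 0.02)
})

test_that("novelty_trend fits the group-mean curve against seconds", {
  ramp <- seq(0.3, 0.5, length.out = 40)
  tc <- build_timecourse(list(d1 = toy_series(ramp, 120),
                              d2 = toy_series(ramp, 120)),
                         G = 400, smooth_s = 0)
  tr <- novelty_trend(tc, c("d1", "d2"))
  expect_gt(tr$r, 0.99)
  # the curve spans 0.2 novelty units over ~120 s
  expect_equal(tr$slope, 0.2 / 120, tolerance = 0.1)

  down <- novelty_trend(
    build_timecourse(list(d1 = toy_series(rev(ramp), 120)), G = 400,
                     smooth_s = 0), "d1")
  expect_lt(down$r, 0)

  flat <- build_timecourse(list(d1 = toy_series(rep(0.4, 5), 120)), G = 100)
  expect_error(novelty_trend(flat, "d1"), "constant")
})

test_that("compare_correlations applies the Fisher-z closed form", {
  expect_equal(compare_correlations(0.5, 53, 0.5, 53, "greater")$z, 0)
  expect_equal(compare_correlations(0.5, 53, 0.5, 53, "greater")$p, 0.5)

  cc <- compare_correlations(0.5, 53, 0, 53, tail = "greater")
  expect_equal(cc$z, atanh(0.5) / 0.2, tolerance = 1e-12)

  expect_error(compare_correlations(1, 50, 0.5, 50), "< 1")
  expect_error(compare_correlations(0.5, 3, 0.5, 50), "exceed 3")
})

test_that("higher-drift groups show higher novelty along the game", {
  wins <- 0
  for (rep in 1:6) {
    lo_cfg <- quick_cfg(drift = 0.5, seed = 200 + rep, n_dyads = 4)
    hi_cfg <- quick_cfg(drift = 2, seed = 300 + rep, n_dyads = 4)
    lo <- lapply(1:4, function(i) generate_dyad(lo_cfg, i)$record)
    hi <- lapply(1:4, function(i) generate_dyad(hi_cfg, i)$record)
    series <- c(
      setNames(lapply(lo, function(r) analyze_dyad(r)$series),
               paste0("L", 1:4)),
      setNames(lapply(hi, function(r) analyze_dyad(r)$series),
               paste0("H", 1:4)))
    tc <- build_timecourse(series, G = 300)
    gc <- compare_groups(tc, low = paste0("L", 1:4),
                         high = paste0("H", 1:4), "novelty")
    if (gc$fraction_high_gt_low > 0.5) wins <- wins + 1
  }
  expect_gte(wins, 5)
})
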