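test_that("sync_pearson matches hand-computed correlations", {
  a <- motion_signal(c(1, 2, 3, 4))
  expect_equal(sync_pearson(a, a), 1)
  neg <- motion_signal(-c(1, 2, 3, 4))
  expect_equal(sync_pearson(a, neg), -1)

  b <- motion_signal(c(1, 2, 3, 5))
  # cov = 6.5/3, sd_a = sqrt(5/3), sd_b = sqrt(8.75/3)
  expect_equal(sync_pearson(a, b), (6.5 / 3) / sqrt(5 / 3 * 8.75 / 3),
               tolerance = 1e-12)
  expect_equal(round(sync_pearson(a, b), 3), 0.983)

  set.seed(1)
  expect_lt(abs(sync_pearson(rnorm(10000), rnorm(10000))), 0.05)

  expect_error(sync_pearson(motion_signal(c(1, 1, 1, 1)), a), "constant")
  expect_error(sync_pearson(a, motion_signal(c(1, 2))), "equal length")
})

test_that("sync_maxxcorr finds the aligning lag with deterministic ties", {
  fps <- 30
  set.seed(2)
  base <- cumsum(rnorm(600))
  a <- motion_signal(base, fps = fps)
  b <- motion_signal(c(base[4:600], base[597:599]), fps = fps)  # b leads: a delayed
  # b[t] = a[t+3], so the max correlation is at lag -3
  r <- sync_maxxcorr(a, b, max_lag_s = 0.5)
  expect_equal(r$lag, -3)
  expect_gt(r$r, 0.99)

  bb <- motion_signal(c(base[598:600], base[1:597]), fps = fps)  # b delayed by 3
  r <- sync_maxxcorr(a, bb, max_lag_s = 0.5)
  expect_equal(r$lag, 3)

  # zero max lag reduces to the zero-lag Pearson correlation
  x <- motion_signal(rnorm(200), fps = fps)
  y <- motion_signal(rnorm(200), fps = fps)
  expect_equal(sync_maxxcorr(x, y, 0)$r, sync_pearson(x, y))

  # identical signals: perfect correlation at many lags, tie-break to 0
  expect_equal(sync_maxxcorr(a, a, 0.5)$lag, 0)
  expect_equal(sync_maxxcorr(a, a, 0.5)$r, 1)
})

test_that("maximal cross-correlation never falls below zero-lag sync", {
  set.seed(3)
  for (i in 1:10) {
    a <- motion_signal(rnorm(300))
    b <- motion_signal(rnorm(300))
    expect_gte(sync_maxxcorr(a, b, 1)$r, sync_pearson(a, b))
  }
})

test_that("complexity_entropy counts unique-value frequencies in bits", {
  expect_equal(complexity_entropy(c(1, 1, 1, 1)), 0)
  expect_equal(complexity_entropy(c(1, 1, 2, 2)), 1)
  expect_equal(complexity_entropy(c(1, 2, 3, 4)), 2)

  # permutation invariance and the log2(n) maximum for unique values
  set.seed(4)
  x <- sample(0:15, 200, replace = TRUE)
  expect_equal(complexity_entropy(x), complexity_entropy(sample(x)))
  expect_lte(complexity_entropy(x), log2(16))
  u <- runif(64)
  expect_equal(complexity_entropy(u), log2(64))

  # quantization merges nearby values
  expect_equal(complexity_entropy(c(1, 1 + 1e-9, 2, 2 - 1e-9), 6), 1)
})

test_that("complexity_dyad averages member entropies", {
  two <- motion_signal(rep(c(0, 1), 8))
  four <- motion_signal(rep(c(0, 1, 2, 3), 4))
  expect_equal(complexity_dyad(two, four), 1.5)
  expect_equal(complexity_dyad(four, four), 2)
  expect_error(complexity_entropy(numeric(0)), "empty")
})

test_that("ks_distance matches closed forms, ks.test, and brute force", {
  expect_equal(ks_distance(1:10, 1:10), 0)
  expect_equal(ks_distance(c(0, 1), c(10, 11)), 1)
  expect_equal(ks_distance(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.25)
  expect_error(ks_distance(numeric(0), 1), "empty")

  set.seed(5)
  for (i in 1:25) {
    x <- round(rnorm(sample(3:50, 1)), 1)   # ties on purpose
    y <- round(rnorm(sample(3:50, 1), sd = runif(1, 0.5, 2)), 1)
    d <- ks_distance(x, y)
    expect_identical(d, brute_ks(x, y))
    expect_equal(d,
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("novelty_series follows the cumulative comparison scheme", {
  fps <- 29.97
  seg <- toy_segmentation(c(101, 201), n_frames = 300, fps = fps)

  # all segments drawn identical -> every score is zero
  block <- rep(sin((1:100) / 5), 3)
  a <- motion_signal(block, fps = fps)
  nv <- novelty_series(a, a, seg)
  expect_equal(unname(nv$segment_scores), rep(0, 3))
  expect_equal(nv$dyad_novelty, 0)

  # dyadic score averages the two members' mean distances
  set.seed(6)
  a <- motion_signal(rnorm(300), fps = fps)
  b <- motion_signal(rnorm(300), fps = fps)
  nv <- novelty_series(a, b, seg)
  va <- lapply(1:3, function(k) a$values[seg$segments$start[k]:
                                           (seg$segments$end[k] - 1)])
  vb <- lapply(1:3, function(k) b$values[seg$segments$start[k]:
                                           (seg$segments$end[k] - 1)])
  s3a <- mean(c(ks_distance(va[[3]], va[[1]]), ks_distance(va[[3]], va[[2]])))
  s3b <- mean(c(ks_distance(vb[[3]], vb[[1]]), ks_distance(vb[[3]], vb[[2]])))
  expect_equal(nv$segment_scores[3], mean(c(s3a, s3b)))

  # the first segment inherits the second segment's score, and the dyad
  # score averages segments 2..N only
  expect_equal(nv$segment_scores[1], nv$segment_scores[2])
  expect_equal(nv$dyad_novelty, mean(nv$segment_scores[2:3]))

  # fewer than two segments: novelty is flagged missing
  one <- suppressWarnings(toy_segmentation(integer(0), n_frames = 300))
  expect_warning(nv1 <- novelty_series(a, b, one), "fewer than 2")
  expect_true(is.na(nv1$dyad_novelty))
})

test_that("novelty matches an independent brute-force oracle", {
  cfg <- quick_cfg(seed = 41)
  for (i in 1:4) {
    rec <- generate_dyad(cfg, i)$record
    za <- zscore(rec$a); zb <- zscore(rec$b)
    seg <- segment_dyad(za, zb)
    nv <- novelty_series(za, zb, seg)
    bf <- brute_novelty(za, zb, seg)
    expect_equal(unname(nv$segment_scores), bf$segment_scores,
                 tolerance = 1e-12)
    expect_equal(nv$dyad_novelty, bf$dyad_novelty, tolerance = 1e-12)
  }
})

test_that("segment-wise sync and complexity handle edge cases", {
  fps <- 29.97
  seg <- toy_segmentation(c(101, 201), n_frames = 300, fps = fps)
  set.seed(7)
  a <- motion_signal(rnorm(300), fps = fps)

  # identical members: per-segment sync is 1 everywhere
  sc <- sync_complexity_series(a, a, seg)
  expect_equal(sc$sync, rep(1, 3))

  # whole-game entropy equals the segment entropy when there is 1 segment
  one <- suppressWarnings(toy_segmentation(integer(0), n_frames = 300))
  sc1 <- sync_complexity_series(a, a, one)
  expect_equal(sc1$complexity, complexity_dyad(a, a))

  # segments shorter than 3 frames get a missing sync value
  tiny <- toy_segmentation(c(5, 7), n_frames = 300, fps = fps,
                           window = 2)
  sc2 <- sync_complexity_series(a, motion_signal(rnorm(300), fps = fps),
                                tiny)
  expect_true(is.na(sc2$sync[2]))
})

test_that("dyad_measures assembles the whole-game summary", {
  cfg <- quick_cfg(seed = 43)
  rec <- generate_dyad(cfg, 1)$record
  za <- zscore(rec$a); zb <- zscore(rec$b)
  seg <- segment_dyad(za, zb)
  m <- dyad_measures(za, zb, seg, max_lag_s = 2)
  expect_equal(m$sync, sync_pearson(za, zb))
  expect_gte(m$sync_max, m$sync)
  expect_true(m$novelty > 0 && m$novelty < 1)
  expect_equal(m$n_segments, nrow(seg$segments))
})
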