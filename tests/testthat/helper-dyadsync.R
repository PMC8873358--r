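# short-duration configuration for fast unit tests; the study-scale defaults
# are exercised in test-acceptance.R
quick_cfg <- function(...) {
  synth_config(duration_range_s = c(55, 65), ...)
}

# independent brute-force two-sample KS distance: loop over every threshold
brute_ks <- function(x, y) {
  d <- 0
  for (t in c(x, y)) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# independent brute-force novelty: direct nested loops over (k, j) pairs
brute_novelty <- function(a, b, seg) {
  vals <- function(sig) lapply(seq_len(nrow(seg$segments)), function(k)
    sig$values[seg$segments$start[k]:(seg$segments$end[k] - 1L)])
  va <- vals(a); vb <- vals(b)
  n_seg <- nrow(seg$segments)
  scores <- rep(NA_real_, n_seg)
  for (k in 2:n_seg) {
    sa <- 0; sb <- 0
    for (j in seq_len(k - 1L)) {
      sa <- sa + ks_distance(va[[k]], va[[j]])
      sb <- sb + ks_distance(vb[[k]], vb[[j]])
    }
    scores[k] <- (sa / (k - 1) + sb / (k - 1)) / 2
  }
  scores[1] <- scores[2]
  list(segment_scores = scores, dyad_novelty = mean(scores[-1]))
}

# toy segmentation result with prescribed boundaries, for measure tests
toy_segmentation <- function(boundaries, n_frames, fps = 29.97, window = 8L) {
  match_shared_minima(boundaries, boundaries,
                      segmentation_params(window),
                      n_frames = n_frames, fps = fps)
}
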