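# dyadsync

Analysis of dyadic movement coordination from motion-energy time series.

When two people play a mirroring game — facing each other and moving their
hands as coordinately as possible for about two minutes — how well they end
up liking each other is not just a matter of how *synchronized* they were.
`dyadsync` implements a pipeline for testing the interplay between
synchronization and *interest* (movement complexity and novelty) in such
interactions, for researchers working with motion energy analysis (MEA):
per-frame counts of video pixels whose intensity changed beyond a noise
threshold, one signal per person.

## What it computes

Given a dyad's two Z-scored MEA signals \(x_a(t), x_b(t)\):

* **Segmentation** — shared movement segments delimited by the members'
  matched stopping points: local minima of the moving-average-smoothed
  signals with value < 0, minimum spacing of one smoothing window, and a
  0.1 SD prominence, paired across members by mutual nearest neighbours.
* **Synchronization** — zero-lag Pearson correlation r(x_a, x_b), plus the
  maximal lagged cross-correlation within ±5 s.
* **Complexity** — Shannon entropy H(X) = −Σ p(x) log₂ p(x) of each
  member's value distribution (unique-value frequencies), averaged within
  the dyad; in bits.
* **Novelty** — for each segment, the mean two-sample Kolmogorov–Smirnov
  distance D = sup |F̂_k − F̂_j| between its value distribution and every
  earlier segment's, averaged over members; the dyad score averages
  segments 2..N.
* **Coupling structure** — bivariate VAR Granger causality per direction
  (AIC order selection, exclusion F-tests): bidirectional vs
  leader–follower vs none.
* **Liking models** — dyadic liking (mean of the two 0–100 ratings)
  regressed on sync, then sync + complexity, then + novelty, with nested
  F-tests and round-robin permutation inference (dyadic label shuffling,
  10,000 permutations, add-one rule).
* **Dynamics** — median-split liking groups compared point-by-point along a
  relative-time grid (Welch tests, binomial sign test, novelty-over-time
  trends, Fisher-z slope-correlation comparison).

A synthetic-data module (`synth_config()`, `simulate_study()`,
`generate_ln_hn_references()`) generates MEA-like dyads with known
coupling, entropy, drift, and liking structure, so every stage is testable
without the study's data. See the methods vignette
(`vignettes/dyadsync-methods.Rmd`) for models, parameters and design
choices.

## Worked example

```r
library(dyadsync)

cfg <- synth_config(n_dyads = 12, seed = 42)   # ~2-minute games, 29.97 fps
st  <- simulate_study(cfg)

one <- analyze_dyad(st$records[["dyad001"]])
one$measures
#>  dyad_id n_segments  sync sync_max sync_max_lag complexity novelty
#>  dyad001         25 0.889    0.889            0        6.5   0.343
```

This dyad's recording split into 25 movement segments; the members'
signals correlate at r = 0.889 with no lag improving on zero, their
movement entropy averages 6.5 bits, and a typical segment sits at K-S
distance 0.343 from its predecessors (0 = every movement repeats an
earlier one, 1 = completely new value range each time).

```r
granger_direction(zscore(st$records[["dyad001"]]$a),
                  zscore(st$records[["dyad001"]]$b))
#> <gca_result> order 28: a->b F = 9.67 (p = 1.12e-39),
#>              b->a F = 9.00 (p = 3.08e-36) => bidirectional
```

Each member's past predicts the other beyond self-prediction: the dyad
trades leader and follower roles rather than fixing them.

```r
ms  <- measure_study(st$records)
tab <- build_dyad_table(ms$table, st$liking)
fit_liking_models(tab)
#> M1: R2 = 0.659, F(1, 10) = 19.36, p = 0.00134 (dR2 = 0.659, p = 0.00134)
#> M2: R2 = 0.673, F(2, 9) = 9.26, p = 0.00655 (dR2 = 0.014, p = 0.557)
#> M3: R2 = 0.721, F(3, 8) = 6.87, p = 0.0132 (dR2 = 0.048, p = 0.276)
```

Synchronization predicts the generated liking ratings; with only 12 dyads
the complexity increment is not resolved (the acceptance script runs the
full 100-dyad design, where it is).

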