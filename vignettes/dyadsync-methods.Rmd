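---
title: "Measuring synchronization, complexity and novelty in dyadic movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring synchronization, complexity and novelty in dyadic movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dyadsync` analyzes dyadic motion-energy recordings from mirroring games:
two people face each other and move their hands as coordinately as possible
for about two minutes, then report how much they liked each other on a
0-100 scale. A hidden camera films both players at 29.97 frames per second;
motion energy analysis (MEA) reduces each player to one number per frame —
the count of pixels in that player's region of the frame whose intensity
changed by more than a noise threshold since the previous frame. This
vignette documents the models, the tunable parameters, and the design
choices behind each processing stage.

```{r setup}
library(dyadsync)
```

## Signals

`motion_signal` holds one member's MEA series. Before analysis each signal
is Z-scored (`zscore()`), which removes differences in body size and
distance from the camera. Z-scoring divides by the population SD by
default; a `ddof` argument gives the sample-SD convention. Every
correlation downstream is invariant to this choice. A constant signal means
the member never moved; it is a degenerate input and raises an error
instead of propagating NaNs (such recordings are excluded from studies for
the same reason).

`compute_mea()` implements the video stage for grayscale frame stacks with
one rectangular region of interest per member (default: a vertical split at
the frame midline). The noise threshold defaults to 10 intensity units on
an 8-bit scale; it is the only tunable of this stage and trades sensor
noise against sensitivity to small movements. `read_mea_table()` /
`write_mea_table()` define the canonical on-disk CSV layout
(`frame, member_a, member_b`).

## Segmentation into movements

Movements are delimited by the moments both members stop or decelerate
together. The pipeline is:

1. **Smoothing window** (`choose_window()`). Both members' Z-scored signals
   are smoothed by a centered moving average. The window is chosen from the
   signals themselves: the smallest lag at which the mean of the two
   autocorrelation functions falls below 1/e, clamped to 0.25-2 s. The
   clamp floor keeps noise-dominated signals from skipping smoothing
   altogether; the ceiling keeps slowly-drifting signals from being smoothed
   into featurelessness. This rule is deterministic and documented, unlike
   the opaque smoothing-factor heuristics of closed-source toolboxes, and on
   synthetic data it yields the ~4 s average movement length expected for
   this task.
2. **Per-member stopping points** (`find_member_minima()`). Local minima of
   the smoothed signal qualify when (i) the value is below zero — the member
   moves more slowly than their own average; (ii) kept minima are at least
   one window apart (the deeper of two close minima wins); (iii) the signal
   rises at least 0.1 SD between consecutive minima (shallower minimum
   dropped otherwise). The 0.1-SD prominence is evaluated on the smoothed
   signal, where the minima live. Tie-breaks (deeper minimum, then earlier
   frame) are not dictated by the method; they were fixed once for
   determinism.
3. **Shared minima** (`match_shared_minima()`). The members' minima are
   paired by mutual nearest neighbours within one window of tolerance; each
   boundary is the rounded mean of the paired frame indices; boundaries
   also keep one window of separation (the tighter pair wins). Segments are
   half-open frame intervals `[start, end)` covering the whole recording.
   With no shared minima the recording is one segment, with a warning.

## The three dyadic measures

**Synchronization** is the zero-lag Pearson correlation between the
members' Z-scored signals (`sync_pearson()`): the degree to which the two
accelerate and decelerate together. `sync_maxxcorr()` additionally scans
lags up to ±5 s (configurable) and returns the maximal correlation and its
lag; it can never fall below the zero-lag value and is reported alongside
it.

**Complexity** is the Shannon entropy, in bits, of the empirical
distribution of a member's signal values, averaged across the two members
(`complexity_entropy()`, `complexity_dyad()`). Because MEA values are
integer pixel counts, the Z-scored values remain discrete and
"frequency of each unique value" is well defined; the `quantization`
argument (default: round to 6 decimals) preserves that discreteness while
making the measure usable on continuous synthetic signals. Entropy uses
log base 2; higher entropy means the moment-to-moment movement intensity is
less predictable.

**Novelty** asks how non-repetitive the movement is across segments. For
each member, each segment's value distribution is compared to every earlier
segment's with the two-sample Kolmogorov-Smirnov distance
(`ks_distance()`), and the mean of those distances is the segment's score;
member scores are averaged into a dyadic score (`novelty_series()`). The
first segment has no predecessors and inherits the second segment's score;
the dyad-level score averages segments 2..N so the duplicate is not counted
twice. Novelty compares the raw Z-scored values, not the smoothed ones:
smoothing is a segmentation device, whereas novelty is about movement
content. K-S distances are computed segment-against-segment even though
segment lengths differ; the K-S statistic is well defined for unequal
sample sizes and bounded in [0, 1].

## Leader-follower structure

`granger_direction()` fits a bivariate VAR by OLS and F-tests, in each
direction, the exclusion of the cross-lag coefficients: member a
Granger-causes member b when a's past improves the prediction of b beyond
b's own past. Both directions significant at `alpha` (default 0.05, per
direction, no multiplicity correction) is a bidirectional dyad — the
members trade leader and follower roles; exactly one is a leader-follower
dyad; neither is "none". The VAR order is selected by AIC up to
`max_order` (default 30 frames ≈ 1 s). The selection uses the two
*univariate* autoregressions' summed AICs at a common order rather than the
bivariate criterion: selecting on own-lag structure only keeps the order
choice independent of the cross-lag coefficients under the null, which
preserves the size of the subsequent F-tests (with bivariate-AIC selection
the empirical false-positive rate on independent noise was visibly
inflated). Stationarity is not enforced by differencing or detrending;
results can shift with such preprocessing choices.

## Liking models and round-robin inference

The dyadic liking score is the mean of the two members' 0-100 ratings
(`build_dyad_table()`; min and max are kept for sensitivity analyses).
Dyads farther than 3 SDs from a screened column's mean are excluded in a
single pass (`exclude_outliers()`). Three nested OLS models of liking are
fitted (`fit_liking_models()`): synchronization only; adding complexity;
adding novelty — with raw and standardized coefficients, R², overall and
incremental F-tests.

Because every participant plays several partners (a round-robin design),
dyads share members and are not independent. `permutation_test()` builds a
null distribution by shuffling the dyadic labels of one variable — each
dyad's synchronization gets paired with another dyad's complexity, say —
while every observed value is preserved; 10,000 permutations by default,
with the add-one rule `p = (k + 1) / (n_perm + 1)` so p is never zero.
Member-level resampling is deliberately not attempted; the label-shuffling
scheme matches how such designs are analyzed in practice. The default tail
is two-sided; a one-tailed variant is available per test.

## Time-course dynamics

`median_split()` divides dyads into low- and high-liking halves (ties at
the median alternate, by sorted dyad id, into whichever group is smaller,
so sizes differ by at most one). Games differ in duration (109.81-130.56
s), and no canonical pointwise alignment exists; the package normalizes
each dyad's per-segment step function onto a common 1000-point relative
time grid (0 = game start, 1 = game end) and then applies a 4-s moving
average — the average movement length — converted to grid units via each
dyad's own duration (`build_timecourse()`). Fractions "of the game
duration" are fractions of this grid.

`compare_groups()` compares the groups at every grid point with a Welch
t-test, reports the fraction of the game where the high-liking mean exceeds
the low-liking mean, and tests that fraction against 0.5 with an exact
binomial sign test. Neighbouring grid points are autocorrelated, so the
sign test treats as exchangeable points that are not independent; the
result carries this caveat explicitly and should be read as descriptive.
`novelty_trend()` fits the group-mean novelty curve against time in
seconds, and `compare_correlations()` compares two groups' trend
correlations with the independent-groups Fisher-z statistic.

## The synthetic-data generator

`generate_dyad()` emulates the statistical shape of the study's recordings
so the whole pipeline can be tested with known ground truth. Defaults are
the study's conditions: 100 dyads, 29.97 fps, durations uniform on
109.81-130.56 s, pauses at ~0.25/s (≈4 s mean segments), and liking
generated from the linear model
`liking = -59.33 + 64.73·sync + 8.38·complexity` plus member-level Gaussian
noise (SD 10), clipped to 0-100.

Each dyad is built from three movement components that share per-segment
amplitude and waveshape *templates*: a shared component — one single-peaked
burst arc per segment, so its only sub-zero minima sit at the pauses — and
one oscillatory idiosyncratic component per member whose shallow dips are
independently timed. Member signals mix these with weight `coupling` vs
`1 - coupling`, are gated to near zero during pauses, and are quantized to
`n_levels` (default 128) nonnegative integer levels, making the values
pixel-count-like so that entropy-by-unique-values is well defined. Within
each segment, member b leads or lags member a by up to
`lag_max_s · (1 - coupling)` seconds with alternating sign — coupled dyads
trade small leads in both directions, which is what makes Granger analysis
classify them bidirectional, while a perfectly coupled dyad (`coupling = 1`,
`noise_sd = 0`) is sample-identical to its partner.

Tunable knobs and what they control:

* `coupling` — realized inter-member correlation (monotonically). A scalar
  applies to every dyad; the default is the range `c(0.4, 0.95)` from which
  each dyad draws its own coupling, reproducing the between-dyad
  synchronization spread a real round-robin shows.
* `n_levels` — attainable entropy (complexity grows with it).
* `drift` — SD scale of the per-segment log-level and log-shape templates;
  0 makes all segment distributions equal (novelty near its finite-sample
  floor), larger values separate them (novelty grows).
* `pause_rate`, `min_segment_s`, `pause_dur_s` — segment geometry.
* `liking_noise_sd` — within-dyad rating disagreement. No data pins this
  down beyond "relatively small"; 10 rating points is the package's choice.

At the defaults the generator lands on the study's scale: detected segments
average ≈3.5 s, novelty ≈0.40 (SD ≈0.05), the strictly periodic low-novelty
reference (`generate_ln_hn_references()`) falls below every simulated dyad
and the deliberately varied high-novelty reference above the median, and
essentially all dyads classify bidirectional.

What the generator does **not** emulate: real video noise and its spatial
structure, person-specific movement styles, the round-robin sharing of
members across dyads (ratings are independent across dyads here), session
effects, and any genuine dependence of liking on novelty beyond its
correlation with the modeled predictors. Passing tests on synthetic data
therefore demonstrate that the pipeline measures what it claims under known
ground truth — not that real data will show the same effect sizes. In
particular, synthetic between-dyad variance is cleaner than real data, so
R² values for the liking models run higher than a real study's. Two
empirical signatures of real dyads are deliberately not built in: the
negative synchronization-complexity association (in real interactions
complex movement *causes* lower synchrony; in the generator the two emerge
slightly positively associated, because mid-strength mixtures of shared and
idiosyncratic components have more concentrated value distributions), and
the within-game rise of novelty over time (segment templates are drawn from
a stationary law). Analyses of those phenomena need real recordings.

## Numerical choices and degenerate inputs

* Z-score validity is checked to 1e-6 under either SD convention; constant
  signals raise errors at every stage that needs variance.
* Segment intervals are half-open `[start, end)` on 1-based frame indices;
  boundaries are rounded means of paired minima, deduplicated.
* Cross-correlation ties break toward the smaller absolute lag, then the
  negative lag; lags with fewer than 3 overlapping samples are skipped.
* Entropy quantization: 6 decimals by default (preserves count-derived
  discreteness; configurable for continuous data).
* Permutation p-values use the add-one rule; a statistic that fails on a
  permuted table counts as extreme (conservative) and is logged.
* Segments shorter than 3 frames get missing per-segment sync; missing
  values stay missing through the time-course resampling (all-missing
  windows yield NA rather than 0).
* Problem sizes in the test suite: property checks run on 50-65 s synthetic
  games and 4-20 dyads per property; study-scale conditions (full
  durations, 50-100 dyads, 200 replicates, 1000 null seeds) are exercised
  in the acceptance checks. These sizes are the package's own choice of
  desk-scale experiments.

## Known limitations

* The smoothing-window rule is a documented replacement for an unspecified
  heuristic; different windows move segment boundaries and, with them,
  per-segment measures.
* The binomial sign test over grid points ignores temporal autocorrelation;
  its p-values are descriptive, not calibrated.
* Granger classification depends on the order cap and on stationarity of
  the signals; no spectral or conditional variant is provided.
* Bayesian model comparison is out of scope throughout.
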