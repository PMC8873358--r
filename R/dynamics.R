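#' Median split into low- and high-liking groups
#'
#' Dyads strictly above the column's median go to the high group, strictly
#' below to the low group. Dyads exactly at the median are assigned
#' alternately (in sorted dyad-id order) to whichever group is currently
#' smaller, so the two group sizes differ by at most one.
#'
#' @param table per-dyad data frame (>= 2 rows).
#' @param column column to split on (default `liking_mean`).
#' @return A list with character vectors `low` and `high` of dyad ids.
#' @export
median_split <- function(table, column = "liking_mean") {
  stopifnot(is.data.frame(table), column %in% names(table),
            nrow(table) >= 2L)
  v <- table[[column]]
  ids <- as.character(table$dyad_id)
  med <- stats::median(v)
  low <- ids[v < med]
  high <- ids[v > med]
  ties <- sort(ids[v == med])
  for (id in ties) {
    if (length(low) <= length(high)) low <- c(low, id)
    else high <- c(high, id)
  }
  list(low = low, high = high)
}

#' Resample per-segment measures onto a common relative-time grid
#'
#' Games differ in duration, so each dyad's per-segment step function (every
#' time point inherits its segment's value) is resampled onto a common grid
#' of `G` points spanning relative time 0 (game start) to 1 (game end). Each
#' dyad's curve is then smoothed with a moving average of `smooth_s` seconds
#' (default 4 s, the average movement-segment length), converted to grid
#' points via that dyad's own duration. Missing segment values (e.g. sync in
#' very short segments) stay missing.
#'
#' @param series_list named list (names = dyad ids) of
#'   [segment_measure_series()] tables.
#' @param G number of grid points (default 1000).
#' @param measures measure columns to carry (default sync, complexity,
#'   novelty).
#' @param smooth_s smoothing window in seconds (default 4).
#' @return An object of class `"timecourse"`: `grid` (relative times),
#'   `measures` (list of dyads x G matrices), `durations`, `dyad_ids`,
#'   `smooth_s`.
#' @export
build_timecourse <- function(series_list, G = 1000L,
                             measures = c("sync", "complexity", "novelty"),
                             smooth_s = 4) {
  stopifnot(is.list(series_list), length(series_list) >= 1L, G >= 2L)
  ids <- names(series_list)
  if (is.null(ids)) stop("`series_list` must be named by dyad id",
                         call. = FALSE)
  empty <- vapply(series_list, function(s) is.null(s) || nrow(s) == 0L,
                  logical(1))
  if (any(empty)) {
    warning("excluding dyad(s) with no segments: ",
            paste(ids[empty], collapse = ", "), call. = FALSE)
    series_list <- series_list[!empty]
    ids <- ids[!empty]
  }
  grid <- (seq_len(G) - 0.5) / G
  durations <- vapply(series_list, function(s) attr(s, "duration_s"),
                      numeric(1))
  mats <- lapply(measures, function(m)
    matrix(NA_real_, length(ids), G, dimnames = list(ids, NULL)))
  names(mats) <- measures
  for (d in seq_along(ids)) {
    s <- series_list[[d]]
    dur <- durations[d]
    t_s <- grid * dur
    idx <- findInterval(t_s, s$start_s)
    idx[idx < 1L] <- 1L
    idx[idx > nrow(s)] <- nrow(s)
    w <- max(1L, as.integer(round(smooth_s / dur * G)))
    for (m in measures)
      mats[[m]][d, ] <- moving_avg_na(s[[m]][idx], w)
  }
  structure(list(grid = grid, measures = mats,
                 durations = stats::setNames(durations, ids),
                 dyad_ids = ids, smooth_s = smooth_s),
            class = "timecourse")
}

#' Pointwise comparison of two liking groups along the game
#'
#' At every grid point, compares the measure between the high- and
#' low-liking groups with a Welch two-sample t-test across dyads, reports
#' the fraction of the game during which the high group's mean exceeds the
#' low group's, and tests that fraction against chance (0.5) with an exact
#' binomial sign test over the grid points. Neighbouring grid points are
#' autocorrelated, so the sign test treats as exchangeable points that are
#' not strictly independent; the output carries this caveat.
#'
#' @param tc a [build_timecourse()] result.
#' @param low,high dyad-id vectors (each of size >= 2).
#' @param measure which measure to compare.
#' @param alpha level for counting pointwise-significant grid points.
#' @return A list of class `"group_comparison"`: `fraction_high_gt_low`,
#'   `n_higher`, `G`, `binomial_p`, `pointwise_p` (vector), `sig_fraction`,
#'   `sig_fraction_high`, `mean_high`, `mean_low`, `alpha`, `caveat`.
#' @export
compare_groups <- function(tc, low, high, measure = "sync", alpha = 0.05) {
  stopifnot(inherits(tc, "timecourse"), measure %in% names(tc$measures))
  M <- tc$measures[[measure]]
  miss <- setdiff(c(low, high), rownames(M))
  if (length(miss)) stop("unknown dyad id(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (length(low) < 2L || length(high) < 2L)
    stop("each group needs at least 2 dyads", call. = FALSE)
  A <- M[high, , drop = FALSE]
  B <- M[low, , drop = FALSE]
  col_stats <- function(X) {
    n <- colSums(!is.na(X))
    m <- colMeans(X, na.rm = TRUE)
    v <- apply(X, 2, stats::var, na.rm = TRUE)
    list(n = n, m = m, v = v)
  }
  sa <- col_stats(A); sb <- col_stats(B)
  se2 <- sa$v / sa$n + sb$v / sb$n
  tstat <- (sa$m - sb$m) / sqrt(se2)
  df <- se2^2 / ((sa$v / sa$n)^2 / (sa$n - 1) + (sb$v / sb$n)^2 / (sb$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  higher <- sa$m > sb$m
  G <- length(higher)
  n_higher <- sum(higher, na.rm = TRUE)
  bt <- stats::binom.test(n_higher, G, 0.5)
  structure(list(
    fraction_high_gt_low = n_higher / G,
    n_higher = n_higher, G = G,
    binomial_p = bt$p.value,
    pointwise_p = p,
    sig_fraction = mean(p < alpha, na.rm = TRUE),
    sig_fraction_high = mean(p < alpha & higher, na.rm = TRUE),
    mean_high = sa$m, mean_low = sb$m, alpha = alpha,
    caveat = paste("grid points are autocorrelated; the binomial sign test",
                   "treats them as exchangeable")),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> high > low at %.1f%% of the game (binomial p = %.3g)\n",
    100 * x$fraction_high_gt_low, x$binomial_p))
  invisible(x)
}

#' Trend of a group's measure over the game
#'
#' Correlates the group-mean curve of a measure with time (in seconds, using
#' the group's mean game duration as the time base) and fits the
#' corresponding least-squares line.
#'
#' @param tc a [build_timecourse()] result.
#' @param ids dyad ids forming the group.
#' @param measure measure column (default `novelty`).
#' @return A list with `r`, `slope` (per second), `intercept`, `G`.
#' @export
novelty_trend <- function(tc, ids, measure = "novelty") {
  stopifnot(inherits(tc, "timecourse"))
  M <- tc$measures[[measure]]
  miss <- setdiff(ids, rownames(M))
  if (length(miss)) stop("unknown dyad id(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  curve <- colMeans(M[ids, , drop = FALSE], na.rm = TRUE)
  t_s <- tc$grid * mean(tc$durations[ids])
  ok <- is.finite(curve)
  if (stats::sd(curve[ok]) < 1e-15)
    stop("constant curve: trend undefined", call. = FALSE)
  fit <- stats::lm(curve[ok] ~ t_s[ok])
  list(r = stats::cor(t_s[ok], curve[ok]),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       G = sum(ok))
}

#' Compare two independent Pearson correlations (Fisher z)
#'
#' Independent-groups comparison of two correlation coefficients:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with the
#' p-value from the standard normal tail.
#'
#' @param r1,r2 correlations with `|r| < 1`.
#' @param n1,n2 sample sizes (> 3).
#' @param tail `"two.sided"`, `"greater"` (r1 > r2) or `"less"`.
#' @return A list with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2,
                                 tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1", call. = FALSE)
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(tail,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(z = z, p = p)
}

#' Plot group time courses
#'
#' Basic visual of the group means (with pointwise SE bands) of one measure
#' along relative game time.
#'
#' @param tc a [build_timecourse()] result.
#' @param groups list with dyad-id vectors `low` and `high`.
#' @param measure measure to plot.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the matrix of group means.
#' @export
plot_timecourse <- function(tc, groups, measure = "sync", ...) {
  stopifnot(inherits(tc, "timecourse"))
  M <- tc$measures[[measure]]
  band <- function(ids) {
    X <- M[ids, , drop = FALSE]
    n <- colSums(!is.na(X))
    m <- colMeans(X, na.rm = TRUE)
    se <- sqrt(apply(X, 2, stats::var, na.rm = TRUE) / n)
    list(m = m, se = se)
  }
  lo <- band(groups$low); hi <- band(groups$high)
  ylim <- range(c(lo$m - lo$se, lo$m + lo$se, hi$m - hi$se, hi$m + hi$se),
                na.rm = TRUE)
  graphics::plot(tc$grid, hi$m, type = "l", col = "darkorange", ylim = ylim,
                 xlab = "relative game time", ylab = measure, ...)
  shade <- function(b, col) {
    ok <- is.finite(b$m) & is.finite(b$se)
    graphics::polygon(c(tc$grid[ok], rev(tc$grid[ok])),
                      c((b$m + b$se)[ok], rev((b$m - b$se)[ok])),
                      col = col, border = NA)
  }
  shade(hi, grDevices::adjustcolor("darkorange", 0.3))
  shade(lo, grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(tc$grid, lo$m, col = "steelblue")
  graphics::legend("topleft", c("high liking", "low liking"), lty = 1,
                   col = c("darkorange", "steelblue"), bty = "n")
  invisible(rbind(high = hi$m, low = lo$m))
}
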