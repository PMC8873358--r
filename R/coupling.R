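#' Leader-follower classification by Granger causality
#'
#' Fits a bivariate vector autoregression (VAR) to the two members' z-scored
#' motion signals and tests, in each direction, whether one member's past
#' improves the prediction of the other beyond the other's own past (Granger
#' causality). The model order is selected by AIC up to `max_order` on a
#' common estimation sample, using the two members' univariate
#' autoregressions (their summed AICs at a common order): selecting the
#' order from own-lag structure only keeps the selection independent of the
#' cross-lag coefficients, which preserves the size of the subsequent
#' tests. Each direction is then tested by an F-test that excludes the
#' cross-lag coefficients from that member's equation. Dyads
#' where both directions are significant at `alpha` are classified
#' `bidirectional` (members interchange leader and follower roles); exactly
#' one significant direction gives `leader_follower_a` (a leads b) or
#' `leader_follower_b`; neither gives `none`.
#'
#' @param a,b [motion_signal()]s (or numeric vectors) of equal length; the
#'   length must be at least `10 * max_order`.
#' @param max_order maximal VAR order considered by AIC (default 30 frames,
#'   about one second of video).
#' @param alpha per-direction significance level (default 0.05, no
#'   multiplicity correction: directions are reported per dyad).
#' @param order optional fixed order, bypassing AIC selection.
#' @return An object of class `"gca_result"`: `F_ab`, `p_ab` (a -> b),
#'   `F_ba`, `p_ba` (b -> a), `order`, `alpha`, `classification`.
#' @export
granger_direction <- function(a, b, max_order = 30L, alpha = 0.05,
                              order = NULL) {
  x <- signal_values(a); y <- signal_values(b)
  n <- length(x)
  if (length(y) != n) stop("signals must have equal length", call. = FALSE)
  max_order <- as.integer(max_order)
  if (max_order < 1L) stop("`max_order` must be >= 1", call. = FALSE)
  if (n < 10L * max_order)
    stop("signal too short: need length >= 10 * max_order", call. = FALSE)
  if (pop_sd(x) < 1e-12 || pop_sd(y) < 1e-12)
    stop("constant signal: VAR undefined", call. = FALSE)
  dyad <- if (inherits(a, "motion_signal")) a$dyad_id else "<unnamed>"

  # lag matrix: column j of Lx is x lagged by j, rows t = max_order+1 .. n
  lagmat <- function(v, p, from) {
    sapply(seq_len(p), function(j) v[(from - j):(n - j)])
  }

  if (is.null(order)) {
    from <- max_order + 1L      # common sample across candidate orders
    yx <- x[from:n]; yy <- y[from:n]
    neff <- length(yx)
    Lx <- lagmat(x, max_order, from)
    Ly <- lagmat(y, max_order, from)
    aic <- rep(NA_real_, max_order)
    for (p in seq_len(max_order)) {
      fx <- stats::lm.fit(cbind(1, Lx[, seq_len(p), drop = FALSE]), yx)
      fy <- stats::lm.fit(cbind(1, Ly[, seq_len(p), drop = FALSE]), yy)
      if (fx$rank < p + 1L || fy$rank < p + 1L)
        stop("rank-deficient VAR regression for dyad ", dyad, call. = FALSE)
      aic[p] <- neff * (log(sum(fx$residuals^2) / neff) +
                          log(sum(fy$residuals^2) / neff)) +
        2 * (2 * (p + 1))
    }
    order <- which.min(aic)
  }
  p <- as.integer(order)

  from <- p + 1L                # full sample at the chosen order
  yx <- x[from:n]; yy <- y[from:n]
  neff <- length(yx)
  Lx <- lagmat(x, p, from)
  Ly <- lagmat(y, p, from)
  test_dir <- function(resp, Lown, Lcross) {
    Xu <- cbind(1, Lown, Lcross)
    Xr <- cbind(1, Lown)
    fu <- stats::lm.fit(Xu, resp)
    fr <- stats::lm.fit(Xr, resp)
    if (fu$rank < ncol(Xu))
      stop("rank-deficient VAR regression for dyad ", dyad, call. = FALSE)
    rss_u <- sum(fu$residuals^2)
    rss_r <- sum(fr$residuals^2)
    df2 <- neff - ncol(Xu)
    Fstat <- ((rss_r - rss_u) / p) / (rss_u / df2)
    list(F = Fstat, p = stats::pf(Fstat, p, df2, lower.tail = FALSE))
  }
  ab <- test_dir(yy, Ly, Lx)    # does a's past predict b?
  ba <- test_dir(yx, Lx, Ly)    # does b's past predict a?

  sig_ab <- ab$p < alpha
  sig_ba <- ba$p < alpha
  classification <-
    if (sig_ab && sig_ba) "bidirectional"
    else if (sig_ab) "leader_follower_a"
    else if (sig_ba) "leader_follower_b"
    else "none"
  structure(list(F_ab = ab$F, p_ab = ab$p, F_ba = ba$F, p_ba = ba$p,
                 order = p, alpha = alpha, classification = classification),
            class = "gca_result")
}

#' @export
print.gca_result <- function(x, ...) {
  cat(sprintf(
    paste0("<gca_result> order %d: a->b F = %.2f (p = %.3g), ",
           "b->a F = %.2f (p = %.3g) => %s\n"),
    x$order, x$F_ab, x$p_ab, x$F_ba, x$p_ba, x$classification))
  invisible(x)
}
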