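#' Build the per-dyad analysis table
#'
#' Joins whole-game movement measures with the members' liking ratings. The
#' dyadic liking score is the mean of the two members' ratings; the minimum
#' and maximum are kept for sensitivity analyses.
#'
#' @param measures data frame with one row per dyad, containing at least
#'   `dyad_id`, `sync`, `complexity`, `novelty` (e.g. rows from
#'   [dyad_measures()]).
#' @param liking data frame with columns `dyad_id`, `rating_a`, `rating_b`
#'   (and optionally `session_id`).
#' @return A data frame with one row per dyad, the measure columns plus
#'   `liking_mean`, `liking_min`, `liking_max`.
#' @export
build_dyad_table <- function(measures, liking) {
  stopifnot(is.data.frame(measures), is.data.frame(liking))
  if (anyDuplicated(measures$dyad_id))
    stop("duplicated dyad ids in `measures`", call. = FALSE)
  if (anyDuplicated(liking$dyad_id))
    stop("duplicated dyad ids in `liking`", call. = FALSE)
  tab <- merge(measures, liking, by = "dyad_id", all.x = TRUE, sort = TRUE)
  bad <- tab$dyad_id[is.na(tab$rating_a) | is.na(tab$rating_b)]
  if (length(bad))
    stop("missing liking rating for dyad(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab$liking_mean <- (tab$rating_a + tab$rating_b) / 2
  tab$liking_min <- pmin(tab$rating_a, tab$rating_b)
  tab$liking_max <- pmax(tab$rating_a, tab$rating_b)
  tab
}

#' Exclude outlying dyads
#'
#' Drops rows whose value in any of the listed columns lies farther than
#' `k_sd` standard deviations from that column's mean. Means and SDs are
#' taken from the full table in a single pass (no iterative re-screening).
#'
#' @param table per-dyad data frame (see [build_dyad_table()]).
#' @param columns character vector of columns to screen.
#' @param k_sd exclusion threshold in SDs (default 3).
#' @return The filtered table; the dropped ids are in attribute `"excluded"`
#'   and reported via `message()`.
#' @export
exclude_outliers <- function(table, columns = c("complexity", "liking_mean"),
                             k_sd = 3) {
  stopifnot(is.data.frame(table), all(columns %in% names(table)))
  if (!is.finite(k_sd)) {
    attr(table, "excluded") <- character(0)
    return(table)
  }
  out <- rep(FALSE, nrow(table))
  for (col in columns) {
    v <- table[[col]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) next
    out <- out | abs(v - mean(v)) > k_sd * s
  }
  dropped <- table$dyad_id[out]
  if (length(dropped))
    message("excluding ", length(dropped), " outlier dyad(s): ",
            paste(dropped, collapse = ", "))
  res <- table[!out, , drop = FALSE]
  attr(res, "excluded") <- as.character(dropped)
  res
}

#' Pairwise Pearson correlations between dyad-level measures
#'
#' @param table per-dyad data frame with at least 4 complete rows.
#' @param pairs list of 2-element character vectors naming column pairs;
#'   default: all pairs among sync, complexity, novelty, liking_mean (those
#'   present).
#' @return Data frame with columns `x`, `y`, `n`, `r`, `p` (two-tailed),
#'   `ci_lo`, `ci_hi` (Fisher-z 95% CI).
#' @export
pairwise_correlations <- function(table, pairs = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(pairs)) {
    vars <- intersect(c("sync", "complexity", "novelty", "liking_mean"),
                      names(table))
    cmb <- utils::combn(vars, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  res <- lapply(pairs, function(pr) {
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4L) stop("fewer than 4 complete rows for ",
                           pr[1], " vs ", pr[2], call. = FALSE)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("constant column in pair ", pr[1], " vs ", pr[2], call. = FALSE)
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(x = pr[1], y = pr[2], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Nested linear models of dyadic liking
#'
#' Fits the three nested ordinary-least-squares models of mean dyadic
#' liking: M1 with synchronization only, M2 adding complexity, M3 adding
#' novelty. Each fit reports raw and standardized coefficients, R-squared,
#' the overall F-test, and the incremental F-test against the previous
#' model (M1 is compared against the intercept-only model).
#'
#' @param table per-dyad data frame with at least 10 complete rows of the
#'   response and predictors.
#' @param response response column (default `liking_mean`).
#' @return A list of class `"liking_models"` with elements `m1`, `m2`, `m3`;
#'   each holds `fit` (the `lm` object), `coefficients`, `std_beta`, `r2`,
#'   `F`, `df`, `p`, `delta_r2`, `delta_F`, `delta_p`, `n`.
#' @export
fit_liking_models <- function(table, response = "liking_mean") {
  preds <- c("sync", "complexity", "novelty")
  stopifnot(is.data.frame(table),
            all(c(response, preds) %in% names(table)))
  dat <- table[stats::complete.cases(table[, c(response, preds)]), ,
               drop = FALSE]
  if (nrow(dat) < 10L) stop("need at least 10 complete rows", call. = FALSE)

  fits <- vector("list", 3)
  prev <- stats::lm(stats::reformulate("1", response), data = dat)
  prev_r2 <- 0
  for (k in 1:3) {
    f <- stats::reformulate(preds[seq_len(k)], response)
    fit <- stats::lm(f, data = dat)
    if (fit$rank < k + 1L)
      stop("collinear predictors: ",
           paste(preds[seq_len(k)], collapse = ", "), call. = FALSE)
    sm <- summary(fit)
    cf <- stats::coef(fit)
    sdy <- stats::sd(dat[[response]])
    std <- vapply(preds[seq_len(k)],
                  function(pv) cf[[pv]] * stats::sd(dat[[pv]]) / sdy,
                  numeric(1))
    an <- stats::anova(prev, fit)
    fits[[k]] <- list(
      fit = fit,
      coefficients = cf,
      std_beta = std,
      r2 = sm$r.squared,
      F = unname(sm$fstatistic[1]),
      df = unname(sm$fstatistic[2:3]),
      p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE),
      delta_r2 = sm$r.squared - prev_r2,
      delta_F = an$F[2],
      delta_p = an$`Pr(>F)`[2],
      n = nrow(dat))
    prev <- fit
    prev_r2 <- sm$r.squared
  }
  structure(list(m1 = fits[[1]], m2 = fits[[2]], m3 = fits[[3]]),
            class = "liking_models")
}

#' @export
print.liking_models <- function(x, ...) {
  for (nm in c("m1", "m2", "m3")) {
    m <- x[[nm]]
    cat(sprintf(
      "%s: R2 = %.3f, F(%d, %d) = %.2f, p = %.3g (dR2 = %.3f, p = %.3g)\n",
      toupper(nm), m$r2, m$df[1], m$df[2], m$F, m$p, m$delta_r2, m$delta_p))
  }
  invisible(x)
}

#' Round-robin permutation test by dyadic label shuffling
#'
#' Because each participant plays in several dyads, the dyads are not
#' independent; significance is therefore assessed against a null
#' distribution obtained by randomly shuffling the dyadic labels of one
#' variable (decoupling it from the others while preserving every observed
#' value). The p-value uses the add-one rule
#' `p = (#{extreme permutations} + 1) / (n_perm + 1)`, so it is never zero.
#'
#' @param table per-dyad data frame.
#' @param statistic function mapping a table to a scalar statistic.
#' @param target name of the column whose dyadic labels are shuffled.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional seed; the caller's RNG stream is preserved.
#' @param alternative `"two.sided"` (compare `|T|`), `"greater"`, or
#'   `"less"`.
#' @return A list of class `"permutation_test"`: `observed`, `p`, `n_perm`,
#'   `alternative`, `n_failed` (permutations where the statistic failed;
#'   these count as extreme and trigger a warning).
#' @export
permutation_test <- function(table, statistic, target, n_perm = 10000L,
                             seed = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(table), is.function(statistic),
            target %in% names(table), n_perm >= 1L)
  obs <- statistic(table)
  if (!is.finite(obs)) stop("observed statistic is not finite", call. = FALSE)
  run <- function() {
    vals <- table[[target]]
    perm <- table
    stats_out <- rep(NA_real_, n_perm)
    for (i in seq_len(n_perm)) {
      perm[[target]] <- sample(vals)
      stats_out[i] <- tryCatch(statistic(perm), error = function(e) NA_real_)
    }
    stats_out
  }
  perm_stats <- if (is.null(seed)) run() else local_seed(seed, run())
  failed <- !is.finite(perm_stats)
  n_failed <- sum(failed)
  if (n_failed)
    warning(n_failed, " permutation(s) failed; counted as extreme",
            call. = FALSE)
  extreme <- switch(alternative,
    two.sided = abs(perm_stats) >= abs(obs),
    greater = perm_stats >= obs,
    less = perm_stats <= obs)
  extreme[failed] <- TRUE
  p <- (sum(extreme) + 1) / (n_perm + 1)
  structure(list(observed = obs, p = p, n_perm = as.integer(n_perm),
                 alternative = alternative, n_failed = n_failed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed = %.4g, permuted p = %.4g (%s, %d perms)\n",
              x$observed, x$p, x$alternative, x$n_perm))
  invisible(x)
}
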