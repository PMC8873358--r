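#' Analyze one dyad end to end
#'
#' Z-scores both members (unless already z-scored), segments the recording
#' into shared movements, and computes the whole-game and per-segment
#' measures; optionally the Granger-causality coupling classification.
#'
#' @param record a [dyad_record()].
#' @param params optional [segmentation_params()].
#' @param quantization decimals for the entropy value count.
#' @param max_lag_s maximal lag for the cross-correlation synchronization.
#' @param gca if `TRUE`, also run [granger_direction()].
#' @param gca_max_order maximal VAR order for the GCA (default 30).
#' @return A list with `measures` (one-row data frame), `series`
#'   ([segment_measure_series()]), `segmentation`, and (if requested)
#'   `granger`.
#' @export
analyze_dyad <- function(record, params = NULL, quantization = 6,
                         max_lag_s = 5, gca = FALSE, gca_max_order = 30L) {
  stopifnot(inherits(record, "dyad_record"))
  za <- if (record$a$is_zscored) record$a else zscore(record$a)
  zb <- if (record$b$is_zscored) record$b else zscore(record$b)
  seg <- segment_dyad(za, zb, params)
  series <- segment_measure_series(za, zb, seg, quantization)
  measures <- dyad_measures(za, zb, seg, max_lag_s, quantization)
  out <- list(measures = measures, series = series, segmentation = seg)
  if (gca) out$granger <- granger_direction(za, zb, gca_max_order)
  out
}

#' Analyze many dyads
#'
#' Runs [analyze_dyad()] over a list of records and stacks the whole-game
#' measures into one table.
#'
#' @param records named list of [dyad_record()]s.
#' @param ... passed to [analyze_dyad()].
#' @return A list with `table` (one row per dyad) and `series` (named list
#'   of per-segment series for [build_timecourse()]).
#' @export
measure_study <- function(records, ...) {
  stopifnot(is.list(records), length(records) >= 1L)
  res <- lapply(records, analyze_dyad, ...)
  table <- do.call(rbind, lapply(res, `[[`, "measures"))
  rownames(table) <- NULL
  series <- lapply(res, `[[`, "series")
  names(series) <- vapply(records, function(r) r$dyad_id, character(1))
  list(table = table, series = series, results = res)
}
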