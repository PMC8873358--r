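#' Region-of-interest specification for a two-person video
#'
#' One rectangle per member, in pixel coordinates (x = column, y = row,
#' 1-based inclusive). The two rectangles must be disjoint so each member's
#' motion is counted separately.
#'
#' @param member_a,member_b integer vectors `c(x0, y0, x1, y1)`.
#' @return An object of class `"roi_spec"`.
#' @export
roi_spec <- function(member_a, member_b) {
  chk <- function(r, who) {
    if (length(r) != 4L || any(!is.finite(r)))
      stop("ROI for ", who, " must be c(x0, y0, x1, y1)", call. = FALSE)
    if (r[1] > r[3] || r[2] > r[4])
      stop("ROI for ", who, " has x0 > x1 or y0 > y1", call. = FALSE)
    as.integer(r)
  }
  a <- chk(member_a, "member_a")
  b <- chk(member_b, "member_b")
  overlap <- a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
  if (overlap) stop("the two members' ROIs must be disjoint", call. = FALSE)
  structure(list(member_a = a, member_b = b), class = "roi_spec")
}

#' Split a frame vertically into two member ROIs
#'
#' Default ROI layout when both players are filmed by one camera: the left
#' half of the frame is member a, the right half member b.
#'
#' @param width,height frame size in pixels.
#' @return A [roi_spec()].
#' @export
roi_vertical_split <- function(width, height) {
  mid <- width %/% 2L
  roi_spec(member_a = c(1L, 1L, mid, height),
           member_b = c(mid + 1L, 1L, width, height))
}

#' Compute motion energy from grayscale video frames
#'
#' Motion energy is the frame-by-frame count of pixels, inside a member's
#' region of interest, whose absolute intensity change between consecutive
#' frames exceeds a noise threshold. Because camera and lighting are static,
#' such changes index body motion. The output has one value per frame
#' transition (length = number of frames - 1) and consists of nonnegative
#' integer counts.
#'
#' @param frames a list of numeric matrices (rows = y, columns = x) or a 3-D
#'   array `[y, x, frame]`, all frames the same size; at least two frames.
#' @param roi a [roi_spec()]; both rectangles must fit inside the frame.
#' @param noise_threshold nonnegative intensity change below which a pixel is
#'   treated as video noise (default 10 on an 8-bit scale).
#' @param fps sampling rate recorded on the output signals.
#' @param dyad_id identifier carried on the output signals.
#' @return A list with `motion_signal`s `a` and `b`.
#' @export
compute_mea <- function(frames, roi, noise_threshold = 10, fps = 29.97,
                        dyad_id = NA_character_) {
  stopifnot(inherits(roi, "roi_spec"))
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) < 2L)
    stop("need at least 2 frames", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same size", call. = FALSE)
  if (!is.finite(noise_threshold) && noise_threshold != Inf)
    stop("`noise_threshold` must be nonnegative (Inf allowed)", call. = FALSE)
  if (noise_threshold < 0)
    stop("`noise_threshold` must be nonnegative", call. = FALSE)
  h <- dims[1, 1]; w <- dims[2, 1]
  idx <- function(r) {
    if (r[1] < 1 || r[2] < 1 || r[3] > w || r[4] > h)
      stop("ROI outside frame bounds", call. = FALSE)
    list(rows = r[2]:r[4], cols = r[1]:r[3])
  }
  ia <- idx(roi$member_a); ib <- idx(roi$member_b)
  n <- length(frames)
  va <- integer(n - 1L); vb <- integer(n - 1L)
  for (t in seq_len(n - 1L)) {
    d <- abs(frames[[t + 1L]] - frames[[t]])
    va[t] <- sum(d[ia$rows, ia$cols] > noise_threshold)
    vb[t] <- sum(d[ib$rows, ib$cols] > noise_threshold)
  }
  list(a = motion_signal(va, fps = fps, member_id = "a", dyad_id = dyad_id),
       b = motion_signal(vb, fps = fps, member_id = "b", dyad_id = dyad_id))
}

#' Read a per-dyad motion-energy table
#'
#' Canonical on-disk format: a UTF-8 CSV with a header row and columns
#' `member_a` and `member_b` (an optional `frame` column is ignored), one row
#' per frame. If one member's column ends in a run of missing values (a NaN
#' tail from unequal recording lengths), both signals are trimmed to the
#' common length with a warning; missing values elsewhere are an error.
#'
#' @param path file to read.
#' @param fps sampling rate of the recording (default 29.97).
#' @param dyad_id,session_id identifiers for the returned record; `dyad_id`
#'   defaults to the file name without extension.
#' @return A [dyad_record()] (liking ratings are `NA`; see
#'   [build_dyad_table()] for joining ratings).
#' @export
read_mea_table <- function(path, fps = 29.97, dyad_id = NULL,
                           session_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dyad_id)) dyad_id <- sub("\\.[^.]*$", "", basename(path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  for (col in c("member_a", "member_b")) {
    if (!col %in% names(df))
      stop(path, " lacks required column `", col, "`", call. = FALSE)
    if (!is.numeric(df[[col]])) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(num) & !is.na(df[[col]]) &
                     !toupper(df[[col]]) %in% c("NAN", "NA", ""))
      if (length(bad))
        stop("unparseable value in ", path, ", column `", col,
             "`, data row ", bad[1], call. = FALSE)
      df[[col]] <- num
    }
  }
  last_ok <- function(v) { w <- which(!is.na(v)); if (length(w)) max(w) else 0L }
  n_keep <- min(last_ok(df$member_a), last_ok(df$member_b))
  if (n_keep < 2L)
    stop(path, ": fewer than 2 usable rows per member", call. = FALSE)
  if (n_keep < nrow(df)) {
    warning(sprintf("%s: trimmed to %d rows (unequal member lengths)",
                    path, n_keep), call. = FALSE)
    df <- df[seq_len(n_keep), , drop = FALSE]
  }
  if (anyNA(df$member_a) || anyNA(df$member_b))
    stop(path, ": missing values inside the recording", call. = FALSE)
  dyad_record(
    motion_signal(df$member_a, fps = fps, member_id = "a", dyad_id = dyad_id),
    motion_signal(df$member_b, fps = fps, member_id = "b", dyad_id = dyad_id),
    dyad_id = dyad_id, session_id = session_id)
}

#' Write a dyad record to the canonical CSV layout
#'
#' @param record a [dyad_record()].
#' @param path output file; columns `frame, member_a, member_b`.
#' @return `path`, invisibly.
#' @export
write_mea_table <- function(record, path) {
  stopifnot(inherits(record, "dyad_record"))
  df <- data.frame(frame = seq_along(record$a$values),
                   member_a = record$a$values,
                   member_b = record$b$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
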