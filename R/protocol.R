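#' Ground-truth protocol of activity segments
#'
#' A protocol is the annotation of one recorded session: an ordered set of
#' labeled segments (break / dip / pullup / squat) that tile the recording
#' without gaps or overlaps, each exercise segment carrying its repetition
#' count. Segments use 0-based, half-open `[start, end)` sample indexing.
#'
#' Invariants enforced: segments tile `[0, N)`; `start < end`; consecutive
#' segments carry different labels; every pair of consecutive exercise
#' segments is separated by a break (sessions always pause between
#' activities); `repetitions` is present exactly for non-break segments.
#'
#' @param label Character vector of activity labels (see
#'   [activity_levels()]).
#' @param start,end Integer vectors, 0-based half-open sample bounds.
#' @param repetitions Integer vector, `NA` for break segments.
#' @return A data.frame of class `protocol` with columns `label`, `start`,
#'   `end`, `repetitions`.
#' @export
#' @examples
#' protocol(c("break", "squat", "break"), c(0, 100, 400), c(100, 400, 500),
#'          c(NA, 5, NA))
protocol <- function(label, start, end, repetitions) {
  p <- data.frame(label = as.character(label),
                  start = as.integer(start),
                  end = as.integer(end),
                  repetitions = as.integer(repetitions),
                  stringsAsFactors = FALSE)
  class(p) <- c("protocol", "data.frame")
  validate_protocol(p)
  p
}

#' @rdname protocol
#' @param p Object to validate.
#' @export
validate_protocol <- function(p) {
  stopifnot(is.data.frame(p),
            all(c("label", "start", "end", "repetitions") %in% names(p)))
  if (nrow(p) == 0L) stop("protocol must contain at least one segment")
  if (!all(p$label %in% activity_levels())) {
    stop("unknown activity label(s): ",
         paste(setdiff(p$label, activity_levels()), collapse = ", "))
  }
  if (any(p$start >= p$end)) stop("every segment must satisfy start < end")
  if (p$start[1] != 0L) stop("protocol must start at sample 0")
  if (nrow(p) > 1L) {
    if (any(p$start[-1] != p$end[-nrow(p)])) {
      stop("segments must tile the recording without gaps or overlaps")
    }
    if (any(p$label[-1] == p$label[-nrow(p)])) {
      stop("consecutive segments must have different labels")
    }
    ex <- p$label != "break"
    run <- rle(ex)
    if (any(run$values & run$lengths > 1L)) {
      stop("consecutive exercise segments must be separated by a break")
    }
  }
  is_break <- p$label == "break"
  if (any(is_break & !is.na(p$repetitions))) {
    stop("break segments must not carry repetition counts")
  }
  if (any(!is_break & (is.na(p$repetitions) | p$repetitions < 0L))) {
    stop("exercise segments must carry a nonnegative repetition count")
  }
  invisible(p)
}

#' Per-sample label vector of a protocol
#'
#' @param p A `protocol` (or any segment table with `label`, `start`, `end`).
#' @return Character vector of length `max(p$end)`: the activity label of
#'   each sample.
#' @export
protocol_sample_labels <- function(p) {
  rep(p$label, p$end - p$start)
}

#' Scenario of a protocol
#'
#' The scenario is the ordered sequence of non-break activities performed
#' in a session (e.g. pull-ups, dips, squats). Repeated labels are legal:
#' two squat series separated by a break give scenario
#' `c("squat", "squat")`.
#'
#' @param p A `protocol` or segment table.
#' @return Character vector of non-break labels in order (possibly empty).
#' @export
protocol_scenario <- function(p) {
  p$label[p$label != "break"]
}

#' Read and write recordings and annotations
#'
#' Recordings are stored as plain CSV with header
#' `t,chest_ax,chest_ay,chest_az,hand_ax,hand_ay,hand_az` (`t` in seconds)
#' plus a JSON sidecar `<path>.json` holding the sampling rate and channel
#' order. Columns may appear in any order in the file; reading restores
#' the canonical order. Annotations are CSV with header
#' `label,start,end,repetitions` (samples, 0-based half-open; empty
#' repetitions for breaks).
#'
#' @param path File path.
#' @return `read_recording` returns a `signal_matrix`;
#'   `read_annotations` returns a `protocol`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("recording file lacks a 't' column: ", path)
  chan_cols <- setdiff(names(df), "t")
  required <- canonical_channels()
  missing <- setdiff(required, chan_cols)
  if (length(missing) > 0L) {
    stop("recording file lacks required channel column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(diff(df$t) <= 0)) stop("non-monotone timestamps in ", path)
  meta_path <- paste0(path, ".json")
  rate <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)$rate
  } else if (nrow(df) > 1L) {
    1 / stats::median(diff(df$t))
  } else {
    30
  }
  extra <- setdiff(chan_cols, required)
  ord <- c(required, extra)
  signal_matrix(as.matrix(df[ord]), rate = as.numeric(rate), channels = ord)
}

#' @rdname read_recording
#' @param sig A `signal_matrix` to write.
#' @param digits Decimal digits written for signal values (default 6,
#'   lossless for read-back comparisons at that precision).
#' @export
write_recording <- function(sig, path, digits = 6) {
  stopifnot(inherits(sig, "signal_matrix"))
  if (!all(canonical_channels() %in% sig$channels)) {
    stop("write_recording requires the full canonical channel set")
  }
  t <- (seq_len(nrow(sig$samples)) - 1L) / sig$rate
  df <- data.frame(t = round(t, 6), round(sig$samples, digits),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rate = sig$rate, channels = sig$channels,
                            n_samples = nrow(sig$samples)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname read_recording
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  protocol(df$label, df$start, df$end, df$repetitions)
}

#' @rdname read_recording
#' @param p A `protocol` to write.
#' @export
write_annotations <- function(p, path) {
  validate_protocol(p)
  utils::write.csv(as.data.frame(p), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
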