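#' Post-processing block configuration
#'
#' Thresholds for converting raw per-sample classifier outputs into clean
#' activity segments: the moving-average window `w`, the minimum
#' run lengths `delta1` (a 1-run of at most `delta1` samples is a spurious
#' peak and is removed) and `delta0` (a 0-run of at most `delta0` samples
#' is a spurious gap and is filled), and the binarization threshold.
#' Defaults (`w = 50`, `delta1 = 90`, `delta0 = 60`) were chosen from the
#' corpus duration statistics: the shortest activity occurrence is 91
#' samples and the shortest break 63, so genuine activity runs and breaks
#' survive while classifier glitches do not.
#'
#' @param w Moving-average window, samples.
#' @param delta1 Peak-elimination threshold, samples.
#' @param delta0 Gap-filling threshold, samples.
#' @param threshold Binarization probability threshold.
#' @return A list of class `ppb_config`.
#' @export
ppb_config <- function(w = 50L, delta1 = 90L, delta0 = 60L, threshold = 0.5) {
  stopifnot(w >= 1L, delta1 >= 1L, delta0 >= 1L,
            threshold >= 0, threshold <= 1)
  structure(list(w = as.integer(w), delta1 = as.integer(delta1),
                 delta0 = as.integer(delta0), threshold = threshold),
            class = "ppb_config")
}

#' Forward moving-average filter
#'
#' Smooths a series with a forward-looking moving average: the output at
#' sample `i` is the mean of the `w` samples starting at `i`. Near the end
#' of the series the window is truncated, so the tail averages over fewer
#' samples and the output has the same length as the input.
#'
#' @param y Numeric series.
#' @param w Window length in samples (`w = 1` is the identity).
#' @return Numeric series, same length as `y`.
#' @export
#' @examples
#' moving_average(c(0, 0, 2, 2), 2)  # 0 1 2 2
moving_average <- function(y, w) {
  n <- length(y)
  stopifnot(n >= 1L, w >= 1L)
  cs <- c(0, cumsum(y))
  i <- seq_len(n)
  hi <- pmin(i + w - 1L, n)
  (cs[hi + 1L] - cs[i]) / (hi - i + 1L)
}

#' Binarize a probability series
#'
#' @param p Numeric series of probabilities in `[0, 1]` (or a matrix,
#'   processed per column).
#' @param threshold Values `>= threshold` map to 1, others to 0.
#' @return Integer 0/1 series (or matrix).
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- (p >= threshold) + 0L
  out
}

# Apply the run-length rule: runs of `value` whose length is <= delta are
# flipped; longer runs are kept.
flip_short_runs <- function(b, value, delta) {
  stopifnot(all(b %in% c(0L, 1L)))
  r <- rle(as.integer(b))
  flip <- r$values == value & r$lengths <= delta
  r$values[flip] <- 1L - value
  inverse.rle(r)
}

#' Eliminate short peaks in a binary stream
#'
#' A sample keeps the value 1 only if it lies in a maximal run of 1s whose
#' length exceeds `delta1`; shorter 1-runs (spurious activations) are set
#' to 0. The comparison is strict: a run of exactly `delta1` samples is
#' removed.
#'
#' @param b Integer 0/1 series.
#' @param delta1 Run-length threshold; only 1-runs strictly longer survive.
#' @return Integer 0/1 series.
#' @export
#' @examples
#' eliminate_peaks(c(0, 0, 1, 1, 0), 3)  # all zeros
eliminate_peaks <- function(b, delta1) {
  flip_short_runs(b, 1L, delta1)
}

#' Fill short gaps in a binary stream
#'
#' The dual of [eliminate_peaks()]: a sample keeps the value 0 only if it
#' lies in a maximal run of 0s longer than `delta0`; shorter 0-runs
#' (spurious dropouts inside an activity) are set to 1.
#'
#' @param b Integer 0/1 series.
#' @param delta0 Run-length threshold; only 0-runs strictly longer survive.
#' @return Integer 0/1 series.
#' @export
#' @examples
#' fill_gaps(c(1, 1, 0, 0, 1, 1), 3)  # all ones
fill_gaps <- function(b, delta0) {
  flip_short_runs(b, 0L, delta0)
}

#' Post-process per-sample class probabilities into binary streams
#'
#' The two-stage cleanup applied to each class output independently:
#' moving-average smoothing, binarization, then run-length cleanup -
#' peaks removed first, gaps filled second (filling last avoids
#' re-fragmenting an activity block that peak removal just cleaned).
#'
#' @param probs N x 4 matrix of per-sample class probabilities (from
#'   [sample_probabilities()]).
#' @param cfg A [ppb_config()].
#' @return N x 4 integer 0/1 matrix, one cleaned stream per class.
#' @export
postprocess <- function(probs, cfg = ppb_config()) {
  stopifnot(is.matrix(probs), ncol(probs) == 4L)
  out <- apply(probs, 2L, function(p) {
    b <- binarize(moving_average(p, cfg$w), cfg$threshold)
    fill_gaps(eliminate_peaks(b, cfg$delta1), cfg$delta0)
  })
  colnames(out) <- activity_levels()
  out
}

#' Read labeled segments off cleaned binary streams
#'
#' Assigns each sample a single label and compresses maximal runs into
#' segments. Per sample: if exactly one exercise stream is active, that
#' exercise; if none, break; if several overlap (possible because the
#' streams are cleaned independently), the exercise that has been active
#' for the longest contiguous stretch up to that sample wins, ties going
#' to the earlier class in [activity_levels()] order.
#'
#' @param binaries N x 4 0/1 matrix from [postprocess()]; the break
#'   column is ignored (break is the absence of any exercise).
#' @return A data.frame of class `segment_list` (`label`, `start`, `end`,
#'   0-based half-open) tiling `[0, N)` with alternating labels.
#' @export
streams_to_segments <- function(binaries) {
  stopifnot(is.matrix(binaries), ncol(binaries) == 4L)
  N <- nrow(binaries)
  ex <- binaries[, 2:4, drop = FALSE]
  # contiguous active-run length per exercise class, up to each sample
  runlen <- apply(ex, 2L, function(b) {
    r <- rle(as.integer(b))
    cum <- sequence(r$lengths)
    cum[rep(r$values, r$lengths) == 0L] <- 0L
    cum
  })
  runlen <- matrix(runlen, nrow = N)
  active <- ex == 1L
  n_active <- rowSums(active)
  winner <- rep("break", N)
  one <- n_active == 1L
  if (any(one)) {
    winner[one] <- exercise_levels()[max.col(active[one, , drop = FALSE],
                                             ties.method = "first")]
  }
  multi <- n_active > 1L
  if (any(multi)) {
    score <- runlen[multi, , drop = FALSE] * active[multi, , drop = FALSE]
    winner[multi] <- exercise_levels()[max.col(score, ties.method = "first")]
  }
  r <- rle(winner)
  end <- cumsum(r$lengths)
  segs <- data.frame(label = r$values,
                     start = as.integer(c(0L, end[-length(end)])),
                     end = as.integer(end), stringsAsFactors = FALSE)
  class(segs) <- c("segment_list", "data.frame")
  segs
}

#' Extract the recognized scenario from segments
#'
#' @param segs A `segment_list` (or `protocol`).
#' @return Character vector of the non-break labels in order.
#' @export
extract_scenario <- function(segs) {
  segs$label[segs$label != "break"]
}

#' Run the full activity-recognition module over a recording
#'
#' Streams step-1 window probabilities, aligns them to samples,
#' post-processes each class stream and extracts segments and the
#' scenario.
#'
#' @param model A trained `cnn_model`.
#' @param sig A `signal_matrix` (raw; z-scored automatically when the
#'   model was trained on normalized data).
#' @param cfg A [ppb_config()].
#' @return A list: `segments` (a `segment_list`), `scenario` (character
#'   vector), `sample_probs` (N x 4), `binaries` (N x 4).
#' @export
recognize_activities <- function(model, sig, cfg = ppb_config()) {
  if (model$normalization == "zscore") {
    sig <- normalize_signal(sig, model$channel_stats)
  }
  ps <- stream_probabilities(model, sig)
  probs <- sample_probabilities(ps)
  binaries <- postprocess(probs, cfg)
  segs <- streams_to_segments(binaries)
  list(segments = segs, scenario = extract_scenario(segs),
       sample_probs = probs, binaries = binaries)
}
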