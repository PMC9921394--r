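#' Repetition-counter configuration
#'
#' Per-activity parameters of the repetition-counting module, derived
#' from the corpus repetition-duration statistics: which channels carry
#' the repetition waveform, the Butterworth low-pass order and normalized
#' cutoff `Wn = fc / (0.5 fs)` (at 30 Hz, `Wn = 0.05` means a 0.75 Hz
#' cutoff), and the minimum peak spacing in samples (just below the
#' fastest observed single repetition).
#'
#' @param channels Named list mapping each exercise to its counting
#'   channels.
#' @param order Butterworth filter order (shared).
#' @param Wn Named numeric, per-exercise normalized cutoff in (0, 1).
#' @param min_distance Named numeric, per-exercise minimum peak spacing
#'   in samples.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   filtered segment's value range; 0 disables the prominence floor.
#' @param polarity How repetition excursions of unknown sign are counted.
#'   `"max"` (default) counts both the signal's peaks and its troughs
#'   (peaks of the negated signal) and takes the larger count - for a
#'   train of n single-sided excursions the excursion side yields n and
#'   the other side at most n - 1 interior troughs, so the rule is
#'   sign-agnostic without overcounting. `"median"` picks the side with
#'   the larger excursion from the median; `"positive"`/`"negative"`
#'   force one side.
#' @return A list of class `rcm_config`.
#' @export
rcm_config <- function(channels = list(dip = informative_channels("dip"),
                                       pullup = informative_channels("pullup"),
                                       squat = informative_channels("squat")),
                       order = 2L,
                       Wn = c(dip = 0.05, pullup = 0.04, squat = 0.06),
                       min_distance = c(dip = 40, pullup = 50, squat = 30),
                       prominence_frac = 0.1,
                       polarity = c("max", "median", "positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(all(exercise_levels() %in% names(channels)),
            all(exercise_levels() %in% names(Wn)),
            all(exercise_levels() %in% names(min_distance)),
            all(Wn > 0 & Wn < 1), all(min_distance >= 1),
            all(lengths(channels[exercise_levels()]) >= 1L),
            prominence_frac >= 0, order >= 1L)
  structure(list(channels = channels, order = as.integer(order), Wn = Wn,
                 min_distance = min_distance,
                 prominence_frac = prominence_frac, polarity = polarity),
            class = "rcm_config")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward filtering with a Butterworth low-pass design, giving
#' zero phase shift (peaks stay put) and an effective magnitude response
#' of `|H(f)|^2`. The series is extended at both ends by odd reflection
#' before filtering to suppress edge transients, then trimmed back.
#'
#' @param x Numeric series, length greater than `3 * order`.
#' @param order Filter order.
#' @param Wn Normalized cutoff frequency, fraction of Nyquist, in (0, 1).
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' lowpass(rep(2, 100), 2, 0.06)  # constant in, constant out
lowpass <- function(x, order = 2L, Wn) {
  n <- length(x)
  if (n <= 3L * order) stop("series too short to filter (length ", n, ")")
  stopifnot(Wn > 0, Wn < 1)
  bf <- signal::butter(order, Wn, type = "low")
  pad <- min(n - 1L, max(3L * (order + 1L), ceiling(6 / Wn)))
  left <- 2 * x[1] - x[pad + 1L - seq_len(pad) + 1L]
  right <- 2 * x[n] - x[n - seq_len(pad)]
  xe <- c(left, x, right)
  ye <- signal::filtfilt(bf, xe)
  ye[pad + seq_len(n)]
}

# Locations of local maxima, plateaus resolved to their midpoint.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- sign(diff(x))
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(length(nz) - 1L)) {
    if (d[nz[i]] == 1 && d[nz[i + 1L]] == -1) {
      out <- c(out, (nz[i] + 1L + nz[i + 1L]) %/% 2L)
    }
  }
  out
}

# Topographic prominence of peak at position p: height above the higher
# of the two bases (the minima separating it from higher terrain or the
# series ends).
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- if (p == 1L) h else {
    seg <- x[(p - 1L):1L]
    stop_at <- which(seg > h)[1]
    if (!is.na(stop_at)) min(seg[seq_len(stop_at)]) else min(seg)
  }
  right <- if (p == length(x)) h else {
    seg <- x[(p + 1L):length(x)]
    stop_at <- which(seg > h)[1]
    if (!is.na(stop_at)) min(seg[seq_len(stop_at)]) else min(seg)
  }
  h - max(left, right)
}

#' Count peaks with prominence and spacing constraints
#'
#' Counts local maxima that (a) have topographic prominence of at least
#' `prominence_frac` times the series value range and (b) survive
#' highest-first greedy suppression of peaks closer than `min_distance`
#' samples to an already-kept peak. A constant series has no peaks.
#'
#' @param x Numeric series.
#' @param min_distance Minimum spacing between counted peaks, samples.
#' @param prominence_frac Prominence floor as a fraction of
#'   `max(x) - min(x)`; 0 disables it.
#' @return Integer peak count.
#' @export
#' @examples
#' count_peaks(rep(1, 50), 40)  # 0
count_peaks <- function(x, min_distance, prominence_frac = 0.1) {
  stopifnot(length(x) >= 1L, min_distance >= 1)
  rng <- max(x) - min(x)
  if (rng == 0) return(0L)
  cand <- local_maxima(x)
  if (length(cand) == 0L) return(0L)
  if (prominence_frac > 0) {
    prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
    cand <- cand[prom >= prominence_frac * rng]
    if (length(cand) == 0L) return(0L)
  }
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(kept - p) >= min_distance)) kept <- c(kept, p)
  }
  length(kept)
}

# Peak count of one filtered channel under the configured polarity rule.
count_channel <- function(y, min_distance, prominence_frac, polarity) {
  switch(polarity,
    positive = count_peaks(y, min_distance, prominence_frac),
    negative = count_peaks(-y, min_distance, prominence_frac),
    max = max(count_peaks(y, min_distance, prominence_frac),
              count_peaks(-y, min_distance, prominence_frac)),
    median = {
      med <- stats::median(y)
      if (max(y) - med >= med - min(y)) {
        count_peaks(y, min_distance, prominence_frac)
      } else {
        count_peaks(-y, min_distance, prominence_frac)
      }
    })
}

#' Count repetitions within one exercise segment
#'
#' For each of the activity's configured channels, the segment slice is
#' low-pass filtered ([lowpass()]) and its peaks counted
#' ([count_peaks()]); the repetition estimate is the per-channel mean,
#' rounded half-up to an integer.
#'
#' @param sig A `signal_matrix` (raw signals).
#' @param seg One-row segment (list or data.frame row with `label`,
#'   `start`, `end`; 0-based half-open). Must not be a break.
#' @param cfg An [rcm_config()].
#' @return Integer repetition count; the per-channel counts are attached
#'   as attribute `"per_channel"`.
#' @export
count_repetitions <- function(sig, seg, cfg = rcm_config()) {
  stopifnot(inherits(sig, "signal_matrix"))
  label <- as.character(seg$label)
  if (label == "break") stop("cannot count repetitions of a break segment")
  stopifnot(seg$start >= 0L, seg$end <= n_samples(sig), seg$start < seg$end)
  rows <- (seg$start + 1L):seg$end
  chans <- cfg$channels[[label]]
  counts <- vapply(chans, function(ch) {
    y <- lowpass(sig$samples[rows, ch], cfg$order, cfg$Wn[[label]])
    as.numeric(count_channel(y, cfg$min_distance[[label]],
                             cfg$prominence_frac, cfg$polarity))
  }, numeric(1))
  structure(as.integer(floor(mean(counts) + 0.5)), per_channel = counts)
}

#' Count repetitions for every exercise segment of a recording
#'
#' @param sig A `signal_matrix` (raw signals).
#' @param segs A `segment_list` (from [recognize_activities()]) or a
#'   [protocol()] (ground-truth segmentation, for ablation).
#' @param cfg An [rcm_config()].
#' @return A data.frame of class `repetition_report`: one row per
#'   exercise segment with `label`, `start`, `end`, `predicted`, and
#'   `truth` (`NA` unless `segs` carries repetition counts). Segments too
#'   short to filter are skipped.
#' @export
count_protocol <- function(sig, segs, cfg = rcm_config()) {
  ex <- segs[segs$label != "break", , drop = FALSE]
  if (nrow(ex) == 0L) {
    out <- data.frame(label = character(0), start = integer(0),
                      end = integer(0), predicted = integer(0),
                      truth = integer(0))
    class(out) <- c("repetition_report", "data.frame")
    return(out)
  }
  pred <- integer(nrow(ex))
  keep <- logical(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    if (ex$end[i] - ex$start[i] <= 3L * cfg$order) next
    pred[i] <- count_repetitions(sig, ex[i, ], cfg)
    keep[i] <- TRUE
  }
  out <- data.frame(label = ex$label[keep], start = ex$start[keep],
                    end = ex$end[keep], predicted = pred[keep],
                    truth = if ("repetitions" %in% names(ex)) {
                      ex$repetitions[keep]
                    } else NA_integer_)
  class(out) <- c("repetition_report", "data.frame")
  out
}
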