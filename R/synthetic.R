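#' Scenario inventory of the study protocol corpus
#'
#' The 15 scenarios (ordered sequences of exercises) used in the study,
#' with the number of recorded protocols per scenario (78 in total). The
#' generator samples scenarios proportional to these counts by default.
#'
#' @return A data.frame with columns `scenario` (list column of character
#'   vectors) and `weight` (protocol counts).
#' @export
#' @examples
#' sum(scenario_table()$weight)  # 78
scenario_table <- function() {
  scen <- list(
    "dip",
    "pullup",
    "squat",
    c("dip", "squat"),
    c("pullup", "squat"),
    c("squat", "dip"),
    c("squat", "squat"),
    c("dip", "pullup", "squat"),
    c("dip", "squat", "pullup"),
    c("pullup", "dip", "squat"),
    c("pullup", "squat", "dip"),
    c("squat", "dip", "pullup"),
    c("squat", "pullup", "dip"),
    c("squat", "squat", "squat"),
    c("pullup", "dip", "squat", "squat")
  )
  weight <- c(1, 2, 7, 3, 1, 1, 5, 5, 4, 28, 1, 4, 2, 13, 1)
  out <- data.frame(weight = weight)
  out$scenario <- scen
  out[c("scenario", "weight")]
}

#' Per-activity duration and count statistics of the study corpus
#'
#' Occurrence-duration bounds (one contiguous series of a single
#' activity), repetition-count bounds and single-repetition duration
#' bounds, all in samples at 30 Hz. The post-processing thresholds and
#' repetition-counter distances are tuned against these statistics, so
#' the generator enforces them.
#'
#' @return A data.frame keyed by activity.
#' @export
activity_stats_table <- function() {
  data.frame(
    activity = c("dip", "pullup", "squat"),
    reps_min = c(2L, 1L, 2L),
    reps_max = c(12L, 14L, 15L),
    rep_dur_min = c(48L, 55L, 33L),
    rep_dur_max = c(171L, 220L, 130L),
    occ_dur_min = c(135L, 91L, 157L),
    occ_dur_max = c(768L, 765L, 956L),
    row.names = c("dip", "pullup", "squat")
  )
}

#' Occurrence inventory of the study corpus
#'
#' Counts and duration statistics (samples at 30 Hz) of the 488 activity
#' occurrences - contiguous single-activity parts, breaks included - that
#' the 78 recorded protocols were split into. The break row's minimum
#' (63 samples) underpins the post-processing gap threshold, and the
#' break duration bounds are the generator's default break range.
#'
#' @return A data.frame with columns `activity`, `n_occurrences`,
#'   `dur_min`, `dur_avg`, `dur_max`.
#' @export
#' @examples
#' sum(occurrence_table()$n_occurrences)  # 488
occurrence_table <- function() {
  data.frame(
    activity = c("break", "dip", "pullup", "squat"),
    n_occurrences = c(283L, 50L, 48L, 107L),
    dur_min = c(63L, 135L, 91L, 157L),
    dur_avg = c(382L, 297L, 249L, 474L),
    dur_max = c(1844L, 768L, 765L, 956L),
    row.names = c("break", "dip", "pullup", "squat")
  )
}

#' Configuration of the synthetic signal generator
#'
#' Defaults reproduce the statistical structure of the study corpus:
#' scenarios drawn with the protocol-count weights of the 15-scenario
#' inventory; repetition counts and single-repetition durations uniform
#' within the per-activity bounds; occurrence durations constrained to
#' the observed per-activity ranges (rejection sampling); break durations
#' uniform within 63-1844 samples (the observed break range - the
#' 63-sample minimum is what the post-processing gap thresholds assume).
#'
#' Signal model: every repetition contributes one half-cosine
#' excursion-and-return bump spanning its duration on the activity's
#' informative channels (amplitude `amp_informative`), and a smaller bump
#' on the remaining channels (`amp_residual`); all channels ride on a
#' per-channel gravity baseline with additive Gaussian noise; breaks are
#' baseline + noise + sparse low-amplitude transients emulating incidental
#' movement.
#'
#' @param rate Sampling rate, Hz.
#' @param scenario_weights Data.frame as [scenario_table()].
#' @param stats Data.frame as [activity_stats_table()].
#' @param break_range Length-2 integer vector, break duration bounds in
#'   samples.
#' @param amp_informative Bump amplitude (m/s^2) on informative channels.
#' @param amp_residual Bump amplitude on the other channels during
#'   exercise.
#' @param amplitude Optional 3 x 6 matrix (activities x channels)
#'   overriding the per-(activity, channel) bump amplitudes.
#' @param baseline Length-6 numeric, per-channel static offset (m/s^2);
#'   default puts gravity (9.81) on both z channels.
#' @param noise_sd Gaussian noise standard deviation (m/s^2).
#' @param transient_rate Expected break transients per second.
#' @param transient_amp Peak amplitude of break transients (m/s^2).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(rate = 30,
                             scenario_weights = scenario_table(),
                             stats = activity_stats_table(),
                             break_range = c(63L, 1844L),
                             amp_informative = 3.0,
                             amp_residual = 1.0,
                             amplitude = NULL,
                             baseline = c(0, 0, 9.81, 0, 0, 9.81),
                             noise_sd = 0.3,
                             transient_rate = 0.05,
                             transient_amp = 1.0) {
  stopifnot(rate > 0, noise_sd >= 0, transient_rate >= 0,
            length(break_range) == 2L, break_range[1] <= break_range[2],
            break_range[1] >= 1L,
            all(stats$reps_min <= stats$reps_max),
            all(stats$rep_dur_min <= stats$rep_dur_max),
            all(scenario_weights$weight >= 0),
            sum(scenario_weights$weight) > 0,
            length(baseline) == 6L)
  if (is.null(amplitude)) {
    amplitude <- matrix(amp_residual, nrow = 3, ncol = 6,
                        dimnames = list(exercise_levels(), canonical_channels()))
    for (a in exercise_levels()) {
      amplitude[a, informative_channels(a)] <- amp_informative
    }
  } else {
    stopifnot(is.matrix(amplitude), nrow(amplitude) == 3L, ncol(amplitude) == 6L)
    dimnames(amplitude) <- list(exercise_levels(), canonical_channels())
  }
  structure(list(rate = rate, scenario_weights = scenario_weights,
                 stats = stats, break_range = as.integer(break_range),
                 amplitude = amplitude, baseline = baseline,
                 noise_sd = noise_sd, transient_rate = transient_rate,
                 transient_amp = transient_amp),
            class = "generator_config")
}

# Draw (repetition count, per-repetition durations) for one occurrence of
# `activity`, rejecting draws whose total duration falls outside the
# observed occurrence-duration range.
sample_occurrence <- function(activity, cfg) {
  s <- cfg$stats[activity, ]
  for (i in seq_len(10000L)) {
    count <- sample(s$reps_min:s$reps_max, 1L)
    durs <- sample(s$rep_dur_min:s$rep_dur_max, count, replace = TRUE)
    if (sum(durs) >= s$occ_dur_min && sum(durs) <= s$occ_dur_max) {
      return(list(count = count, durations = durs))
    }
  }
  stop("occurrence-duration constraints unsatisfiable for ", activity)
}

#' Sample a protocol specification
#'
#' Draws one protocol plan from the generator distribution: a scenario
#' (proportional to the configured weights), per-occurrence repetition
#' counts and durations, and break durations bracketing every activity
#' (leading break, one between each pair of activities, trailing break).
#' Uses the R random stream; call `set.seed()` first for reproducibility.
#'
#' @param cfg A [generator_config()].
#' @return A list of class `protocol_spec` with elements `scenario`
#'   (character vector), `occurrences` (list of `list(count, durations)`),
#'   `breaks` (integer vector, length `length(scenario) + 1`).
#' @export
sample_protocol <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  w <- cfg$scenario_weights
  k <- sample.int(nrow(w), 1L, prob = w$weight)
  scenario <- w$scenario[[k]]
  occurrences <- lapply(scenario, sample_occurrence, cfg = cfg)
  breaks <- sample(cfg$break_range[1]:cfg$break_range[2],
                   length(scenario) + 1L, replace = TRUE)
  structure(list(scenario = scenario, occurrences = occurrences,
                 breaks = as.integer(breaks)),
            class = "protocol_spec")
}

# One repetition: half-cosine excursion and return over `d` samples,
# normalized to peak 1 (single interior extremum).
rep_bump <- function(d) {
  (1 - cos(2 * pi * (seq_len(d) - 0.5) / d)) / 2
}

#' Synthesize the signal for a protocol specification
#'
#' Renders a `protocol_spec` into a six-channel 30 Hz acceleration signal
#' plus its exact ground-truth annotation. See [generator_config()] for
#' the signal model.
#'
#' @param spec A `protocol_spec` from [sample_protocol()].
#' @param cfg The matching [generator_config()].
#' @return A list with elements `signal` (a `signal_matrix`) and
#'   `protocol` (a [protocol()] tiling it).
#' @export
synthesize_protocol <- function(spec, cfg = generator_config()) {
  stopifnot(inherits(spec, "protocol_spec"))
  n_act <- length(spec$scenario)
  seg_label <- character(0); seg_len <- integer(0); seg_reps <- integer(0)
  for (i in seq_len(n_act)) {
    seg_label <- c(seg_label, "break", spec$scenario[i])
    seg_len <- c(seg_len, spec$breaks[i], sum(spec$occurrences[[i]]$durations))
    seg_reps <- c(seg_reps, NA_integer_, spec$occurrences[[i]]$count)
  }
  seg_label <- c(seg_label, "break")
  seg_len <- c(seg_len, spec$breaks[n_act + 1L])
  seg_reps <- c(seg_reps, NA_integer_)
  ends <- cumsum(seg_len)
  starts <- c(0L, ends[-length(ends)])
  N <- ends[length(ends)]

  mat <- matrix(rep(cfg$baseline, each = N), nrow = N)
  colnames(mat) <- canonical_channels()

  act_idx <- which(seg_label != "break")
  for (j in seq_along(act_idx)) {
    si <- act_idx[j]
    a <- seg_label[si]
    durs <- spec$occurrences[[j]]$durations
    wave <- unlist(lapply(durs, rep_bump))
    rows <- (starts[si] + 1L):ends[si]
    amps <- cfg$amplitude[a, ]
    mat[rows, ] <- mat[rows, ] + outer(wave, amps)
  }

  # sparse low-amplitude transients during breaks
  if (cfg$transient_rate > 0 && cfg$transient_amp > 0) {
    for (si in which(seg_label == "break")) {
      len <- seg_len[si]
      n_ev <- stats::rpois(1L, cfg$transient_rate * len / cfg$rate)
      for (e in seq_len(n_ev)) {
        d <- sample(5:15, 1L)
        if (d >= len) next
        at <- sample.int(len - d, 1L)
        ch <- sample.int(6L, 1L)
        amp <- stats::runif(1L, 0, cfg$transient_amp)
        rows <- starts[si] + at + seq_len(d)
        mat[rows, ch] <- mat[rows, ch] + amp * rep_bump(d)
      }
    }
  }

  if (cfg$noise_sd > 0) {
    mat <- mat + matrix(stats::rnorm(N * 6L, sd = cfg$noise_sd), nrow = N)
  }

  list(signal = signal_matrix(mat, rate = cfg$rate),
       protocol = protocol(seg_label, starts, ends, seg_reps))
}

#' Generate a reproducible synthetic corpus
#'
#' @param cfg A [generator_config()].
#' @param n_protocols Number of independent protocols to draw.
#' @param seed Integer seed; the corpus is fully determined by
#'   `(cfg, n_protocols, seed)`.
#' @return A list of `n_protocols` elements, each
#'   `list(signal, protocol, spec)`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(), n_protocols = 2, seed = 7)
#' length(ds)
generate_dataset <- function(cfg = generator_config(), n_protocols, seed) {
  stopifnot(n_protocols >= 1L)
  set.seed(seed)
  lapply(seq_len(n_protocols), function(i) {
    spec <- sample_protocol(cfg)
    out <- synthesize_protocol(spec, cfg)
    out$spec <- spec
    out
  })
}
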