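#' Slice a recording into labeled windows
#'
#' Applies the sliding-window method: 2-D windows of `size` successive
#' samples across all 6 channels, taken at starts `0, step, 2*step, ...`
#' (0-based) with `start + size <= N`. Three regimes are used downstream:
#' non-overlapping training windows (`step = size`), half-overlapping
#' training windows (`step = size / 2`) and streaming inference
#' (`step = 1`). Each window carries a soft label: the fraction of its
#' samples belonging to each activity class.
#'
#' @param sig A `signal_matrix` with the 6 canonical channels.
#' @param truth A [protocol()] tiling `sig` (used for labels); may be
#'   `NULL` for unlabeled slicing.
#' @param size Window length in samples (default 50).
#' @param step Start-to-start stride in samples.
#' @return A list of class `windowed_dataset`: `windows` (K x size x 6
#'   array), `labels` (K x 4 soft-label matrix), `starts` (0-based),
#'   `size`, `regime` (`"nonoverlap"`, `"overlap"` or `"stream"`),
#'   `normalization` (`"raw"`), `channel_stats` (`NULL` until z-scored).
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(), 1, seed = 1)[[1]]
#' wd <- slice_windows(ds$signal, ds$protocol, step = 25)
#' dim(wd$windows)
slice_windows <- function(sig, truth = NULL, size = 50L, step = size) {
  stopifnot(inherits(sig, "signal_matrix"), step >= 1L)
  N <- n_samples(sig)
  if (N < size) stop("signal shorter (", N, ") than window size (", size, ")")
  starts <- seq.int(0L, N - size, by = step)
  K <- length(starts)
  windows <- array(0, dim = c(K, size, ncol(sig$samples)))
  for (k in seq_len(K)) {
    windows[k, , ] <- sig$samples[(starts[k] + 1L):(starts[k] + size), ]
  }
  labels <- NULL
  if (!is.null(truth)) {
    lab <- protocol_sample_labels(truth)
    if (length(lab) != N) stop("protocol does not tile the signal")
    code <- match(lab, activity_levels())
    labels <- t(vapply(starts, function(s) {
      tabulate(code[(s + 1L):(s + size)], nbins = 4L) / size
    }, numeric(4)))
    colnames(labels) <- activity_levels()
  }
  regime <- if (step == size) "nonoverlap" else if (step * 2L == size) "overlap"
            else if (step == 1L) "stream" else "custom"
  structure(list(windows = windows, labels = labels, starts = starts,
                 size = size, regime = regime, normalization = "raw",
                 channel_stats = NULL),
            class = "windowed_dataset")
}

#' Soft label of a run of sample labels
#'
#' The desired classifier response for a window: the per-class fraction of
#' its samples, so homogeneous windows get a one-hot vector and windows
#' spanning an activity boundary get fractional targets.
#'
#' @param sample_labels Character vector of per-sample activity labels.
#' @return Numeric 4-vector over [activity_levels()] order, summing to 1.
#' @export
#' @examples
#' soft_label(rep(c("break", "squat"), c(20, 30)))  # 0.4, 0, 0, 0.6
soft_label <- function(sample_labels) {
  code <- match(sample_labels, activity_levels())
  if (anyNA(code)) stop("unknown activity label")
  out <- tabulate(code, nbins = 4L) / length(sample_labels)
  names(out) <- activity_levels()
  out
}

#' Hard label of a soft label
#'
#' Collapses a soft label to a single class. Because breaks separate all
#' activities and the shortest break exceeds the window length, a
#' heterogeneous window can only mix one exercise with break; such windows
#' are treated as the exercise: registered non-break mass wins over break,
#' even a break majority. "Registered" means at least `min_mass` - one
#' sample's worth (1/50) by default, so for composition-derived soft
#' labels any activity sample in the window decides the label, while for
#' probabilistic classifier outputs sub-sample leakage mass does not flip
#' a confident break. Ties between exercises break by class-index order.
#'
#' @param sl Numeric 4-vector (soft label) or a K x 4 matrix of them.
#' @param min_mass Minimum class mass that counts as presence.
#' @return Character label(s).
#' @export
#' @examples
#' hard_label(c(0.6, 0.4, 0, 0))  # "dip"
hard_label <- function(sl, min_mass = 1 / 50) {
  if (is.matrix(sl)) {
    ex <- sl[, 2:4, drop = FALSE]
    out <- rep("break", nrow(sl))
    present <- ex >= min_mass
    any_ex <- rowSums(present) > 0
    out[any_ex] <- exercise_levels()[max.col(ex[any_ex, , drop = FALSE],
                                             ties.method = "first")]
    return(out)
  }
  stopifnot(length(sl) == 4L)
  ex <- sl[2:4]
  if (any(ex >= min_mass)) exercise_levels()[which.max(ex)] else "break"
}

#' Fit per-channel normalization statistics
#'
#' Mean and standard deviation of every channel over all samples of all
#' training windows. Standard deviations are floored at `1e-8` so constant
#' channels stay finite under z-scoring.
#'
#' @param ds A `windowed_dataset` (the training split).
#' @return A data.frame with columns `channel`, `mean`, `sd`.
#' @export
fit_normalizer <- function(ds) {
  stopifnot(inherits(ds, "windowed_dataset"), length(ds$starts) > 0L)
  M <- dim(ds$windows)[3]
  flat <- matrix(ds$windows, ncol = M)
  data.frame(channel = canonical_channels()[seq_len(M)],
             mean = colMeans(flat),
             sd = pmax(apply(flat, 2L, stats::sd), 1e-8))
}

#' Apply z-score normalization to a windowed dataset
#'
#' @param ds A `windowed_dataset`.
#' @param stats Channel statistics from [fit_normalizer()] (fitted on the
#'   training split only, to keep test isolation).
#' @return The dataset with normalized windows, `normalization = "zscore"`
#'   and the statistics attached.
#' @export
apply_normalizer <- function(ds, stats) {
  stopifnot(inherits(ds, "windowed_dataset"))
  for (m in seq_len(dim(ds$windows)[3])) {
    ds$windows[, , m] <- (ds$windows[, , m] - stats$mean[m]) / stats$sd[m]
  }
  ds$normalization <- "zscore"
  ds$channel_stats <- stats
  ds
}

# Subset a windowed_dataset by window index.
subset_windows <- function(ds, idx) {
  structure(list(windows = ds$windows[idx, , , drop = FALSE],
                 labels = if (!is.null(ds$labels)) ds$labels[idx, , drop = FALSE],
                 starts = ds$starts[idx], size = ds$size, regime = ds$regime,
                 normalization = ds$normalization,
                 channel_stats = ds$channel_stats),
            class = "windowed_dataset")
}

#' Combine windowed datasets
#'
#' Concatenates windows (and labels) from several recordings sliced under
#' the same regime.
#'
#' @param dss List of `windowed_dataset` objects.
#' @return One `windowed_dataset`.
#' @export
combine_windows <- function(dss) {
  stopifnot(length(dss) >= 1L)
  windows <- abind_first(lapply(dss, `[[`, "windows"))
  labels <- if (!is.null(dss[[1]]$labels)) {
    do.call(rbind, lapply(dss, `[[`, "labels"))
  }
  structure(list(windows = windows, labels = labels,
                 starts = unlist(lapply(dss, `[[`, "starts")),
                 size = dss[[1]]$size, regime = dss[[1]]$regime,
                 normalization = dss[[1]]$normalization,
                 channel_stats = dss[[1]]$channel_stats),
            class = "windowed_dataset")
}

# rbind for 3-d arrays along the first dimension
abind_first <- function(arrs) {
  ns <- vapply(arrs, function(a) dim(a)[1], integer(1))
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(sum(ns), d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Split a windowed dataset into train / validation / test
#'
#' Uniform random partition at window level with the study's 70:15:15
#' default. Sizes are `floor` of the first two ratios with the remainder
#' in the test split, so the three parts always exhaust the dataset.
#'
#' @param ds A `windowed_dataset`.
#' @param ratios Numeric length-3, summing to 1.
#' @param seed Integer seed for the partition.
#' @return A list with `train`, `val`, `test` (each a `windowed_dataset`).
#' @export
split_dataset <- function(ds, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(inherits(ds, "windowed_dataset"),
            length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-9)
  K <- length(ds$starts)
  if (K < 3L) stop("dataset too small to split three ways")
  set.seed(seed)
  perm <- sample.int(K)
  n_train <- floor(ratios[1] * K)
  n_val <- floor(ratios[2] * K)
  list(train = subset_windows(ds, perm[seq_len(n_train)]),
       val = subset_windows(ds, perm[n_train + seq_len(n_val)]),
       test = subset_windows(ds, perm[(n_train + n_val + 1L):K]))
}
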