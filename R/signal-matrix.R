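#' Multichannel signal matrix
#'
#' Container for a uniformly sampled multichannel accelerometer recording:
#' an N x M numeric matrix (rows = samples in time order, columns =
#' channels, units m/s^2) plus the sampling rate and the ordered channel
#' names. Row `i` corresponds to time `(i - 1) / rate` seconds.
#'
#' @param samples Numeric matrix, N rows x M columns, no missing values.
#' @param rate Sampling rate in Hz (default 30).
#' @param channels Character vector of channel identifiers, length M.
#' @return An object of class `signal_matrix`.
#' @export
#' @examples
#' sig <- signal_matrix(matrix(rnorm(60), 10, 6))
#' dim(sig)
signal_matrix <- function(samples, rate = 30, channels = canonical_channels()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L) stop("signal_matrix needs at least one sample row")
  if (length(channels) < 1L) stop("signal_matrix needs at least one channel")
  if (ncol(samples) != length(channels)) {
    stop("number of columns (", ncol(samples), ") does not match number of channels (",
         length(channels), ")")
  }
  if (anyNA(samples)) stop("signal_matrix must not contain missing values")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  colnames(samples) <- channels
  structure(list(samples = samples, rate = as.numeric(rate), channels = channels),
            class = "signal_matrix")
}

#' @export
dim.signal_matrix <- function(x) dim(x$samples)

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, nrow(x$samples) / x$rate))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a signal matrix
#' @param sig A `signal_matrix`.
#' @return Integer number of rows.
#' @export
n_samples <- function(sig) nrow(sig$samples)

#' Select and reorder channels
#'
#' @param sig A `signal_matrix`.
#' @param wanted Character vector of channel identifiers to keep, in the
#'   desired output order. Must be a subset of `sig$channels`.
#' @return A `signal_matrix` with the requested columns, same N and rate.
#' @export
#' @examples
#' sig <- signal_matrix(matrix(rnorm(60), 10, 6))
#' select_channels(sig, informative_channels("dip"))
select_channels <- function(sig, wanted) {
  stopifnot(inherits(sig, "signal_matrix"))
  missing <- setdiff(wanted, sig$channels)
  if (length(missing) > 0L) {
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(wanted, sig$channels)
  signal_matrix(sig$samples[, idx, drop = FALSE], rate = sig$rate, channels = wanted)
}

#' Resample timestamped samples onto a uniform grid
#'
#' Places possibly irregular timestamped observations (e.g. a stream with
#' transmission dropouts) on a uniform grid at `target_rate` by linear
#' interpolation, the same correction the acquisition chain applies when
#' the transmission rate falls below the nominal 30 Hz. The grid spans the
#' observed support only: it starts at the first timestamp and ends at or
#' before the last; no extrapolation is performed.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param values Numeric vector or matrix of observations (rows matched to
#'   `t`).
#' @param target_rate Target sampling rate in Hz (default 30).
#' @param channels Channel names for the output (defaults to the input
#'   column names, or canonical names if absent).
#' @return A `signal_matrix` on the uniform grid. Output rows number
#'   `floor((t[n] - t[1]) * target_rate) + 1`.
#' @export
#' @examples
#' resample_to_rate(c(0, 2/30), c(0, 2))  # dropout at 1/30 s -> value 1
resample_to_rate <- function(t, values, target_rate = 30, channels = NULL) {
  values <- as.matrix(values)
  if (length(t) < 2L) stop("resampling needs at least 2 timestamped samples")
  if (length(t) != nrow(values)) stop("length(t) must match nrow(values)")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- canonical_channels()[seq_len(ncol(values))]
  }
  n_out <- floor((t[length(t)] - t[1]) * target_rate) + 1L
  grid <- t[1] + (seq_len(n_out) - 1L) / target_rate
  out <- apply(values, 2L, function(v) stats::approx(t, v, xout = grid)$y)
  out <- matrix(out, nrow = n_out)
  signal_matrix(out, rate = target_rate, channels = channels)
}

#' Synchronize several sensor streams onto a common grid
#'
#' Temporally aligns per-sensor timestamped streams: each stream is
#' linearly resampled at `target_rate` over the intersection of all time
#' supports, then the streams are column-bound and reordered to canonical
#' channel order (any channels outside the canonical set keep their given
#' order after the canonical ones).
#'
#' @param streams List of streams; each is a list (or data.frame) with
#'   `t` (seconds) and named signal columns / a `values` matrix with
#'   column names.
#' @param target_rate Target rate in Hz (default 30).
#' @return A `signal_matrix` covering the common support.
#' @export
synchronize_streams <- function(streams, target_rate = 30) {
  if (length(streams) < 1L) stop("need at least one stream")
  parts <- lapply(streams, function(s) {
    if (is.data.frame(s)) {
      t <- s$t
      v <- as.matrix(s[setdiff(names(s), "t")])
    } else {
      t <- s$t
      v <- as.matrix(s$values)
    }
    list(t = t, values = v)
  })
  start <- max(vapply(parts, function(p) p$t[1], numeric(1)))
  end <- min(vapply(parts, function(p) p$t[length(p$t)], numeric(1)))
  if (end <= start) stop("streams have no overlapping time support")
  n_out <- floor((end - start) * target_rate) + 1L
  grid <- start + (seq_len(n_out) - 1L) / target_rate
  cols <- lapply(parts, function(p) {
    out <- apply(p$values, 2L, function(v) stats::approx(p$t, v, xout = grid)$y)
    out <- matrix(out, nrow = n_out)
    colnames(out) <- colnames(p$values)
    out
  })
  mat <- do.call(cbind, cols)
  canon <- intersect(canonical_channels(), colnames(mat))
  ord <- c(canon, setdiff(colnames(mat), canon))
  signal_matrix(mat[, ord, drop = FALSE], rate = target_rate, channels = ord)
}
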