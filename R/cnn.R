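#' Configuration of the window classifier
#'
#' The compact convolutional architecture used for activity recognition:
#' one convolution layer (5 filters, 7 x 1 kernel sliding along time only,
#' ReLU, no padding), 2 x 1 max pooling along time, flatten, and a dense
#' softmax output over the 4 activity classes. With 50 x 6 input windows
#' the layer shapes are conv (44, 6, 5), pool (22, 6, 5), flatten 660,
#' dense 4, for 5*(7+1) + 4*(660+1) = 2684 trainable parameters.
#'
#' Training hyperparameters (optimizer, learning rate, batch size,
#' early-stopping patience) are part of the configuration; the loss is
#' categorical cross-entropy against soft targets.
#'
#' @param input_size Window length in samples (default 50).
#' @param n_channels Number of input channels (default 6).
#' @param n_filters Convolution filters (default 5).
#' @param kernel Kernel length along time (default 7).
#' @param pool Pooling factor along time (default 2).
#' @param n_classes Output classes (default 4).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_size = 50L, n_channels = 6L, n_filters = 5L,
                         kernel = 7L, pool = 2L, n_classes = 4L,
                         lr = 1e-3, batch_size = 128L, max_epochs = 200L,
                         patience = 10L, seed = 1L) {
  conv_len <- input_size - kernel + 1L
  if (conv_len < 1L) stop("kernel does not fit the input window")
  if (conv_len %% pool != 0L) stop("pooling must divide the conv output length")
  structure(list(input_size = as.integer(input_size),
                 n_channels = as.integer(n_channels),
                 n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 n_classes = as.integer(n_classes),
                 conv_len = conv_len, pool_len = conv_len %/% pool,
                 flat = conv_len %/% pool * n_channels * n_filters,
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) window classifier
#'
#' Initializes weights with Glorot-uniform draws (seeded from the config).
#' The parameter-count identity `n_filters*(kernel+1) +
#' n_classes*(flat+1)` is asserted at build time.
#'
#' @param cfg A [model_config()].
#' @return A list of class `cnn_model` holding the weight tensors, the
#'   config, an (empty) training history and a normalization tag.
#' @export
#' @examples
#' m <- build_model(model_config())
#' n_parameters(m)  # 2684
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(cfg$seed)
  lim_c <- sqrt(6 / (cfg$kernel + cfg$kernel * cfg$n_filters))
  lim_d <- sqrt(6 / (cfg$flat + cfg$n_classes))
  m <- structure(list(
    W_conv = matrix(stats::runif(cfg$kernel * cfg$n_filters, -lim_c, lim_c),
                    cfg$kernel, cfg$n_filters),
    b_conv = numeric(cfg$n_filters),
    W_dense = matrix(stats::runif(cfg$flat * cfg$n_classes, -lim_d, lim_d),
                     cfg$flat, cfg$n_classes),
    b_dense = numeric(cfg$n_classes),
    cfg = cfg, history = NULL, normalization = "raw", channel_stats = NULL),
    class = "cnn_model")
  stopifnot(n_parameters(m) ==
              cfg$n_filters * (cfg$kernel + 1L) + cfg$n_classes * (cfg$flat + 1L))
  m
}

#' Trainable parameter count
#' @param model A `cnn_model`.
#' @return Integer.
#' @export
n_parameters <- function(model) {
  length(model$W_conv) + length(model$b_conv) +
    length(model$W_dense) + length(model$b_dense)
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<cnn_model> conv(%d,%d,%d) -> pool(%d,%d,%d) -> flatten(%d) -> dense(%d)\n",
              cfg$conv_len, cfg$n_channels, cfg$n_filters,
              cfg$pool_len, cfg$n_channels, cfg$n_filters,
              cfg$flat, cfg$n_classes))
  cat(sprintf("parameters: %d | normalization: %s | trained epochs: %d\n",
              n_parameters(x), x$normalization,
              if (is.null(x$history)) 0L else nrow(x$history)))
  invisible(x)
}

# im2col row-index machinery for a batch of K windows.
# Row order of the column matrix: window k fastest, then time position j,
# then channel c; column kk holds input sample j + kk - 1.
conv_indices <- function(K, cfg) {
  J <- cfg$conv_len
  base <- rep(seq_len(K), times = J * cfg$n_channels) +
    K * rep(rep(seq_len(J) - 1L, each = K), times = cfg$n_channels) +
    K * cfg$input_size * rep(seq_len(cfg$n_channels) - 1L, each = K * J)
  P <- cfg$pool_len
  r_of <- function(j) {
    rep(seq_len(K), times = P * cfg$n_channels) +
      K * rep(rep(j - 1L, each = K), times = cfg$n_channels) +
      K * J * rep(seq_len(cfg$n_channels) - 1L, each = K * P)
  }
  list(base = base,
       odd = r_of(2L * seq_len(P) - 1L),
       even = r_of(2L * seq_len(P)))
}

# Forward pass over a K x size x channels array. Returns intermediates
# needed for backprop when `keep = TRUE`.
cnn_forward <- function(model, X, idx = NULL, keep = FALSE) {
  cfg <- model$cfg
  K <- dim(X)[1]
  if (is.null(idx)) idx <- conv_indices(K, cfg)
  Xv <- as.vector(X)
  A <- matrix(0, K * cfg$conv_len * cfg$n_channels, cfg$kernel)
  for (kk in seq_len(cfg$kernel)) {
    A[, kk] <- Xv[idx$base + K * (kk - 1L)]
  }
  Z <- A %*% model$W_conv
  Z <- sweep(Z, 2L, model$b_conv, "+")
  Z[Z < 0] <- 0
  Po <- Z[idx$odd, , drop = FALSE]
  Pe <- Z[idx$even, , drop = FALSE]
  P <- pmax(Po, Pe)
  Fm <- matrix(as.vector(P), nrow = K)
  logits <- sweep(Fm %*% model$W_dense, 2L, model$b_dense, "+")
  probs <- softmax_rows(logits)
  if (keep) list(probs = probs, A = A, Z = Z, Po = Po, Pe = Pe, Fm = Fm, idx = idx)
  else probs
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

cross_entropy <- function(probs, targets) {
  -mean(rowSums(targets * log(pmax(probs, 1e-12))))
}

#' Predict class probabilities for windows
#'
#' @param model A trained `cnn_model`.
#' @param X A K x size x channels array of windows, or a `windowed_dataset`.
#' @return K x 4 matrix of class probabilities (rows sum to 1).
#' @export
predict_batch <- function(model, X) {
  if (inherits(X, "windowed_dataset")) X <- X$windows
  stopifnot(length(dim(X)) == 3L,
            dim(X)[2] == model$cfg$input_size,
            dim(X)[3] == model$cfg$n_channels)
  probs <- cnn_forward(model, X)
  colnames(probs) <- activity_levels()
  probs
}

#' @rdname predict_batch
#' @param w A single size x channels window matrix.
#' @return `predict_window` returns a soft-label 4-vector.
#' @export
predict_window <- function(model, w) {
  w <- as.matrix(w)
  stopifnot(nrow(w) == model$cfg$input_size, ncol(w) == model$cfg$n_channels)
  predict_batch(model, array(w, dim = c(1L, dim(w))))[1L, ]
}

#' Train the window classifier
#'
#' Minimizes categorical cross-entropy against soft targets with Adam on
#' shuffled minibatches. After every epoch the validation loss is
#' evaluated; training stops once it has failed to improve for
#' `cfg$patience` consecutive epochs (or at `cfg$max_epochs`), and the
#' weights of the best-validation epoch are restored.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param train_set,val_set `windowed_dataset`s with soft labels, in the
#'   same normalization mode.
#' @param verbose Print per-epoch progress.
#' @return The trained `cnn_model` with a `history` data.frame
#'   (epoch, train_loss, val_loss, val_accuracy).
#' @export
train_model <- function(model, train_set, val_set, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"),
            inherits(train_set, "windowed_dataset"),
            inherits(val_set, "windowed_dataset"),
            !is.null(train_set$labels), !is.null(val_set$labels),
            train_set$normalization == val_set$normalization)
  cfg <- model$cfg
  model$normalization <- train_set$normalization
  model$channel_stats <- train_set$channel_stats
  K <- dim(train_set$windows)[1]
  B <- min(cfg$batch_size, K)
  idx_full <- conv_indices(B, cfg)
  val_hard <- hard_label(val_set$labels)

  adam <- list(t = 0)
  for (nm in c("W_conv", "b_conv", "W_dense", "b_dense")) {
    adam[[paste0("m_", nm)]] <- model[[nm]] * 0
    adam[[paste0("v_", nm)]] <- model[[nm]] * 0
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  set.seed(cfg$seed + 1L)
  best <- list(loss = Inf, weights = NULL, epoch = 0L)
  hist <- NULL
  wait <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(K)
    n_batch <- K %/% B
    tr_loss <- 0
    for (bi in seq_len(n_batch)) {
      rows <- perm[(bi - 1L) * B + seq_len(B)]
      Xb <- train_set$windows[rows, , , drop = FALSE]
      Tb <- train_set$labels[rows, , drop = FALSE]
      fw <- cnn_forward(model, Xb, idx = idx_full, keep = TRUE)
      tr_loss <- tr_loss + cross_entropy(fw$probs, Tb)

      dlogit <- (fw$probs - Tb) / B
      g <- list(W_dense = crossprod(fw$Fm, dlogit),
                b_dense = colSums(dlogit))
      dF <- tcrossprod(dlogit, model$W_dense)
      dP <- matrix(as.vector(dF), ncol = cfg$n_filters)
      m1 <- fw$Po >= fw$Pe
      dZ <- matrix(0, nrow(fw$Z), cfg$n_filters)
      dZ[fw$idx$odd, ] <- dP * m1
      dZ[fw$idx$even, ] <- dZ[fw$idx$even, ] + dP * !m1
      dZ <- dZ * (fw$Z > 0)
      g$W_conv <- crossprod(fw$A, dZ)
      g$b_conv <- colSums(dZ)

      adam$t <- adam$t + 1
      corr1 <- 1 - b1^adam$t
      corr2 <- 1 - b2^adam$t
      for (nm in names(g)) {
        adam[[paste0("m_", nm)]] <- b1 * adam[[paste0("m_", nm)]] + (1 - b1) * g[[nm]]
        adam[[paste0("v_", nm)]] <- b2 * adam[[paste0("v_", nm)]] + (1 - b2) * g[[nm]]^2
        model[[nm]] <- model[[nm]] - cfg$lr * (adam[[paste0("m_", nm)]] / corr1) /
          (sqrt(adam[[paste0("v_", nm)]] / corr2) + eps)
      }
    }
    tr_loss <- tr_loss / n_batch

    val_probs <- cnn_forward(model, val_set$windows)
    val_loss <- cross_entropy(val_probs, val_set$labels)
    if (!is.finite(val_loss) || !is.finite(tr_loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
    val_acc <- mean(hard_label(val_probs) == val_hard)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss, val_accuracy = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val acc %.3f",
                      epoch, tr_loss, val_loss, val_acc))
    }
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss,
                   weights = model[c("W_conv", "b_conv", "W_dense", "b_dense")],
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (!is.null(best$weights)) model[names(best$weights)] <- best$weights
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Stream per-sample class probabilities over a recording
#'
#' Live-stream emulation: the window slides over the recording with a
#' step of one sample, and every window is classified. The convolution is
#' computed once over the whole signal and shared across windows, so the
#' result is identical to classifying each of the `N - 50 + 1` windows
#' separately but much faster.
#'
#' @param model A trained `cnn_model`.
#' @param sig A `signal_matrix` with at least `input_size` samples (in the
#'   model's normalization mode; use [normalize_signal()] for z-score
#'   models).
#' @return A list of class `probability_stream`: `probs` (T x 4 matrix,
#'   T = N - size + 1, row `t` = prediction of the window starting at
#'   sample t-1, 0-based), `size`, `n_samples`.
#' @export
stream_probabilities <- function(model, sig) {
  stopifnot(inherits(model, "cnn_model"), inherits(sig, "signal_matrix"))
  cfg <- model$cfg
  S <- sig$samples
  N <- nrow(S)
  if (N < cfg$input_size) stop("signal shorter than the model input window")
  nc <- cfg$n_channels
  stopifnot(ncol(S) == nc)
  Lc <- N - cfg$kernel + 1L           # full-signal conv length
  Tn <- N - cfg$input_size + 1L       # number of window positions
  P <- cfg$pool_len
  off <- 2L * (seq_len(P) - 1L)
  idx <- outer(seq_len(Tn), off, "+")  # rows into the pairwise-max series

  Fm <- matrix(0, Tn, cfg$flat)
  for (f in seq_len(cfg$n_filters)) {
    Cf <- matrix(model$b_conv[f], Lc, nc)
    for (kk in seq_len(cfg$kernel)) {
      Cf <- Cf + cfg_w(model, kk, f) * S[kk:(kk + Lc - 1L), , drop = FALSE]
    }
    Cf[Cf < 0] <- 0
    Mf <- pmax(Cf[-Lc, , drop = FALSE], Cf[-1L, , drop = FALSE])
    for (ch in seq_len(nc)) {
      cols <- (f - 1L) * P * nc + (ch - 1L) * P + seq_len(P)
      Fm[, cols] <- matrix(Mf[, ch][idx], Tn, P)
    }
  }
  logits <- sweep(Fm %*% model$W_dense, 2L, model$b_dense, "+")
  probs <- softmax_rows(logits)
  colnames(probs) <- activity_levels()
  structure(list(probs = probs, size = cfg$input_size, n_samples = N),
            class = "probability_stream")
}

cfg_w <- function(model, kk, f) model$W_conv[kk, f]

#' Align a probability stream to samples
#'
#' Causal alignment for live use: the window starting at sample `t`
#' (0-based) covers samples `t ... t+49`, and its prediction is assigned
#' to the most recent covered sample, `t + 49`. The first 49 samples,
#' which no window ends at, take the first window's prediction. The
#' roughly half-window latency this introduces is what produces the small
#' time shifts of recognized segments relative to the protocol.
#'
#' @param ps A `probability_stream`.
#' @return An N x 4 matrix of per-sample class probabilities.
#' @export
sample_probabilities <- function(ps) {
  stopifnot(inherits(ps, "probability_stream"))
  Tn <- nrow(ps$probs)
  rows <- pmax(seq_len(ps$n_samples) - (ps$size - 1L), 1L)
  rows <- pmin(rows, Tn)
  ps$probs[rows, , drop = FALSE]
}

#' Z-score a full recording with a model's training statistics
#'
#' @param sig A `signal_matrix`.
#' @param stats Channel statistics from [fit_normalizer()].
#' @return The normalized `signal_matrix`.
#' @export
normalize_signal <- function(sig, stats) {
  stopifnot(inherits(sig, "signal_matrix"))
  out <- sweep(sig$samples, 2L, stats$mean, "-")
  out <- sweep(out, 2L, stats$sd, "/")
  signal_matrix(out, rate = sig$rate, channels = sig$channels)
}
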