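# Shared fixtures: small configs and independent oracles used across tests.

# Noise-free generator for analytic checks.
clean_config <- function(...) {
  generator_config(noise_sd = 0, transient_rate = 0, ...)
}

# Degenerate generator drawing a single fixed scenario.
one_scenario_config <- function(scenario, ...) {
  sw <- data.frame(weight = 1)
  sw$scenario <- list(scenario)
  generator_config(scenario_weights = sw[c("scenario", "weight")], ...)
}

# Independent extremum enumeration: interior local maxima, with runs of
# equal values (plateaus, e.g. the two-sample crest of an even-length
# cosine bump) condensed to a single candidate first.
oracle_local_maxima <- function(x) {
  r <- rle(x)
  v <- r$values
  n <- length(v)
  is_max <- vapply(seq_len(n), function(i) {
    i > 1 && i < n && v[i] > v[i - 1] && v[i] > v[i + 1]
  }, logical(1))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ((starts + ends) %/% 2L)[is_max]
}

# Brute-force run-length rule: flip runs of `value` with length <= delta.
oracle_flip_short_runs <- function(b, value, delta) {
  n <- length(b)
  out <- b
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && b[j + 1L] == b[i]) j <- j + 1L
    if (b[i] == value && (j - i + 1L) <= delta) out[i:j] <- 1L - value
    i <- j + 1L
  }
  out
}

# Direct per-point evaluation of Eq-style forward moving average.
oracle_moving_average <- function(y, w) {
  n <- length(y)
  vapply(seq_len(n), function(i) mean(y[i:min(i + w - 1L, n)]), numeric(1))
}

# Independent loop implementation of the CNN forward pass for one window.
oracle_forward <- function(model, w) {
  cfg <- model$cfg
  J <- cfg$conv_len; P <- cfg$pool_len; nc <- cfg$n_channels; nf <- cfg$n_filters
  conv <- array(0, dim = c(J, nc, nf))
  for (f in seq_len(nf)) for (c in seq_len(nc)) for (j in seq_len(J)) {
    conv[j, c, f] <- sum(w[j:(j + cfg$kernel - 1L), c] * model$W_conv[, f]) +
      model$b_conv[f]
  }
  conv[conv < 0] <- 0
  flat <- numeric(cfg$flat)
  for (f in seq_len(nf)) for (c in seq_len(nc)) for (p in seq_len(P)) {
    flat[(f - 1L) * P * nc + (c - 1L) * P + p] <-
      max(conv[2L * p - 1L, c, f], conv[2L * p, c, f])
  }
  logits <- drop(flat %*% model$W_dense) + model$b_dense
  e <- exp(logits - max(logits))
  e / sum(e)
}

# A hand-built protocol: break / squat(5 reps x 68) / break, with clean
# bump waveforms, for deterministic micro-tests.
tiny_clean_recording <- function() {
  cfg <- clean_config()
  spec <- structure(list(scenario = "squat",
                         occurrences = list(list(count = 5L,
                                                 durations = rep(68L, 5L))),
                         breaks = c(100L, 120L)),
                    class = "protocol_spec")
  synthesize_protocol(spec, cfg)
}
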