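test_that("recording files round-trip losslessly and restore canonical channel order", {
  set.seed(1)
  sig <- signal_matrix(matrix(round(rnorm(300 * 6, sd = 3), 4), 300, 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(sig, path)
  back <- read_recording(path)
  expect_equal(back$samples, sig$samples)
  expect_equal(back$rate, sig$rate)
  expect_equal(back$channels, canonical_channels())

  # shuffle the channel columns on disk; reading restores canonical order
  df <- read.csv(path)
  perm <- c("t", sample(canonical_channels()))
  write.csv(df[perm], path, row.names = FALSE, quote = FALSE)
  shuffled <- read_recording(path)
  expect_equal(shuffled$samples, sig$samples)

  # single-row recordings are legal
  one <- signal_matrix(matrix(1:6, 1, 6))
  write_recording(one, path)
  expect_equal(nrow(read_recording(path)$samples), 1L)
})

test_that("malformed recordings and matrices are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t = 0:2, chest_ax = 1:3), path, row.names = FALSE)
  expect_error(read_recording(path), "required channel")
  df <- data.frame(t = c(0, 2, 1), matrix(0, 3, 6))
  names(df) <- c("t", canonical_channels())
  write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "monotone")
  expect_error(signal_matrix(matrix(0, 0, 6)), "at least one sample")
  expect_error(signal_matrix(matrix(0, 5, 6), channels = "chest_ax"), "channels")
  expect_error(signal_matrix(matrix(NA_real_, 5, 6)), "missing")
})

test_that("linear resampling fills dropouts and is the identity on uniform input", {
  # already uniform at 30 Hz -> unchanged
  t <- (0:99) / 30
  v <- sin(t)
  out <- resample_to_rate(t, v, 30)
  expect_equal(out$samples[, 1], v, tolerance = 1e-12)

  # one dropout between two points of a line -> exact midpoint
  out <- resample_to_rate(c(0, 2 / 30), c(0, 2), 30)
  expect_equal(out$samples[, 1], c(0, 1, 2))

  # random dropout pattern equals a per-point piecewise-linear oracle
  set.seed(42)
  keep <- sort(sample(2:99, 60))
  t_obs <- c(0, keep, 100) / 30
  v_obs <- cos(t_obs * 2)
  out <- resample_to_rate(t_obs, v_obs, 30)
  grid <- (0:100) / 30
  oracle <- vapply(grid, function(g) {
    i <- max(which(t_obs <= g + 1e-12))
    if (i == length(t_obs)) return(v_obs[i])
    v_obs[i] + (v_obs[i + 1] - v_obs[i]) * (g - t_obs[i]) / (t_obs[i + 1] - t_obs[i])
  }, numeric(1))
  expect_equal(out$samples[, 1], oracle, tolerance = 1e-10)
  expect_error(resample_to_rate(1, 1), "at least 2")
})

test_that("stream synchronization trims to the common support with the closed-form length", {
  mk <- function(t0, t1, cols) {
    t <- seq(t0, t1, by = 1 / 30)
    v <- matrix(rnorm(length(t) * length(cols)), ncol = length(cols))
    colnames(v) <- cols
    list(t = t, values = v)
  }
  set.seed(7)
  a <- mk(0, 10, canonical_channels("chest"))
  b <- mk(2, 12, canonical_channels("hand"))
  out <- synchronize_streams(list(a, b))
  expect_equal(nrow(out$samples), floor((10 - 2) * 30) + 1)
  expect_equal(out$channels, canonical_channels())

  # three offset streams equal per-stream resample + manual trim
  s1 <- mk(0.00, 5.0, "chest_ax"); s2 <- mk(0.30, 5.5, "chest_ay")
  s3 <- mk(0.15, 4.8, "chest_az")
  out <- synchronize_streams(list(s1, s2, s3))
  start <- max(sapply(list(s1, s2, s3), function(s) s$t[1]))
  end <- min(sapply(list(s1, s2, s3), function(s) max(s$t)))
  grid <- start + (seq_len(floor((end - start) * 30) + 1) - 1) / 30
  for (s in list(s1, s2, s3)) {
    ch <- colnames(s$values)
    expect_equal(out$samples[, ch], approx(s$t, s$values[, 1], xout = grid)$y,
                 tolerance = 1e-10)
  }
  # property: output length matches the support-intersection formula
  for (i in 1:20) {
    t0 <- runif(2, 0, 3); t1 <- t0 + runif(2, 2, 6)
    ss <- list(mk(t0[1], t1[1], "chest_ax"), mk(t0[2], t1[2], "chest_ay"))
    got <- nrow(synchronize_streams(list(ss[[1]], ss[[2]]))$samples)
    tA <- ss[[1]]$t; tB <- ss[[2]]$t
    expect_equal(got,
                 floor((min(max(tA), max(tB)) - max(min(tA), min(tB))) * 30) + 1)
  }
  expect_error(synchronize_streams(list(mk(0, 1, "chest_ax"),
                                        mk(5, 6, "chest_ay"))), "overlapping")
})

test_that("channel selection subsets and reorders columns", {
  set.seed(3)
  sig <- signal_matrix(matrix(rnorm(60), 10, 6))
  expect_equal(select_channels(sig, sig$channels), sig)
  z <- select_channels(sig, "chest_az")
  expect_equal(ncol(z$samples), 1L)
  expect_equal(z$samples[, 1], sig$samples[, 3])
  dip <- select_channels(sig, informative_channels("dip"))
  expect_equal(dip$channels, c("chest_az", "hand_ax", "hand_az"))
  expect_equal(ncol(dip$samples), 3L)
  expect_error(select_channels(sig, "foot_ax"), "unknown channel")
})

test_that("protocols validate their tiling and break-separation invariants", {
  p <- protocol(c("break", "dip", "break"), c(0, 50, 200), c(50, 200, 300),
                c(NA, 4, NA))
  expect_s3_class(p, "protocol")
  expect_equal(protocol_scenario(p), "dip")
  expect_equal(length(protocol_sample_labels(p)), 300)
  expect_error(protocol("dip", 0, 0, 3), "start < end")
  expect_error(protocol(c("break", "dip"), c(0, 60), c(50, 100), c(NA, 3)),
               "tile")
  expect_error(protocol(c("dip", "squat"), c(0, 50), c(50, 100), c(3, 4)),
               "separated by a break")
  expect_error(protocol(c("break", "dip"), c(0, 50), c(50, 100), c(NA, NA)),
               "repetition count")
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(p, path)
  expect_equal(read_annotations(path), p)
})
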