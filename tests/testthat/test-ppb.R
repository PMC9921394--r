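test_that("the forward moving average matches direct evaluation with tail truncation", {
  expect_equal(moving_average(rep(3.5, 40), 7), rep(3.5, 40))
  y <- rnorm(30)
  expect_equal(moving_average(y, 1), y)
  expect_equal(moving_average(c(0, 0, 2, 2), 2), c(0, 1, 2, 2))
  set.seed(33)
  for (i in 1:20) {
    y <- rnorm(sample(5:200, 1))
    w <- sample(1:60, 1)
    sm <- moving_average(y, w)
    expect_equal(sm, oracle_moving_average(y, w), tolerance = 1e-12)
    # bounded by the input range
    expect_gte(min(sm), min(y))
    expect_lte(max(sm), max(y))
  }
})

test_that("binarization thresholds with the >= convention", {
  expect_equal(binarize(rep(1, 5)), rep(1L, 5))
  expect_equal(binarize(c(0.2, 0.5, 0.8)), c(0L, 1L, 1L))
  expect_equal(binarize(c(0, 0.1, 0.9), threshold = 0), rep(1L, 3))
  expect_error(binarize(c(-0.1, 0.5)))
})

test_that("peak elimination and gap filling use strict run-length thresholds", {
  expect_equal(eliminate_peaks(rep(1L, 200), 90), rep(1L, 200))
  expect_equal(eliminate_peaks(c(0, 0, 1, 1, 0), 3), rep(0L, 5))
  expect_equal(eliminate_peaks(rep(c(0L, 1L), 10), 1), rep(0L, 20))
  expect_equal(fill_gaps(rep(0L, 200), 60), rep(0L, 200))
  expect_equal(fill_gaps(c(1, 1, 0, 0, 1, 1), 3), rep(1L, 6))
  # a gap of exactly delta0 + 1 zeros survives (strict inequality)
  g <- c(rep(1L, 10), rep(0L, 5), rep(1L, 10))
  expect_equal(fill_gaps(g, 4), g)
  expect_equal(fill_gaps(c(rep(1L, 10), rep(0L, 4), rep(1L, 10)), 4),
               rep(1L, 24))
})

test_that("run-length stages equal the brute-force oracle and are idempotent", {
  set.seed(44)
  for (i in 1:500) {
    b <- sample(0:1, sample(1:120, 1), replace = TRUE,
                prob = c(runif(1), runif(1)) + 0.1)
    d1 <- sample(1:15, 1); d0 <- sample(1:15, 1)
    ep <- eliminate_peaks(b, d1)
    fg <- fill_gaps(b, d0)
    expect_equal(ep, oracle_flip_short_runs(b, 1L, d1))
    expect_equal(fg, oracle_flip_short_runs(b, 0L, d0))
    expect_equal(eliminate_peaks(ep, d1), ep)
    expect_equal(fill_gaps(fg, d0), fg)
  }
})

test_that("post-processing removes bursts, fills dropouts and respects the minimum run length", {
  cfg <- ppb_config()
  N <- 1200L
  # dip active on [300, 900), with a 30-sample false-positive burst before
  # it and a 40-sample dropout inside it
  p_dip <- rep(0, N)
  p_dip[301:900] <- 1
  p_dip[101:130] <- 1    # burst: 30 < delta1 = 90 -> removed
  p_dip[501:540] <- 0    # dropout: 40 < delta0 = 60 -> filled
  probs <- cbind(1 - p_dip, p_dip, 0, 0)
  out <- postprocess(probs, cfg)
  expect_true(all(out[151:250, "dip"] == 0))   # burst region cleaned
  expect_true(all(out[451:600, "dip"] == 1))   # dropout region filled
  expect_true(all(out[400:800, "dip"] == 1))

  # per-class 1-runs after post-processing always exceed delta1
  set.seed(67)
  for (i in 1:20) {
    pr <- matrix(runif(400 * 4), ncol = 4)
    bs <- postprocess(pr / rowSums(pr), cfg)
    for (cl in 1:4) {
      r <- rle(as.integer(bs[, cl]))
      runs1 <- r$lengths[r$values == 1L]
      if (length(runs1) > 0) expect_true(all(runs1 > cfg$delta1))
    }
  }
})

test_that("segment extraction resolves stream conflicts by longest contiguous activation", {
  N <- 500L
  b <- matrix(0L, N, 4)
  b[101:250, 2] <- 1L   # dip
  b[301:420, 4] <- 1L   # squat
  segs <- streams_to_segments(b)
  expect_equal(segs$label, c("break", "dip", "break", "squat", "break"))
  expect_equal(segs$start, c(0L, 100L, 250L, 300L, 420L))
  expect_equal(segs$end, c(100L, 250L, 300L, 420L, 500L))
  expect_equal(extract_scenario(segs), c("dip", "squat"))

  # nothing active -> one long break
  none <- streams_to_segments(matrix(0L, 100, 4))
  expect_equal(none$label, "break")
  expect_equal(none$end, 100L)
  expect_equal(extract_scenario(none), character(0))

  # 10-sample overlap: dip active 1:100, squat active 91:200; inside the
  # overlap dip has been active longer, after it squat owns the samples
  o <- matrix(0L, 200, 4)
  o[1:100, 2] <- 1L
  o[91:200, 4] <- 1L
  segs <- streams_to_segments(o)
  expect_equal(segs$label, c("dip", "squat"))
  expect_equal(segs$end, c(100L, 200L))

  # repeated-label scenarios survive extraction
  p <- protocol(c("break", "squat", "break", "squat", "break"),
                c(0, 50, 250, 350, 550), c(50, 250, 350, 550, 650),
                c(NA, 5, NA, 6, NA))
  expect_equal(extract_scenario(p), c("squat", "squat"))
})

test_that("clean probability streams recover the ground-truth segmentation within PPB latency", {
  d <- tiny_clean_recording()
  lab <- protocol_sample_labels(d$protocol)
  probs <- outer(lab, activity_levels(), `==`) * 1.0
  out <- postprocess(probs, ppb_config())
  segs <- streams_to_segments(out)
  expect_equal(extract_scenario(segs), protocol_scenario(d$protocol))
  truth_seg <- d$protocol[d$protocol$label == "squat", ]
  got_seg <- segs[segs$label == "squat", ]
  expect_lte(abs(got_seg$start - truth_seg$start), 100)
  expect_lte(abs(got_seg$end - truth_seg$end), 100)
})
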