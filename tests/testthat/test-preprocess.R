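# Percent signal change, DCT high-pass detrending, block averaging.

make_ts <- function(signal, runs = rep(1L, ncol(signal)), units = "raw") {
  timeseries_table(signal, run = runs, units = units)
}

test_that("percent signal change is exact per voxel per run", {
  sig <- rbind(rep(500, 6), c(990, 1010, 990, 1010, 990, 1010))
  ts <- make_ts(sig)
  psc <- percent_signal_change(ts)
  expect_equal(psc$signal[1, ], rep(0, 6))
  expect_equal(psc$signal[2, ], c(-1, 1, -1, 1, -1, 1))
  expect_equal(psc$units, "psc")
  # per-run voxel means vanish, also across runs
  sig2 <- matrix(rexp(200, 1 / 1000) + 500, 4, 50)
  ts2 <- make_ts(sig2, runs = rep(1:2, each = 25))
  psc2 <- percent_signal_change(ts2)
  for (r in 1:2) {
    expect_lt(max(abs(rowMeans(psc2$signal[, psc2$run == r]))), 1e-10)
  }
})

test_that("the units flag refuses double conversion and bad means", {
  ts <- make_ts(matrix(1000, 2, 10))
  psc <- percent_signal_change(ts)
  expect_error(percent_signal_change(psc), "already in percent")
  bad <- make_ts(rbind(rep(1000, 4), c(-1, -2, -3, -4)))
  expect_error(percent_signal_change(bad), "v2")
})

test_that("detrending removes drift but spares faster signal", {
  n <- 220
  tr <- 1.55
  ramp <- matrix(seq(-1, 1, length.out = n), 1)
  out <- highpass_detrend(make_ts(ramp, units = "raw"), 0.005, tr)
  expect_lt(max(abs(out$signal)), 0.01 * 1)
  # a 0.05 Hz sinusoid (10x the cutoff) keeps its amplitude within 5%
  # (amplitude read off by projecting onto the quadrature pair)
  t_sec <- (seq_len(n) - 1) * tr
  sine <- matrix(sin(2 * pi * 0.05 * t_sec), 1)
  kept <- highpass_detrend(make_ts(sine, units = "raw"), 0.005, tr)
  qp <- cbind(sin(2 * pi * 0.05 * t_sec), cos(2 * pi * 0.05 * t_sec))
  ab <- qr.solve(qp, as.numeric(kept$signal))
  expect_lt(abs(sqrt(sum(ab^2)) - 1), 0.05)
  # zero in, zero out
  z <- highpass_detrend(make_ts(matrix(0, 1, n), units = "raw"), 0.005, tr)
  expect_equal(z$signal, matrix(0, 1, n))
  expect_error(highpass_detrend(make_ts(ramp), cutoff_hz = 0), "positive")
})

test_that("design protection keeps block-locked signal intact", {
  s <- small_subject(noise_sd = 0, seed = 42)
  psc <- percent_signal_change(s$ts)
  d <- block_design_matrix(s$sched, s$ts, lag_trs = 3)
  plain <- highpass_detrend(psc, tr_seconds = s$pd$tr_seconds)
  prot <- highpass_detrend(psc, tr_seconds = s$pd$tr_seconds, protect = d)
  # the protected filter must distort the noiseless block signal far less
  dist_plain <- max(abs(plain$signal - psc$signal))
  dist_prot <- max(abs(prot$signal - psc$signal))
  expect_lt(dist_prot, dist_plain / 5)
  # drift retained by protection is blockwise-constant, so per-block
  # averages shift but the fitted free baseline absorbs it; the plain
  # filter instead reshapes block responses.  Check the protected filter
  # leaves block-average responses nearly unchanged on noiseless data.
  br_raw <- block_average(psc, s$sched)
  br_prot <- block_average(prot, s$sched)
  expect_lt(max(abs(br_prot$response - br_raw$response)), 0.02)
})

test_that("block averaging uses the lagged window", {
  # block at TRs [10, 20), lag 3 -> averages TRs 13..22 (zero-based)
  n <- 40
  sig <- matrix(0, 1, n)
  sig[1, 14:23] <- 5  # zero-based 13..22
  ts <- make_ts(sig, units = "raw")
  ts$units <- "psc"  # values already centered for the test
  blocks <- data.frame(block_id = 1L, run_id = 1L, cue_center = 0,
                       cue_width = 18, tr_start = 10L, tr_end = 20L)
  br <- block_average(ts, blocks, lag_trs = 3, n_trs = 10)
  expect_equal(br$response[1, 1], 5)
  expect_equal(br$n_trs_used, 10L)
  # full-window averaging ignores the seed
  br2 <- block_average(ts, blocks, lag_trs = 3, n_trs = 10, seed = 99)
  expect_identical(br$response, br2$response)
  # subsampling is reproducible per seed
  one_a <- block_average(ts, blocks, lag_trs = 3, n_trs = 1, seed = 5)
  one_b <- block_average(ts, blocks, lag_trs = 3, n_trs = 1, seed = 5)
  expect_identical(one_a$response, one_b$response)
  expect_error(block_average(ts, blocks, n_trs = 4), "one of")
  raw <- make_ts(sig, units = "raw")
  expect_error(block_average(raw, blocks), "percent-signal-change")
})

test_that("block averaging is linear and subsampling is unbiased", {
  s <- small_subject(noise_sd = 0, seed = 42)
  psc <- percent_signal_change(s$ts)
  blocks <- s$sched[1:4, ]
  a <- block_average(psc, blocks)
  doubled <- timeseries_table(2 * psc$signal, psc$run, psc$voxel_id,
                              units = "psc")
  b <- block_average(doubled, blocks)
  expect_equal(b$response, 2 * a$response, tolerance = 1e-12)
  # mean of single-TR draws over many seeds converges to the 10-TR mean
  full <- block_average(psc, blocks, n_trs = 10)$response[1, 1]
  draws <- vapply(1:200, function(s_) {
    block_average(psc, blocks, n_trs = 1, seed = s_)$response[1, 1]
  }, numeric(1))
  tr_sd <- stats::sd(psc$signal[1, 14:23])
  expect_lt(abs(mean(draws) - full), 4 * tr_sd / sqrt(200) + 1e-9)
})
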