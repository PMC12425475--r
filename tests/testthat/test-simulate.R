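# The synthetic pRF table and BOLD time-series generator.

test_that("simulated pRF tables respect their invariants", {
  cfg <- paradigm_config()
  prfs <- simulate_prf_table(600, cfg, seed = 1)
  expect_equal(nrow(prfs), 1800L)
  expect_equal(as.vector(table(prfs$roi)), rep(600L, 3))
  expect_true(all(prfs$polar_angle >= 0 & prfs$polar_angle < 360))
  expect_true(all(prfs$prf_size > 0))
  expect_true(all(prfs$prf_r2 >= 0 & prfs$prf_r2 <= 1))
  expect_true(all(prfs$eccentricity >= 0))
  # polar-angle occupancy: no empty 6-deg bin at n = 600 per ROI
  for (roi in c("V1", "V2", "V3")) {
    occ <- table(floor(prfs$polar_angle[prfs$roi == roi] / 6))
    expect_equal(length(occ), 60L)
  }
})

test_that("a clean table survives selection except for annulus overlap", {
  cfg <- paradigm_config()
  prfs <- simulate_prf_table(500, cfg, seed = 2, violation_fraction = 0)
  sel <- select_voxels(prfs, cfg)
  # selection equals an independent recomputation of the four rules
  pass <- prfs$eccentricity >= 0.7 & prfs$eccentricity <= 9.1 &
    prfs$prf_size >= 0.01 & prfs$prf_r2 >= 0.10 &
    prfs$eccentricity + prfs$prf_size >= cfg$annulus_inner &
    prfs$eccentricity - prfs$prf_size <= cfg$annulus_outer
  expect_setequal(sel$voxel_id, prfs$voxel_id[pass])
  # with no injected violations, drops are due to annulus/stimulus reach
  expect_true(all(sel$eccentricity + sel$prf_size >= cfg$annulus_inner &
                    sel$eccentricity - sel$prf_size <= cfg$annulus_outer))
})

test_that("injected violations are caught by the filters", {
  cfg <- paradigm_config()
  prfs <- simulate_prf_table(400, cfg, seed = 3, violation_fraction = 0.1)
  sel <- select_voxels(prfs, cfg)
  expect_true(all(sel$prf_r2 >= 0.10))
  expect_true(all(sel$prf_size >= 0.01))
  expect_true(all(sel$eccentricity >= 0.7 & sel$eccentricity <= 9.1))
  # each rule removed someone
  expect_gt(sum(prfs$prf_r2 < 0.10), 0)
  expect_gt(sum(prfs$prf_size < 0.01), 0)
  expect_gt(sum(prfs$eccentricity < 0.7 | prfs$eccentricity > 9.1), 0)
})

test_that("default truth ties FWHM to cue width through the closed form", {
  sched <- build_cue_schedule(paradigm_config(), n_runs = 1, seed = 4)
  truth <- default_field_truth(sched)
  expect_equal(truth$mu_true, sched$cue_center)
  expect_equal(compute_fwhm(truth$sigma_true[1], truth$beta_true[1]),
               truth$fwhm_true[1])
  # FWHM increases with cue width
  agg <- aggregate(fwhm_true ~ cue_width, truth, unique)
  expect_true(all(diff(agg$fwhm_true[order(agg$cue_width)]) > 0))
})

test_that("time series place lagged modulation where scheduled", {
  s <- small_subject(noise_sd = 0, seed = 42)
  ts <- s$ts
  expect_equal(ts$units, "raw")
  expect_equal(ncol(ts$signal), s$pd$trs_per_run)
  # baseline TRs carry no modulation: raw == s0 exactly
  lag <- 3L
  modulated <- rep(FALSE, s$pd$trs_per_run)
  for (i in seq_len(nrow(s$sched))) {
    w <- (s$sched$tr_start[i] + lag):(s$sched$tr_end[i] + lag - 1L)
    modulated[w + 1L] <- TRUE
  }
  expect_true(all(ts$signal[, !modulated] == 1000))
  # inside a block, the voxel nearest the cue center carries ~the full gain
  i <- 1L
  cols <- (s$sched$tr_start[i] + lag):(s$sched$tr_end[i] + lag - 1L) + 1L
  vox <- which.min(angular_distance(s$prfs$polar_angle, s$sched$cue_center[i]))
  psc_peak <- (mean(ts$signal[vox, cols]) / 1000 - 1) * 100
  expect_gt(psc_peak, 0.95)
})

test_that("the generator is deterministic and validates inputs", {
  s <- small_subject(noise_sd = 0, seed = 42)
  a <- simulate_timeseries(s$prfs, s$sched, s$truth, s$pd, noise_sd = 1,
                           seed = 9)
  b <- simulate_timeseries(s$prfs, s$sched, s$truth, s$pd, noise_sd = 1,
                           seed = 9)
  expect_identical(a$signal, b$signal)
  expect_error(simulate_timeseries(s$prfs, s$sched, s$truth[-1, ], s$pd),
               "missing block")
  expect_error(simulate_timeseries(s$prfs, s$sched, s$truth, s$pd,
                                   noise_sd = -1), "nonnegative")
})

test_that("zero true gain yields a flat profile and near-zero fitted gain", {
  pd <- paradigm_config()
  sched <- build_cue_schedule(pd, n_runs = 1, seed = 6)
  truth <- default_field_truth(sched, gain_true = 0, baseline_true = 0)
  prfs <- simulate_prf_table(400, pd, seed = 7, violation_fraction = 0)
  v1 <- prfs[prfs$roi == "V1", ]
  ts <- simulate_timeseries(v1, sched, truth, pd, noise_sd = 0, seed = 8)
  psc <- percent_signal_change(ts)
  sel <- select_voxels(v1, pd)
  br <- block_average(psc, sched)
  resp <- br$response[match(sel$voxel_id, psc$voxel_id), 1]
  expect_lt(diff(range(resp)), 1e-10)
  prof <- bin_profile_1d(resp, sel)
  fit <- attfield_fit(prof)
  expect_true("degenerate_profile" %in% fit$flags ||
                abs(fit$params$gain) < 1e-6)
})
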