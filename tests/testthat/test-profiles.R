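# Voxel selection and 1D/2D spatial-profile construction.

test_that("voxel selection applies every exclusion rule", {
  cfg <- paradigm_config()
  prfs <- data.frame(
    voxel_id = paste0("v", 1:6), roi = "V1",
    polar_angle = seq(0, 300, 60),
    eccentricity = c(5.0, 5.0, 4.0, 0.5, 9.5, 2.0),
    prf_size = c(1, 1, 1.0, 1, 1, 0.5),
    prf_r2 = c(0.5, 0.05, 0.5, 0.9, 0.9, 0.9)
  )
  sel <- select_voxels(prfs, cfg)
  # inside the annulus, good fit -> retained
  expect_true("v1" %in% sel$voxel_id)
  # poor pRF model fit (R2 < 10%) -> excluded
  expect_false("v2" %in% sel$voxel_id)
  # outside the annulus but pRF reaches it: 4.0 + 1.0 >= 4.6 -> retained
  expect_true("v3" %in% sel$voxel_id)
  # outside the pRF stimulus bounds -> excluded
  expect_false("v4" %in% sel$voxel_id)
  expect_false("v5" %in% sel$voxel_id)
  # too far below the annulus: 2.0 + 0.5 < 4.6 -> excluded
  expect_false("v6" %in% sel$voxel_id)
  # empty selection names the dominant filter
  far <- transform(prfs, prf_r2 = 0.01)
  expect_error(select_voxels(far, cfg), "prf_r2")
})

test_that("1D binning uses half-open 6-deg bins and the median", {
  cfg <- paradigm_config()
  # three voxels in bin [6, 12): median survives one outlier
  prfs <- data.frame(voxel_id = paste0("v", 1:3), roi = "V1",
                     polar_angle = c(7, 8, 11), eccentricity = 6,
                     prf_size = 1, prf_r2 = 0.9)
  many <- do.call(rbind, lapply(0:59, function(k) {
    transform(prfs, polar_angle = 6 * k + c(1, 3, 5),
              voxel_id = paste0("b", k, "_", 1:3))
  }))
  vals <- rep(0, nrow(many))
  vals[many$polar_angle > 6 & many$polar_angle < 12] <- c(1, 2, 100)
  p <- bin_profile_1d(vals, many)
  expect_s3_class(p, "spatial_profile")
  expect_equal(p$values[2], 2)   # bin index 2 holds [6, 12)
  expect_equal(p$values[1], 0)
  # a constant field gives a flat profile
  flat <- bin_profile_1d(rep(3.5, nrow(many)), many)
  expect_equal(flat$values, rep(3.5, 60))
})

test_that("empty bins are interpolated circularly and flagged", {
  # voxels only in bins 0 and 2; bin 1 interpolated halfway
  prfs <- do.call(rbind, lapply(setdiff(0:59, 1), function(k) {
    data.frame(voxel_id = paste0("k", k), roi = "V1",
               polar_angle = 6 * k + 3, eccentricity = 6, prf_size = 1,
               prf_r2 = 0.9)
  }))
  vals <- ifelse(prfs$polar_angle < 6, 1, ifelse(prfs$polar_angle < 18, 5, 1))
  p <- bin_profile_1d(vals, prfs)
  expect_true(p$interpolated[2])
  expect_equal(p$values[2], 3)  # midpoint of neighbors 1 and 5
  # too many empty bins is an undersampling error
  few <- prfs[1:20, ]
  expect_error(bin_profile_1d(vals[1:20], few), "undersamples")
})

test_that("recentering is an exact circular rotation", {
  set.seed(1)
  p <- spatial_profile(rnorm(60))
  r <- recenter_profile(p, 90)
  # 90 deg = 15 bins; multiset unchanged
  expect_equal(r$values, p$values[((0:59 + 15) %% 60) + 1])
  expect_equal(sort(r$values), sort(p$values))
  expect_true(r$recentered)
  # cue 0 is the identity
  expect_equal(recenter_profile(p, 0)$values, p$values)
  # rotate then inverse-rotate restores the profile exactly
  back <- recenter_profile(recenter_profile(p, 90), -90)
  expect_identical(back$values, p$values)
  expect_error(recenter_profile(p, 4), "integer number")
})

test_that("smoothing is a mean-conserving circular moving average", {
  flat <- spatial_profile(rep(2, 60))
  expect_equal(smooth_profile(flat)$values, rep(2, 60))
  # unit impulse spreads to 1/3 over bins 59, 0, 1
  imp <- spatial_profile(c(1, rep(0, 59)))
  sm <- smooth_profile(imp)
  expect_equal(sm$values[c(60, 1, 2)], rep(1 / 3, 3))
  expect_equal(sum(sm$values[-c(60, 1, 2)]), 0)
  set.seed(2)
  p <- spatial_profile(rnorm(60))
  expect_equal(mean(smooth_profile(p)$values), mean(p$values),
               tolerance = 1e-14)
  expect_error(smooth_profile(p, width_deg = 24), "odd")
  expect_error(smooth_profile(p, width_deg = 10), "multiple")
})

test_that("recentering and smoothing commute", {
  set.seed(3)
  p <- spatial_profile(rnorm(60))
  a <- smooth_profile(recenter_profile(p, 126))
  b <- recenter_profile(smooth_profile(p), 126)
  expect_equal(a$values, b$values, tolerance = 1e-14)
})

test_that("2D reconstruction places the bump at the rotated cue", {
  cfg <- paradigm_config()
  prfs <- simulate_prf_table(600, cfg, seed = 5, violation_fraction = 0)
  v1 <- prfs[prfs$roi == "V1", ]
  # constant responses z-score to all zeros
  m0 <- reconstruct_field_2d(rep(1, nrow(v1)), v1, cue_center = 0,
                             grid_step = 0.25)
  expect_true(all(m0$z[!is.na(m0$z)] == 0))
  # a bump of modulation at 120 deg on the annulus maps to ~(mid, 0)
  # after rotating the cue to the right horizontal meridian
  mid <- (cfg$annulus_inner + cfg$annulus_outer) / 2
  vals <- gen_gaussian(v1$polar_angle, 120, 40, 4) *
    exp(-((v1$eccentricity - mid)^2) / 2)
  m <- reconstruct_field_2d(vals, v1, cue_center = 120, grid_step = 0.1)
  peak <- which(m$z == max(m$z, na.rm = TRUE), arr.ind = TRUE)[1, ]
  px <- m$x[peak[1]]
  py <- m$y[peak[2]]
  expect_lt(sqrt((px - mid)^2 + py^2), 1)
  # degenerate geometry errors
  line <- data.frame(polar_angle = c(0, 0, 180), eccentricity = c(1, 2, 3),
                     prf_size = 1, prf_r2 = 0.9)
  expect_error(reconstruct_field_2d(1:3, line), "collinear")
})
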