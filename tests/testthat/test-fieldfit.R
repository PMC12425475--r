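# The generalized Gaussian model: evaluation, normalization, grid-search
# initialization, bounded fitting, FWHM, angular error, R-squared.

test_that("the curve evaluates correctly on the circle", {
  expect_equal(gen_gaussian(90, 90, 30, 2), 1)
  # at distance sigma the exponent is 1 for any beta
  for (b in c(1.8, 2, 4, 50)) {
    expect_equal(gen_gaussian(120, 90, 30, b), exp(-1))
  }
  # half maximum at sigma * log(2)^(1/beta): 30 * sqrt(log 2) ~ 24.98 deg
  expect_equal(gen_gaussian(30 * log(2)^(1 / 2), 0, 30, 2), 0.5)
  # wrapped distance: 350 deg is 10 deg from 0
  expect_equal(gen_gaussian(350, 0, 30, 2), gen_gaussian(10, 0, 30, 2))
})

test_that("normalization and prediction span [baseline, baseline + gain]", {
  xc <- profile_bin_centers()
  p <- list(mu = 45, sigma = 60, beta = 4, gain = 1.5, baseline = -0.2)
  yhat <- predict_profile(p, xc)
  expect_equal(max(yhat), p$gain + p$baseline)
  expect_equal(min(yhat), p$baseline)
  # zero gain collapses to the constant baseline
  flat <- predict_profile(modifyList(p, list(gain = 0)), xc)
  expect_equal(flat, rep(-0.2, 60))
  # even the broadest admissible curve still spans [0, 1] after min-max
  ngg <- norm_gen_gaussian(xc, 0, 180, 1.8)
  expect_equal(range(ngg), c(0, 1))
})

test_that("grid search returns the SSE-minimizing candidate", {
  prof <- profile_from_params(180, 60, 4, 1, 0)
  init <- grid_search_init(prof)
  expect_equal(init$mu, 180)
  # exhaustive check: no candidate on the 6 x 6 grid beats the winner
  xc <- prof$bin_centers
  for (mu in seq(0, 300, by = 60)) {
    for (sg in seq(9, 162, length.out = 6)) {
      sse <- sum((prof$values - predict_profile(
        list(mu = mu, sigma = sg, beta = 4, gain = 1, baseline = 0),
        xc))^2)
      expect_gte(sse, init$sse - 1e-12)
    }
  }
  # a flat zero profile: every location ties by circular symmetry (the
  # tie-break picks the first), and the narrowest scale minimizes the SSE
  flat_init <- grid_search_init(spatial_profile(rep(0, 60)))
  expect_equal(flat_init$mu, 0)
  expect_equal(flat_init$sigma, 9)
})

test_that("noiseless profiles are recovered to high precision", {
  truth <- list(mu = 90, sigma = 40, beta = 4, gain = 1.2, baseline = 0.1)
  fit <- attfield_fit(profile_from_params(90, 40, 4, 1.2, 0.1),
                      true_center = 90)
  expect_gte(fit$r2, 0.999)
  expect_lt(abs(angular_error(fit$params$mu, 90)), 1)
  expect_lt(abs(fit$abs_angular_error), 1)
  # optimizer never worsens the grid initialization
  expect_lte(fit$sse, fit$init$sse)
})

test_that("location recovery is robust to moderate profile noise", {
  errs <- vapply(1:200, function(i) {
    prof <- profile_from_params(90, 40, 4, 1, 0, noise_sd = 0.05,
                                seed = 1000 + i)
    abs(angular_error(attfield_fit(prof)$params$mu, 90))
  }, numeric(1))
  expect_lt(median(errs), 6)
})

test_that("fitted parameters respect the bounds and flags fire", {
  set.seed(7)
  for (i in 1:10) {
    prof <- spatial_profile(rnorm(60, 0, 0.5))
    fit <- attfield_fit(prof)
    p <- fit$params
    expect_true(p$mu >= 0 && p$mu < 360)
    expect_true(p$sigma >= 6 && p$sigma <= 180)
    expect_true(p$beta >= 1.8 && p$beta <= 50)
    expect_true(p$gain >= 0 && p$gain <= 20)
    expect_lte(fit$sse, fit$init$sse + 1e-12)
  }
  flat <- attfield_fit(spatial_profile(rep(1, 60)))
  expect_true("degenerate_profile" %in% flat$flags)
  expect_true(is.na(flat$r2))
  expect_equal(flat$params$gain, 0)
})

test_that("fitting is equivariant under rotation of the profile", {
  prof <- profile_from_params(40, 50, 3, 1, 0.2, noise_sd = 0.03,
                              seed = 11)
  base <- attfield_fit(prof)
  rot <- prof
  shift <- 10L  # 60 deg
  rot$values <- prof$values[((0:59 + shift) %% 60) + 1]
  rfit <- attfield_fit(rot)
  expect_lt(abs(angular_error(rfit$params$mu, base$params$mu - 60)), 1e-4)
  expect_equal(rfit$params$sigma, base$params$sigma, tolerance = 1e-6)
  expect_equal(rfit$params$beta, base$params$beta, tolerance = 1e-6)
  expect_equal(rfit$params$gain, base$params$gain, tolerance = 1e-6)
  expect_equal(rfit$params$baseline, base$params$baseline,
               tolerance = 1e-6)
})

test_that("the closed-form FWHM matches a brute-force half-max search", {
  expect_equal(compute_fwhm(50, 2), 2 * 50 * sqrt(log(2)))
  expect_equal(round(compute_fwhm(50, 2), 2), 83.26)
  expect_equal(round(compute_fwhm(50, 50), 2), 99.27)
  expect_lte(compute_fwhm(180, 50), 360)
  # brute force: finest-grid search for the half-maximum crossing
  brute_fwhm <- function(sigma, beta) {
    d <- seq(0, 180, by = 0.001)
    g <- exp(-(d / sigma)^beta)
    if (all(g >= 0.5)) return(360)
    min(2 * d[which(g < 0.5)[1]], 360)
  }
  for (sg in c(6, 30, 60, 120, 180)) {
    for (b in c(1.8, 2, 4, 10, 50)) {
      expect_lt(abs(compute_fwhm(sg, b) - brute_fwhm(sg, b)), 0.1)
    }
  }
  # the normalized-curve variant agrees when the curve reaches ~0 on the
  # grid, and is defined (<= 360) everywhere in bounds
  expect_equal(compute_fwhm(30, 4, mode = "normalized"),
               compute_fwhm(30, 4), tolerance = 0.01)
  expect_lte(compute_fwhm(180, 1.8, mode = "normalized"), 360)
})

test_that("estimated width grows with the true width", {
  sigmas <- c(30, 60, 90, 120)
  fwhms <- vapply(sigmas, function(sg) {
    attfield_fit(profile_from_params(180, sg, 4, 1, 0))$fwhm
  }, numeric(1))
  expect_true(all(diff(fwhms) > 0))
})

test_that("angular error wraps and signs as specified", {
  expect_equal(angular_error(10, 350), 20)
  expect_equal(angular_error(350, 10), -20)
  expect_equal(angular_error(180, 0), 180)   # boundary convention: +180
  expect_equal(angular_error(0, 180), 180)
  expect_equal(angular_error(90, 90), 0)
})

test_that("R-squared follows the explained-variance definition", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  expect_lt(r_squared(y, rev(y)), 0)
  expect_warning(out <- r_squared(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(out))
})

test_that("model methods are coherent with the stored fit", {
  prof <- profile_from_params(120, 70, 2.5, 0.8, 0.05, noise_sd = 0.02,
                              seed = 3)
  fit <- attfield_fit(prof, true_center = 120)
  expect_named(coef(fit), c("mu", "sigma", "beta", "gain", "baseline"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, prof$bin_centers), fitted(fit))
  expect_equal(residuals(fit), prof$values - fitted(fit))
  expect_equal(sum(residuals(fit)^2), fit$sse, tolerance = 1e-10)
  s <- summary(fit)
  expect_s3_class(s, "summary.attfield")
  expect_equal(s$fwhm, fit$fwhm)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(60L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  expect_output(print(fit), "Attentional-field fit")
})
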