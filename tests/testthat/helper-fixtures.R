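# Shared fixtures, built in code and cached for the duration of the test
# run.  The "small subject" is one noiseless and one noisy run through the
# simulator at reduced voxel count, enough for every bin to be occupied.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A deterministic synthetic subject: schedule, truth, pRFs, raw series.
small_subject <- function(noise_sd = 0, seed = 42, n_runs = 1,
                          n_vox = 400) {
  key <- paste0("subj_", noise_sd, "_", seed, "_", n_runs, "_", n_vox)
  fixture(key, function() {
    pd <- paradigm_config()
    sched <- build_cue_schedule(pd, n_runs = n_runs, seed = seed)
    truth <- default_field_truth(sched)
    prfs <- simulate_prf_table(n_vox, pd, seed = seed + 1,
                               violation_fraction = 0)
    roi_prfs <- prfs[prfs$roi == "V1", , drop = FALSE]
    ts <- simulate_timeseries(roi_prfs, sched, truth, pd,
                              noise_sd = noise_sd, seed = seed + 2)
    list(pd = pd, sched = sched, truth = truth, prfs = roi_prfs, ts = ts)
  })
}

# A noiseless profile generated straight from known field parameters.
profile_from_params <- function(mu, sigma, beta, gain = 1, baseline = 0,
                                noise_sd = 0, seed = NULL) {
  xc <- profile_bin_centers()
  y <- predict_profile(list(mu = mu, sigma = sigma, beta = beta,
                            gain = gain, baseline = baseline), xc)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  spatial_profile(y)
}
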