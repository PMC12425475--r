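# Paradigm configuration and schedule generation for the block-design
# attention task: an iso-eccentric white-noise annulus split into 20 bins of
# 18 deg polar angle, with a fixation cue selecting 1/3/5/9 contiguous bins
# for five-trial (10 TR) blocks.

#' Paradigm configuration
#'
#' Collects the design constants of the attention paradigm.  Defaults are
#' the main experiment: 20 cue positions (18 deg apart), cue widths 18, 54,
#' 90, 162 deg of polar angle, 5 trials of 2 TRs per block, TR = 1.55 s,
#' 100 trials per run with 15.5 s of baseline at the start and end of each
#' run (341 s, 220 TRs per run), and a noise annulus spanning 4.6-7.4 deg
#' of visual angle.  `contrast_mode = TRUE` switches to the physical
#' contrast variant: widths gain 126 deg, cue centers are restricted to the
#' cardinal directions, and the modulation edge has a Gaussian rolloff
#' (sigma 15 deg).
#'
#' @param n_bins number of annulus segments (default 20).
#' @param bin_width segment width, deg polar angle (default 18).
#' @param widths cue widths, deg polar angle.
#' @param trials_per_block trials with a constant cue (default 5).
#' @param trs_per_trial TRs per trial (default 2).
#' @param tr_seconds repetition time in seconds (default 1.55).
#' @param baseline_seconds baseline at each end of a run (default 15.5).
#' @param trials_per_run trials per run (default 100).
#' @param annulus_inner,annulus_outer annulus bounds, deg visual angle
#'   (default 4.6 / 7.4; the alternate display used 4.1 / 6.5).
#' @param contrast_mode logical; physical-contrast variant of the paradigm.
#' @param rolloff_sigma Gaussian edge rolloff of the contrast profile, deg
#'   polar angle (contrast mode only).
#' @return an object of class `paradigm_config` (a list), with derived
#'   fields `trial_seconds`, `trs_per_block`, `baseline_trs`,
#'   `blocks_per_run`, `trs_per_run`, `run_seconds`, and `bin_centers`.
#' @export
#' @examples
#' cfg <- paradigm_config()
#' cfg$run_seconds  # 341
#' cfg$trs_per_run  # 220
paradigm_config <- function(n_bins = 20L,
                            bin_width = 18,
                            widths = c(18, 54, 90, 162),
                            trials_per_block = 5L,
                            trs_per_trial = 2L,
                            tr_seconds = 1.55,
                            baseline_seconds = 15.5,
                            trials_per_run = 100L,
                            annulus_inner = 4.6,
                            annulus_outer = 7.4,
                            contrast_mode = FALSE,
                            rolloff_sigma = 15) {
  if (contrast_mode && identical(widths, c(18, 54, 90, 162))) {
    widths <- c(18, 54, 90, 126, 162)
  }
  if (n_bins * bin_width != 360) {
    stop("n_bins * bin_width must equal 360 degrees of polar angle")
  }
  if (any(round(widths / bin_width) %% 2 != 1)) {
    stop("cue widths must be odd multiples of the bin width")
  }
  if (trials_per_run %% trials_per_block != 0) {
    stop("trials_per_run must be divisible by trials_per_block")
  }
  if (annulus_inner <= 0 || annulus_outer <= annulus_inner) {
    stop("annulus bounds must satisfy 0 < inner < outer")
  }
  trial_seconds <- trs_per_trial * tr_seconds
  trs_per_block <- trials_per_block * trs_per_trial
  baseline_trs <- round(baseline_seconds / tr_seconds)
  blocks_per_run <- trials_per_run %/% trials_per_block
  trs_per_run <- 2L * baseline_trs + blocks_per_run * trs_per_block
  cfg <- list(
    n_bins = as.integer(n_bins), bin_width = bin_width, widths = widths,
    trials_per_block = as.integer(trials_per_block),
    trs_per_trial = as.integer(trs_per_trial),
    tr_seconds = tr_seconds, trial_seconds = trial_seconds,
    baseline_seconds = baseline_seconds,
    trials_per_run = as.integer(trials_per_run),
    annulus_inner = annulus_inner, annulus_outer = annulus_outer,
    contrast_mode = isTRUE(contrast_mode), rolloff_sigma = rolloff_sigma,
    trs_per_block = as.integer(trs_per_block),
    baseline_trs = as.integer(baseline_trs),
    blocks_per_run = as.integer(blocks_per_run),
    trs_per_run = as.integer(trs_per_run),
    run_seconds = trs_per_run * tr_seconds,
    bin_centers = bin_width * (seq_len(n_bins) - 1L)
  )
  class(cfg) <- "paradigm_config"
  cfg
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("Attention paradigm:", x$n_bins, "bins x", x$bin_width,
      "deg; widths", paste(x$widths, collapse = "/"), "deg\n")
  cat("  ", x$blocks_per_run, " blocks/run (", x$trs_per_block,
      " TRs each), ", x$trs_per_run, " TRs = ", x$run_seconds,
      " s per run\n", sep = "")
  cat("  annulus ", x$annulus_inner, "-", x$annulus_outer,
      " deg visual angle",
      if (x$contrast_mode) "; contrast mode" else "", "\n", sep = "")
  invisible(x)
}

#' Build a randomized cue schedule
#'
#' Each run contains `trials_per_run / trials_per_block` blocks (20 by
#' default), covering a randomized selection of (center, width) cue
#' combinations with every width appearing equally often and centers drawn
#' without replacement (per width) from the bin centers.  When the centers
#' per width divide the circle evenly (5 centers over 20 bins by default),
#' each width's centers are a randomly rotated evenly spaced lattice
#' (72 deg apart), which balances stimulation over polar angle within the
#' run — the per-voxel run-average modulation is then flat in angle, so
#' percent-signal-change mean removal does not imprint a spatial background
#' on the block profiles.  Block order within the run is shuffled.  TR
#' indices are half-open `[tr_start, tr_end)`, zero-based within the run,
#' with the run's leading baseline before the first block.
#'
#' @param config a [paradigm_config()].
#' @param n_runs number of runs (>= 1).
#' @param seed integer seed; the schedule is a pure function of
#'   `(config, n_runs, seed)`.
#' @return a data frame of class `cue_schedule` with columns `block_id`,
#'   `run_id`, `cue_center`, `cue_width`, `tr_start`, `tr_end`.
#' @export
#' @examples
#' sched <- build_cue_schedule(paradigm_config(), n_runs = 1, seed = 7)
#' nrow(sched)                       # 20 blocks
#' unique(sched$tr_end - sched$tr_start)  # 10 TRs each
build_cue_schedule <- function(config = paradigm_config(), n_runs = 1L,
                               seed = NULL) {
  stopifnot(inherits(config, "paradigm_config"), n_runs >= 1)
  n_widths <- length(config$widths)
  bpr <- config$blocks_per_run
  if (bpr %% n_widths != 0) {
    stop("blocks per run (", bpr, ") not divisible by number of widths (",
         n_widths, ")")
  }
  per_width <- bpr %/% n_widths
  if (per_width > config$n_bins) {
    stop("more blocks per width than available cue centers")
  }
  centers <- if (config$contrast_mode) c(0, 90, 180, 270) else config$bin_centers
  if (per_width > length(centers)) {
    stop("more blocks per width than available cue centers")
  }
  n_centers <- length(centers)
  lattice <- n_centers %% per_width == 0
  with_seed(seed, {
    runs <- lapply(seq_len(n_runs), function(r) {
      combos <- do.call(rbind, lapply(config$widths, function(w) {
        picked <- if (lattice) {
          step <- n_centers %/% per_width
          start <- sample.int(n_centers, 1L)
          centers[((start - 1L + step * (seq_len(per_width) - 1L)) %% n_centers) + 1L]
        } else {
          sample(centers, per_width)
        }
        data.frame(cue_center = picked, cue_width = w)
      }))
      combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
      tr_start <- config$baseline_trs + (seq_len(bpr) - 1L) * config$trs_per_block
      data.frame(
        run_id = r,
        cue_center = combos$cue_center,
        cue_width = combos$cue_width,
        tr_start = tr_start,
        tr_end = tr_start + config$trs_per_block
      )
    })
    out <- do.call(rbind, runs)
    out <- cbind(block_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    class(out) <- c("cue_schedule", "data.frame")
    out
  })
}

#' Assign letter/number categories to cued bins
#'
#' Per trial, the cued bins carry an exact majority ratio fixed by the cue
#' width: 1 bin holds a single item; 3 bins split 2:1; 5 bins split 3:2;
#' 9 bins split 6:3.  The majority category (number vs letter) is chosen
#' uniformly per trial, positions of majority items within the cued span
#' are randomized, and uncued bins are filled independently at random.
#'
#' @param block one row of a [build_cue_schedule()] schedule (or a list
#'   with `block_id`, `cue_center`, `cue_width`).
#' @param config a [paradigm_config()].
#' @param seed integer seed.
#' @return a data frame with one row per (trial, bin): columns `block_id`,
#'   `trial_index`, `bin_center`, `cued`, `category`, `majority_category`.
#' @export
assign_stimulus_categories <- function(block, config = paradigm_config(),
                                       seed = NULL) {
  block <- as.list(block)
  n_cued <- round(block$cue_width / config$bin_width)
  ratio <- switch(as.character(n_cued),
    "1" = c(1L, 0L), "3" = c(2L, 1L), "5" = c(3L, 2L), "9" = c(6L, 3L),
    stop("unsupported cue width: ", block$cue_width, " deg (",
         n_cued, " bins); supported bin counts are 1, 3, 5, 9")
  )
  centers <- config$bin_centers
  offset <- (seq_len(n_cued) - 1L) - (n_cued - 1L) %/% 2L
  cued_centers <- wrap_angle(block$cue_center + offset * config$bin_width)
  cued <- centers %in% cued_centers
  cats <- c("number", "letter")
  with_seed(seed, {
    trials <- lapply(seq_len(config$trials_per_block), function(t) {
      maj <- sample(cats, 1L)
      minr <- setdiff(cats, maj)
      fill <- rep(minr, n_cued)
      fill[sample.int(n_cued, ratio[1])] <- maj
      cat_all <- sample(cats, config$n_bins, replace = TRUE)
      cat_all[match(cued_centers, centers)] <- fill
      data.frame(
        block_id = block$block_id, trial_index = t, bin_center = centers,
        cued = cued, category = cat_all, majority_category = maj
      )
    })
    do.call(rbind, trials)
  })
}

#' Polar-angle profile of the physical contrast manipulation
#'
#' In the contrast variant the annulus contrast is raised to 100% over a
#' span of 1, 3, 5, 7, or 9 bins centered on a cardinal direction, with a
#' Gaussian rolloff (sigma = 15 deg polar angle) at the edges spanning the
#' outer 25% of the furthest included bins and the inner 25% of the
#' adjacent excluded bins.  Returns the resulting modulation profile as a
#' function of polar angle: 1 over the fully included core, Gaussian
#' shoulders across the edge region, ~0 far outside.
#'
#' @param center cue center, one of 0, 90, 180, 270 deg.
#' @param width nominal width, one of 18, 54, 90, 126, 162 deg.
#' @param config a [paradigm_config()] (supplies bin width and rolloff
#'   sigma).
#' @return a function mapping polar angle (deg) to modulation in `[0, 1]`.
#' @export
#' @examples
#' f <- contrast_profile(90, 54)
#' f(90)        # 1 at the center
#' f(270) < 1e-3  # negligible at the antipode
contrast_profile <- function(center, width, config = paradigm_config(contrast_mode = TRUE)) {
  if (!center %in% c(0, 90, 180, 270)) {
    stop("contrast center must be a cardinal direction (0/90/180/270 deg)")
  }
  if (!width %in% c(18, 54, 90, 126, 162)) {
    stop("unsupported contrast width: ", width, " deg")
  }
  sig <- config$rolloff_sigma
  # Rolloff shoulder starts 25% of a bin inside the nominal edge and the
  # Gaussian is anchored there; beyond the edge region it decays with
  # sigma = 15 deg.
  edge <- width / 2 - 0.25 * config$bin_width
  force(center)
  function(x) {
    d <- angular_distance(x, center)
    ifelse(d <= edge, 1, exp(-((d - edge)^2) / (2 * sig^2)))
  }
}

#' Simulate behavioral responses
#'
#' Bernoulli correctness per trial at a per-width accuracy, for summarizing
#' task performance against chance (0.5).
#'
#' @param schedule a [build_cue_schedule()] data frame.
#' @param config a [paradigm_config()].
#' @param accuracy_by_width named numeric vector mapping width (deg, as
#'   character) to probability correct in `(0, 1]`.
#' @param seed integer seed.
#' @return a data frame with one row per trial: `block_id`, `run_id`,
#'   `cue_width`, `trial_index`, `correct`.
#' @export
simulate_behavior <- function(schedule, config = paradigm_config(),
                              accuracy_by_width, seed = NULL) {
  acc <- accuracy_by_width[as.character(schedule$cue_width)]
  if (anyNA(acc)) stop("accuracy_by_width is missing an entry for some cue width")
  if (any(acc <= 0 | acc > 1)) stop("accuracies must lie in (0, 1]")
  k <- config$trials_per_block
  with_seed(seed, {
    data.frame(
      block_id = rep(schedule$block_id, each = k),
      run_id = rep(schedule$run_id, each = k),
      cue_width = rep(schedule$cue_width, each = k),
      trial_index = rep(seq_len(k), times = nrow(schedule)),
      correct = stats::rbinom(nrow(schedule) * k, 1L, rep(acc, each = k)) == 1L
    )
  })
}
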