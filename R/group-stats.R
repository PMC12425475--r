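# Group-level statistics on fitted field parameters: pooled-R2 exclusion
# of poor fits, per-subject slope regressions of each metric on cue width
# (and TR count) with group t-tests, paired ROI comparisons, and
# behavioral accuracy against chance.

#' Exclude the worst fits by pooled R-squared
#'
#' For each subject, each block's pooled R-squared is the unweighted mean
#' of its V1, V2, and V3 fit R-squared.  The lowest `floor(0.2 * n_blocks)`
#' blocks are marked excluded (ties broken by block id, ascending), and the
#' exclusion applies to the block as a whole — all three ROI fits.
#'
#' @param fits a data frame of fit results with columns `block_id`, `roi`,
#'   `r2` (one row per block x ROI) and optionally `subject_id` and
#'   `n_trs` (exclusion is computed within subject and, when present,
#'   within each TR-count level).
#' @param prop fraction excluded (default 0.2).
#' @return `fits` with columns `pooled_r2` and logical `included` added.
#' @export
exclude_low_r2 <- function(fits, prop = 0.2) {
  need <- c("block_id", "roi", "r2")
  miss <- setdiff(need, names(fits))
  if (length(miss) > 0) {
    stop("fit table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!"subject_id" %in% names(fits)) fits$subject_id <- 1L
  grp <- if ("n_trs" %in% names(fits)) {
    paste(fits$subject_id, fits$n_trs)
  } else {
    as.character(fits$subject_id)
  }
  rois <- c("V1", "V2", "V3")
  fits$pooled_r2 <- NA_real_
  fits$included <- NA
  for (s in unique(grp)) {
    rows <- grp == s
    sub <- fits[rows, ]
    tab <- table(sub$block_id, sub$roi)
    if (!all(rois %in% colnames(tab)) ||
        any(tab[, rois, drop = FALSE] != 1)) {
      stop("fit group ", s, ": every block needs exactly one fit per ROI (",
           paste(rois, collapse = ", "), ")")
    }
    pooled <- tapply(sub$r2, sub$block_id, mean)
    blocks <- as.numeric(names(pooled))
    ord <- order(pooled, blocks)
    n_excl <- floor(prop * length(blocks))
    excluded_blocks <- blocks[ord[seq_len(n_excl)]]
    fits$pooled_r2[rows] <- pooled[as.character(sub$block_id)]
    fits$included[rows] <- !(sub$block_id %in% excluded_blocks)
  }
  fits
}

#' Per-subject slope regression with a group-level t-test
#'
#' Fits, within each subject, an ordinary least-squares regression of a
#' block-level metric on cue width (optionally with the number of TRs as a
#' second explanatory variable), then tests the per-subject slopes of the
#' term of interest against zero with a two-sided one-sample t-test
#' (df = n_subjects - 1).
#'
#' @param fits a data frame with columns `subject_id`, `cue_width`, the
#'   metric column, and `n_trs` when used as a predictor.
#' @param metric name of the metric column (e.g. `"fwhm"`,
#'   `"abs_angular_error"`, `"gain"`, `"baseline"`).
#' @param roi optional ROI label to subset on (`fits$roi`).
#' @param predictors `"width"` or `c("width", "n_trs")`.
#' @param test_term which slope to test: `"width"` (default) or `"n_trs"`.
#' @return an object of class `slope_test`: list with `slopes` (named per
#'   subject), `mean_slope`, `t`, `p`, `df`, `metric`, `roi`, `test_term`.
#' @export
slope_test <- function(fits, metric, roi = NULL,
                       predictors = "width", test_term = "width") {
  stopifnot(metric %in% names(fits),
            all(predictors %in% c("width", "n_trs")),
            test_term %in% predictors)
  if (!is.null(roi)) fits <- fits[fits$roi == roi, , drop = FALSE]
  if ("included" %in% names(fits)) {
    fits <- fits[fits$included, , drop = FALSE]
  }
  subjects <- unique(fits$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  rhs <- c(width = "cue_width", n_trs = "n_trs")[predictors]
  form <- stats::as.formula(paste(metric, "~", paste(rhs, collapse = " + ")))
  term <- c(width = "cue_width", n_trs = "n_trs")[[test_term]]
  slopes <- vapply(subjects, function(s) {
    sub <- fits[fits$subject_id == s, , drop = FALSE]
    for (v in rhs) {
      if (length(unique(sub[[v]])) < if (v == term) 3L else 2L) {
        stop("subject ", s, ": too few distinct values of ", v,
             " for a slope regression")
      }
    }
    stats::coef(stats::lm(form, data = sub))[[term]]
  }, numeric(1))
  tt <- stats::t.test(slopes, mu = 0)
  structure(
    list(slopes = stats::setNames(slopes, subjects),
         mean_slope = mean(slopes),
         t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter),
         metric = metric, roi = roi, test_term = test_term),
    class = "slope_test"
  )
}

#' @export
print.slope_test <- function(x, ...) {
  cat("Group slope test:", x$metric, "~", x$test_term,
      if (!is.null(x$roi)) paste0("[", x$roi, "]"), "\n")
  cat(sprintf("  mean slope %.4g, t(%d) = %.3f, p = %.4g  (n = %d subjects)\n",
              x$mean_slope, x$df, x$t, x$p, length(x$slopes)))
  invisible(x)
}

#' Paired comparison of a metric between two conditions
#'
#' Two-sided paired t-test on per-subject summaries (median by default) of
#' a metric under two matched conditions, e.g. gain in V2 vs V1.
#' Identical samples give t = 0, p = 1; a constant nonzero difference has
#' no defined t statistic and is returned flagged.
#'
#' @param a,b numeric vectors of per-subject values, matched by position.
#' @return list with `t`, `p`, `df`, `mean_diff`, `flag` (`NA` or
#'   `"degenerate"`).
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) stop("conditions have mismatched subjects")
  d <- a - b
  if (stats::sd(d) <= .Machine$double.eps * 100) {
    if (all(abs(d) <= .Machine$double.eps * 100)) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0,
                  flag = NA_character_))
    }
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), flag = "degenerate"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), flag = NA_character_)
}

#' Test behavioral accuracy against chance
#'
#' Per cue width, a two-sided one-sample t-test of the subject-level
#' proportion correct against chance (0.5).  A width condition where all
#' subjects share the same proportion (zero variance) is flagged
#' degenerate; all-at-chance gives t = 0.
#'
#' @param behavior a data frame of per-trial flags with columns
#'   `subject_id`, `cue_width`, `correct` (logical), e.g. from
#'   [simulate_behavior()] over subjects.
#' @return a data frame with one row per width: `cue_width`,
#'   `mean_accuracy`, `t`, `p`, `df`, `flag`.
#' @export
accuracy_vs_chance <- function(behavior) {
  need <- c("subject_id", "cue_width", "correct")
  miss <- setdiff(need, names(behavior))
  if (length(miss) > 0) {
    stop("behavior table lacks column(s): ", paste(miss, collapse = ", "))
  }
  widths <- sort(unique(behavior$cue_width))
  rows <- lapply(widths, function(w) {
    sub <- behavior[behavior$cue_width == w, ]
    props <- tapply(sub$correct, sub$subject_id, mean)
    if (length(props) < 2) stop("need at least 2 subjects")
    if (stats::sd(props) <= .Machine$double.eps * 100) {
      t_val <- if (abs(mean(props) - 0.5) <= .Machine$double.eps * 100) 0 else NA_real_
      return(data.frame(cue_width = w, mean_accuracy = mean(props),
                        t = t_val, p = if (is.na(t_val)) NA_real_ else 1,
                        df = length(props) - 1L,
                        flag = if (is.na(t_val)) "degenerate" else NA_character_))
    }
    tt <- stats::t.test(props, mu = 0.5)
    data.frame(cue_width = w, mean_accuracy = mean(props),
               t = unname(tt$statistic), p = tt$p.value,
               df = unname(tt$parameter), flag = NA_character_)
  })
  do.call(rbind, rows)
}

#' Monte-Carlo chance level of the absolute angular error
#'
#' Mean absolute wrapped angular difference between independent uniform
#' location guesses and uniform true centers; converges to 90 deg, the
#' chance reference against which estimator accuracy is judged.
#'
#' @param n_draws number of Monte-Carlo draws (>= 1e4).
#' @param seed integer seed.
#' @return the Monte-Carlo mean absolute angular error in degrees.
#' @export
chance_error_reference <- function(n_draws = 1e6, seed = NULL) {
  stopifnot(n_draws >= 1e4)
  with_seed(seed, {
    mean(angular_distance(stats::runif(n_draws, 0, 360),
                          stats::runif(n_draws, 0, 360)))
  })
}

#' Bonferroni-adjusted significance threshold across ROIs
#'
#' The conventional alpha divided by the number of regions tested;
#' reported alongside uncorrected p-values (0.05 / 3 ~ 0.017 for V1-V3).
#'
#' @param alpha nominal level (default 0.05).
#' @param n_rois number of regions (default 3).
#' @return the corrected threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_rois = 3L) {
  alpha / n_rois
}
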