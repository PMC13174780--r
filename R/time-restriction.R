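# Bootstrap comparison of time-restricted versus random clinical-day sampling.
#
# The clinical day holds three scheduled draws (09:00, 13:00, 17:00). Each
# bootstrap replicate resamples subjects with replacement; the restricted arm
# reads every resampled subject's replicate-mean titer at one fixed clock
# time, the random arm draws each subject's titer at a clock time chosen
# uniformly from the three. The statistic is the ratio of across-subject
# sample SDs (restricted / random); values below 1 mean fixed-time sampling
# is more precise. Replicates whose random-arm SD is zero leave the ratio
# undefined and are discarded and counted.

CLINICAL_DAY_CLOCK <- c(9, 13, 17)

#' Bootstrap the restricted-time / random-time SD ratio
#'
#' @param panel a `titer_panel` containing the clinical-day draws; of the two
#'   09:00 draws the first (elapsed hour 0) is used.
#' @param analyte analyte to analyze.
#' @param fixed_time restriction clock hour: 9, 13 or 17.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @param resample_subjects resample subjects with replacement (default);
#'   `FALSE` keeps the observed subjects and randomizes sampling times only,
#'   a sensitivity mode in which the restricted arm is constant.
#' @return object of class `restriction_result` with `sd_ratio_median`,
#'   `sd_ratio_ci` (2.5/97.5 percentiles), `pct_sd_reduction`
#'   (`100 * (1 - median)`), `n_discarded` and the call parameters.
#' @export
bootstrap_sd_ratio <- function(panel, analyte, fixed_time,
                               n_boot = 10000L, seed = 1L,
                               resample_subjects = TRUE) {
  stopifnot(inherits(panel, "titer_panel"))
  if (!fixed_time %in% CLINICAL_DAY_CLOCK) {
    stop_config(sprintf("fixed_time must be one of %s",
                        paste(CLINICAL_DAY_CLOCK, collapse = ", ")))
  }
  start <- attr(panel, "start_clock") %||% panel_start_clock()
  elapsed <- CLINICAL_DAY_CLOCK - start        # 0, 4, 8 for a 09:00 start
  sched <- attr(panel, "schedule")
  if (!all(elapsed %in% sched)) {
    stop_data("panel does not contain the clinical-day draws (09:00, 13:00, 17:00)")
  }
  means <- replicate_means(panel, analyte)
  means <- means[means$time_h %in% elapsed, ]
  ids <- sort(unique(means$participant_id))
  n <- length(ids)
  if (n < 2L) stop_data("need >= 2 subjects")

  # Y[subject, time] of replicate-mean titers at the three clinical draws
  Y <- matrix(NA_real_, n, 3,
              dimnames = list(ids, as.character(CLINICAL_DAY_CLOCK)))
  Y[cbind(match(means$participant_id, ids), match(means$time_h, elapsed))] <-
    means$titer
  fixed_col <- match(fixed_time, CLINICAL_DAY_CLOCK)

  ratios <- with_seed(seed, {
    B <- as.integer(n_boot)
    idx <- if (resample_subjects) {
      matrix(sample.int(n, n * B, replace = TRUE), n, B)
    } else {
      matrix(rep(seq_len(n), B), n, B)
    }
    tcol <- matrix(sample.int(3, n * B, replace = TRUE), n, B)
    restricted <- matrix(Y[idx, fixed_col], n, B)
    random <- matrix(Y[cbind(as.vector(idx), as.vector(tcol))], n, B)
    col_sd <- function(M) {
      mu <- colMeans(M)
      sqrt(colSums((M - rep(mu, each = n))^2) / (n - 1))
    }
    col_sd(restricted) / col_sd(random)
  })

  keep <- is.finite(ratios)
  n_disc <- sum(!keep)
  if (n_disc > length(ratios) / 2) {
    stop_data(sprintf(
      "degenerate data: %d of %d bootstrap replicates had zero random-arm SD",
      n_disc, length(ratios)))
  }
  ratios <- ratios[keep]
  med <- stats::median(ratios)
  ci <- stats::quantile(ratios, c(0.025, 0.975), names = FALSE, type = 7)

  structure(list(analyte = analyte, fixed_time = fixed_time,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 resample_subjects = resample_subjects,
                 sd_ratio_median = med, sd_ratio_ci = ci,
                 pct_sd_reduction = 100 * (1 - med),
                 n_discarded = n_disc, n_subjects = n,
                 ratios = ratios),
            class = "restriction_result")
}

#' @export
print.restriction_result <- function(x, ...) {
  cat(sprintf("<restriction_result> %s @ %d:00, %d bootstrap replicates (%d discarded)\n",
              x$analyte, x$fixed_time, x$n_boot, x$n_discarded))
  cat(sprintf("  median SD ratio (restricted/random): %.4f  [95%% CI %.4f, %.4f]\n",
              x$sd_ratio_median, x$sd_ratio_ci[1], x$sd_ratio_ci[2]))
  cat(sprintf("  SD reduction: %.1f%%\n", x$pct_sd_reduction))
  invisible(x)
}
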