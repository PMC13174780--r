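# Per-participant descriptive diurnal statistics.
#
# All operations act on a participant's replicate-averaged series over the
# day (both 09:00 draws included as distinct timepoints). The diurnal CV is
# the ordinary sample CV: 100 * sd(series, n-1 denominator) / mean(series).

#' Standardize a series to participant-specific z-scores
#'
#' Uses the sample SD (n-1). A constant series (SD 0) maps to all zeros
#' rather than NaN, so flat trajectories remain usable downstream.
#'
#' @param series numeric vector, length >= 2.
#' @return numeric vector with sample mean 0 and SD 1 (or all zeros).
#' @export
zscore_standardize <- function(series) {
  if (length(series) < 2L) stop_value("z-scoring needs at least 2 values")
  s <- stats::sd(series)
  if (s == 0) return(rep(0, length(series)))
  (series - mean(series)) / s
}

#' Daily range: maximum minus minimum over the day
#' @param series replicate-averaged titers, length >= 1.
#' @return nonnegative scalar.
#' @export
daily_range <- function(series) {
  if (!length(series)) stop_value("daily_range of an empty series")
  max(series) - min(series)
}

#' Diurnal coefficient of variation, percent
#' @param series replicate-averaged titers with positive mean.
#' @return `100 * sd(series) / mean(series)`.
#' @export
diurnal_cv <- function(series) {
  m <- mean(series)
  if (!is.finite(m) || m <= 0) stop_value("diurnal CV needs a positive mean")
  100 * stats::sd(series) / m
}

#' Fold by which a diurnal CV exceeds the laboratory inter-assay CV
#' @param diurnal_cv_pct,interassay_cv_pct percents; the inter-assay CV must
#'   be positive.
#' @return ratio `diurnal_cv_pct / interassay_cv_pct`.
#' @export
cv_fold_vs_interassay <- function(diurnal_cv_pct, interassay_cv_pct) {
  if (interassay_cv_pct <= 0) stop_value("inter-assay CV must be positive")
  if (diurnal_cv_pct < 0) stop_value("diurnal CV must be >= 0")
  diurnal_cv_pct / interassay_cv_pct
}

#' Did detection status change across the day?
#'
#' Detection is the strict comparison `titer > threshold`; a titer exactly at
#' threshold counts as not detected.
#'
#' @param series replicate-averaged titers.
#' @param threshold positive detection threshold.
#' @return `TRUE` iff the series straddles the threshold.
#' @export
detection_changed <- function(series, threshold) {
  if (threshold <= 0) stop_value("threshold must be positive")
  det <- series > threshold
  any(det) && !all(det)
}

#' Per-participant diurnal summary of a panel
#'
#' @param panel a `titer_panel`.
#' @param configs named list of [analyte_config()] supplying thresholds and
#'   inter-assay CVs.
#' @return data frame keyed by participant x analyte with `daily_range`,
#'   `diurnal_cv_pct`, `cv_fold_vs_interassay`, `detection_changed`; carries
#'   `replicate_handling = "timepoint means"` as an attribute.
#' @export
diurnal_summary <- function(panel, configs = default_analyte_configs()) {
  means <- replicate_means(panel)
  unknown <- setdiff(unique(means$analyte), names(configs))
  if (length(unknown)) {
    stop_config(sprintf("no analyte config for: %s",
                        paste(unknown, collapse = ", ")))
  }
  split_keys <- interaction(means$participant_id, means$analyte, drop = TRUE)
  rows <- lapply(split(means, split_keys), function(d) {
    cfg <- configs[[d$analyte[1]]]
    dcv <- diurnal_cv(d$titer)
    data.frame(
      participant_id = d$participant_id[1],
      analyte = d$analyte[1],
      daily_range = daily_range(d$titer),
      diurnal_cv_pct = dcv,
      cv_fold_vs_interassay = cv_fold_vs_interassay(dcv, cfg$interassay_cv_pct),
      detection_changed = detection_changed(d$titer, cfg$detection_threshold),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$analyte, out$participant_id), ]
  rownames(out) <- NULL
  attr(out, "replicate_handling") <- "timepoint means"
  out
}
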