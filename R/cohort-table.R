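# Cross-sectional cohort table: one record per participant per analyte, with
# sampling clock time rounded to the nearest hour and a strict-threshold
# detection flag.

#' Round a clock time to the nearest hour
#'
#' Minutes of 30 or more round up (round-half-up); 23:30-23:59 wrap to hour 0.
#'
#' @param sample_time character vector of `"H:MM"` clock times.
#' @return integer vector of hours.
#' @examples
#' round_time_to_hour("10:29")  # 10
#' round_time_to_hour("10:30")  # 11
#' @export
round_time_to_hour <- function(sample_time) {
  h <- clock_to_hours(sample_time)
  as.integer(floor(h + 0.5) %% 24)
}

#' Construct and validate a cross-sectional cohort table
#'
#' Populates `tod_hour` by rounding `sample_time` and `detected` by strict
#' comparison `titer > threshold`. Rows with nonpositive titers cannot enter
#' the log-scale analyses and are excluded up front; the exclusions are
#' retained in the `"exclusions"` attribute for auditing.
#'
#' @param records data frame with columns `participant_id`, `age_years`,
#'   `sample_time`, `analyte`, `titer`, and optionally `threshold` (otherwise
#'   looked up in `configs`) and `duration_years`.
#' @param configs named list of [analyte_config()] used to fill thresholds.
#' @return a `cohort_table` data frame with attributes `exclusions` (the
#'   dropped rows) and `n_excluded`.
#' @export
cohort_table <- function(records, configs = default_analyte_configs()) {
  required <- c("participant_id", "age_years", "sample_time", "analyte", "titer")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_data(sprintf("cohort is missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(records)
  df$participant_id <- as.character(df$participant_id)
  df$analyte <- as.character(df$analyte)
  df$age_years <- as.numeric(df$age_years)
  df$titer <- as.numeric(df$titer)
  if (any(!is.finite(df$age_years) | df$age_years < 0)) {
    stop_value("age_years must be nonnegative and finite")
  }

  if (!"threshold" %in% names(df)) {
    unknown <- setdiff(unique(df$analyte), names(configs))
    if (length(unknown)) {
      stop_config(sprintf("no analyte config with threshold for: %s",
                          paste(unknown, collapse = ", ")))
    }
    df$threshold <- vapply(df$analyte,
                           function(a) configs[[a]]$detection_threshold, 0)
  }
  if (any(!is.finite(df$threshold) | df$threshold <= 0)) {
    stop_value("thresholds must be positive")
  }

  key <- paste(df$participant_id, df$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])[1]
    stop_data(sprintf("duplicate (participant, analyte) record: %s",
                      gsub("\r", " / ", dup)))
  }

  df$tod_hour <- round_time_to_hour(df$sample_time)
  drop <- !is.finite(df$titer) | df$titer <= 0
  exclusions <- df[drop, , drop = FALSE]
  df <- df[!drop, , drop = FALSE]
  df$detected <- df$titer > df$threshold

  keep <- c("participant_id", "age_years", "sample_time", "tod_hour",
            "analyte", "titer", "threshold", "detected",
            intersect("duration_years", names(df)))
  df <- df[keep]
  rownames(df) <- NULL
  structure(df,
            exclusions = exclusions,
            n_excluded = nrow(exclusions),
            class = c("cohort_table", "data.frame"))
}

#' Read a cross-sectional cohort from CSV
#'
#' Accepts the long layout (an `analyte` column plus `titer`) or the wide
#' layout with one `titer_<analyte>` column per analyte, which is melted to
#' long form.
#'
#' @param path CSV file path.
#' @param configs named list of [analyte_config()] supplying thresholds.
#' @return a validated `cohort_table`.
#' @export
read_cohort <- function(path, configs = default_analyte_configs()) {
  if (!file.exists(path)) stop_data(sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        check.names = FALSE)
  if (!"analyte" %in% names(df)) {
    wide <- grep("^titer_", names(df), value = TRUE)
    if (!length(wide)) {
      stop_data("cohort needs either an 'analyte' column or titer_<analyte> columns")
    }
    base_cols <- setdiff(names(df), wide)
    long <- do.call(rbind, lapply(wide, function(cn) {
      out <- df[base_cols]
      out$analyte <- sub("^titer_", "", cn)
      out$titer <- df[[cn]]
      out
    }))
    df <- long
  }
  cohort_table(df, configs = configs)
}

#' Write a cohort table to CSV
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d records, %d participants, analytes: %s (%d excluded nonpositive)\n",
              nrow(x), length(unique(x$participant_id)),
              paste(sort(unique(x$analyte)), collapse = ", "),
              attr(x, "n_excluded") %||% 0L))
  NextMethod()
}
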