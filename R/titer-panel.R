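# Longitudinal duplicate-assay titer panel: construction, validation, I/O.
#
# The design is the 24-hour inpatient protocol: draws every 4 hours starting
# 09:00, so elapsed hours 0,4,...,24 with the 24-h draw being a second 09:00
# sample the next day. Times are stored as elapsed hours (not folded mod 24)
# so that the repeated 09:00 draw remains a distinct timepoint.

#' Default draw schedule: 7 draws at 4-h spacing starting 09:00
#' @return numeric vector of elapsed hours.
#' @export
default_schedule <- function() seq(0, 24, by = 4)

#' Clock hour at which the panel schedule starts
#' @export
panel_start_clock <- function() 9

#' Construct and validate a longitudinal titer panel
#'
#' @param records data frame with columns `participant_id`, `analyte`,
#'   `time_h` (elapsed hours since the first draw), `replicate` and `titer`.
#' @param schedule expected elapsed-hour schedule (default [default_schedule()]).
#' @param n_replicates expected replicates per timepoint (default 2).
#' @param start_clock clock hour of the first draw (default 9, i.e. 09:00).
#' @return a `titer_panel`: a validated data frame carrying the schedule,
#'   replicate count and start clock as attributes.
#' @export
titer_panel <- function(records, schedule = default_schedule(),
                        n_replicates = 2L, start_clock = panel_start_clock()) {
  required <- c("participant_id", "analyte", "time_h", "replicate", "titer")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_data(sprintf("panel is missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(records)[required]
  df$participant_id <- as.character(df$participant_id)
  df$analyte <- as.character(df$analyte)
  df$time_h <- as.numeric(df$time_h)
  df$replicate <- as.integer(df$replicate)
  df$titer <- as.numeric(df$titer)

  if (anyNA(df)) stop_data("panel contains missing values; the design allows none")
  if (any(df$titer < 0)) stop_value("panel contains negative titers")
  bad_time <- !df$time_h %in% schedule
  if (any(bad_time)) {
    stop_data(sprintf("timepoint(s) off the declared schedule: %s",
                      paste(sort(unique(df$time_h[bad_time])), collapse = ", ")))
  }
  if (!all(df$replicate %in% seq_len(n_replicates))) {
    stop_data(sprintf("replicate labels must be in 1..%d", n_replicates))
  }

  key <- paste(df$participant_id, df$analyte, df$time_h, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])[1]
    stop_data(sprintf("duplicate (participant, analyte, time, replicate) record: %s",
                      gsub("\r", " / ", dup)))
  }
  # completeness: each (participant, analyte) cell must carry the full
  # schedule x replicate grid
  cell <- paste(df$participant_id, df$analyte, sep = "\r")
  counts <- table(cell)
  expected <- length(schedule) * n_replicates
  if (any(counts != expected)) {
    off <- names(counts)[counts != expected][1]
    stop_data(sprintf(
      "incomplete design for (participant, analyte) = (%s): %d records, expected %d",
      gsub("\r", ", ", off), counts[[off]], expected))
  }
  # no duplicates + on-schedule times + in-range replicates + matching counts
  # together imply the grid is complete

  df <- df[order(df$participant_id, df$analyte, df$time_h, df$replicate), ]
  rownames(df) <- NULL
  structure(df,
            schedule = as.numeric(schedule),
            n_replicates = as.integer(n_replicates),
            start_clock = as.numeric(start_clock),
            class = c("titer_panel", "data.frame"))
}

#' Read a titer panel from CSV
#'
#' The CSV dialect is fixed: comma separator, header row, `.` decimal, UTF-8.
#'
#' @inheritParams titer_panel
#' @param path CSV file path.
#' @return a validated `titer_panel`.
#' @export
read_panel <- function(path, schedule = default_schedule(),
                       n_replicates = 2L, start_clock = panel_start_clock()) {
  if (!file.exists(path)) stop_data(sprintf("panel file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  titer_panel(df, schedule = schedule, n_replicates = n_replicates,
              start_clock = start_clock)
}

#' Write a titer panel to CSV
#' @param panel a `titer_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "titer_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Replicate-averaged titers for one participant-analyte series
#'
#' Descriptive diurnal statistics operate on the within-timepoint mean of the
#' duplicate assays.
#'
#' @param panel a `titer_panel`.
#' @param analyte analyte name; `NULL` keeps all.
#' @return data frame with `participant_id`, `analyte`, `time_h`, `titer`
#'   (replicate mean), one row per timepoint.
#' @export
replicate_means <- function(panel, analyte = NULL) {
  stopifnot(inherits(panel, "titer_panel"))
  df <- as.data.frame(panel)
  if (!is.null(analyte)) {
    df <- df[df$analyte %in% analyte, , drop = FALSE]
    if (!nrow(df)) stop_data(sprintf("analyte not present in panel: %s", analyte))
  }
  agg <- stats::aggregate(titer ~ participant_id + analyte + time_h,
                          data = df, FUN = mean)
  agg <- agg[order(agg$participant_id, agg$analyte, agg$time_h), ]
  rownames(agg) <- NULL
  agg
}

#' @export
print.titer_panel <- function(x, ...) {
  sched <- attr(x, "schedule")
  cat(sprintf(
    "<titer_panel> %d participants x %d analytes, %d timepoints (elapsed h: %s), %d replicates\n",
    length(unique(x$participant_id)), length(unique(x$analyte)),
    length(sched), paste(sched, collapse = ","), attr(x, "n_replicates")))
  NextMethod()
}
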