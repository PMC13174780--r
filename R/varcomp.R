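# Variance-components decomposition for the balanced two-level nested design
#   y_ijk = mu + b_i + u_ij + e_ijk     (subject i, timepoint j, replicate k)
# estimated by expected mean squares (method of moments):
#   sigma2_assay   = MS_error
#   sigma2_tod     = (MS_time(subject) - MS_error) / r
#   sigma2_between = (MS_subject - MS_time(subject)) / (t * r)
# Negative moment estimates are truncated to zero and flagged, never hidden.
# The decomposition runs on raw titers with the duplicate assays kept (the
# assay component is inestimable from replicate means).

#' Decompose titer variance into between-participant, time-of-day and assay
#' components
#'
#' @param panel a balanced `titer_panel` with >= 2 replicates.
#' @param analyte analyte to decompose.
#' @return object of class `variance_components` with the three variance
#'   estimates (`var_between`, `var_tod`, `var_assay`), their percent of
#'   total (`pct_*`, summing to 100), `truncated` (which components were
#'   negative before truncation) and `degenerate` (all-zero-variance input,
#'   reported as 100% between-participant by convention).
#' @export
variance_components <- function(panel, analyte) {
  stopifnot(inherits(panel, "titer_panel"))
  df <- as.data.frame(panel)
  df <- df[df$analyte == analyte, , drop = FALSE]
  if (!nrow(df)) stop_data(sprintf("analyte not present in panel: %s", analyte))

  r <- attr(panel, "n_replicates")
  if (r < 2L) stop_data("assay component is inestimable with a single replicate")
  tpts <- attr(panel, "schedule")
  t <- length(tpts)
  n <- length(unique(df$participant_id))
  # titer_panel() guarantees balance; re-check defensively
  if (nrow(df) != n * t * r) {
    stop_data("unbalanced panel: subset to a balanced design before decomposing")
  }

  y <- df$titer
  subj <- factor(df$participant_id)
  cell <- interaction(subj, factor(df$time_h), drop = TRUE)

  grand <- mean(y)
  m_subj <- tapply(y, subj, mean)
  m_cell <- tapply(y, cell, mean)
  cell_subj <- tapply(as.character(subj), cell, `[`, 1)

  ss_subject <- t * r * sum((m_subj - grand)^2)
  ss_time    <- r * sum((m_cell - m_subj[cell_subj])^2)
  ss_error   <- sum((y - m_cell[as.character(cell)])^2)

  ms_subject <- ss_subject / (n - 1)
  ms_time    <- ss_time / (n * (t - 1))
  ms_error   <- ss_error / (n * t * (r - 1))

  raw <- c(between = (ms_subject - ms_time) / (t * r),
           tod = (ms_time - ms_error) / r,
           assay = ms_error)
  truncated <- names(raw)[raw < 0]
  est <- pmax(raw, 0)

  total <- sum(est)
  degenerate <- total == 0
  pct <- if (degenerate) c(between = 100, tod = 0, assay = 0) else 100 * est / total

  structure(list(analyte = analyte,
                 var_between = est[["between"]], var_tod = est[["tod"]],
                 var_assay = est[["assay"]],
                 pct_between = pct[["between"]], pct_tod = pct[["tod"]],
                 pct_assay = pct[["assay"]],
                 ms = c(subject = ms_subject, time = ms_time, error = ms_error),
                 n_subjects = n, n_timepoints = t, n_replicates = r,
                 truncated = truncated, degenerate = degenerate),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> %s (n=%d subjects, t=%d, r=%d)\n",
              x$analyte, x$n_subjects, x$n_timepoints, x$n_replicates))
  cat(sprintf("  between-participant: %.6g  (%.2f%%)\n", x$var_between, x$pct_between))
  cat(sprintf("  time-of-day:         %.6g  (%.2f%%)\n", x$var_tod, x$pct_tod))
  cat(sprintf("  intra-assay:         %.6g  (%.2f%%)\n", x$var_assay, x$pct_assay))
  if (length(x$truncated)) {
    cat("  truncated to zero:", paste(x$truncated, collapse = ", "), "\n")
  }
  if (x$degenerate) cat("  degenerate: all variances zero; 100% between by convention\n")
  invisible(x)
}
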