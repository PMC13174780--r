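# Age x time-of-day subgroup comparisons: mean ln titers (two-group ANOVA),
# fold changes, detection rates with exact binomial intervals, chi-square
# detection comparison, and rank-correlation confounding checks.

#' Fold change implied by a difference of mean ln titers
#' @param diff_ln difference in ln units (early minus late).
#' @return `exp(diff_ln)`.
#' @examples
#' fold_change(1.25)   # 3.49 to 2 dp
#' fold_change(-0.82)  # 0.44 to 2 dp
#' @export
fold_change <- function(diff_ln) {
  if (any(!is.finite(diff_ln))) stop_value("diff_ln must be finite")
  exp(diff_ln)
}

# two-group one-way ANOVA on a numeric response; returns F and p
anova_two_group <- function(y, grp) {
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < 2L || n2 < 2L) {
    stop_data("ANOVA undefined: each subgroup needs >= 2 records")
  }
  m1 <- mean(y[grp]); m2 <- mean(y[!grp]); m <- mean(y)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- sum((y[grp] - m1)^2) + sum((y[!grp] - m2)^2)
  df2 <- n1 + n2 - 2
  if (ssw == 0) {
    # no within-group variance: identical means -> F = 0, p = 1;
    # different means -> infinitely strong evidence
    if (ssb == 0) return(list(F = 0, p = 1, df = c(1, df2)))
    return(list(F = Inf, p = 0, df = c(1, df2)))
  }
  Fst <- (ssb / 1) / (ssw / df2)
  list(F = Fst, p = stats::pf(Fst, 1, df2, lower.tail = FALSE), df = c(1, df2))
}

#' Exact (Clopper-Pearson) binomial confidence interval for a detection rate
#'
#' @param k detected count, `0 <= k <= n`.
#' @param n subgroup size, >= 1.
#' @param level confidence level (default 0.95).
#' @return list with `rate`, `lower`, `upper`.
#' @export
detection_rate_ci <- function(k, n, level = 0.95) {
  if (n < 1L) stop_value("n must be >= 1")
  if (k < 0 || k > n) stop_value("k must lie in 0..n")
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  list(rate = k / n, lower = lower, upper = upper)
}

#' Pearson chi-square comparison of two detection rates
#'
#' 2x2 table, 1 df, no continuity correction unless `correct = TRUE` (Yates).
#'
#' @param k1,n1 detected count and size of the first subgroup.
#' @param k2,n2 detected count and size of the second subgroup.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic` and `p`.
#' @export
chi_square_detection <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 < 1L || n2 < 1L) stop_value("both subgroup sizes must be >= 1")
  O <- matrix(c(k1, k2, n1 - k1, n2 - k2), 2)
  if (any(O < 0)) stop_value("counts exceed subgroup sizes")
  if (any(rowSums(O) == 0) || any(colSums(O) == 0)) {
    stop_data("chi-square undefined: a margin of the 2x2 table is zero")
  }
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  d <- abs(O - E)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties, then the Pearson correlation of ranks;
#' p from `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_check <- function(x, y) {
  if (length(x) != length(y)) stop_value("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_value("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_value("Spearman correlation undefined for constant input")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Compare early versus late sampling within an age band
#'
#' Restricts the cohort to one analyte and an age interval, splits it at a
#' sampling-hour cut (early: `tod_hour <= tod_cut`), and reports the mean ln
#' titers, their difference and fold change, the two-group ANOVA p-value, and
#' the detection comparison (rates with exact 95% intervals, chi-square p).
#' All records with positive titer enter the ln-titer comparison regardless
#' of detection status.
#'
#' @param cohort a `cohort_table`.
#' @param analyte analyte name.
#' @param age_range inclusive `c(lo, hi)` age filter (years); infinite bounds
#'   allowed.
#' @param tod_cut hour cut; early means `tod_hour <= tod_cut` (a CART
#'   threshold like 8.5 and the integer 8 are equivalent on integer hours).
#' @param response response column, default ln of `titer`.
#' @param tod_range optional `c(lo, hi)` restricting the sampling-hour window
#'   before splitting (used when a tree nests one hour split inside another).
#' @return object of class `subgroup_comparison`.
#' @export
subgroup_compare <- function(cohort, analyte, age_range, tod_cut,
                             response = NULL, tod_range = c(-Inf, Inf)) {
  df <- as.data.frame(cohort)
  df <- df[df$analyte == analyte & df$age_years >= age_range[1] &
             df$age_years <= age_range[2] &
             df$tod_hour >= tod_range[1] & df$tod_hour <= tod_range[2], ,
           drop = FALSE]
  if (!nrow(df)) stop_data("no records in the requested age band")
  early <- df$tod_hour <= tod_cut
  if (!any(early) || all(early)) {
    stop_data("time-of-day cut leaves one side empty")
  }
  y <- if (is.null(response)) log(df$titer) else df[[response]]
  aov2 <- anova_two_group(y, early)
  m_early <- mean(y[early]); m_late <- mean(y[!early])
  diff <- m_early - m_late

  k1 <- sum(df$detected[early]); n1 <- sum(early)
  k2 <- sum(df$detected[!early]); n2 <- sum(!early)
  chisq <- tryCatch(chi_square_detection(k1, n1, k2, n2),
                    daab_data_error = function(e) list(statistic = NA_real_,
                                                       p = NA_real_))

  structure(list(analyte = analyte, age_range = age_range, tod_cut = tod_cut,
                 n_early = n1, n_late = n2,
                 mean_ln_early = m_early, mean_ln_late = m_late,
                 diff = diff, fold_change = fold_change(diff),
                 anova_F = aov2$F, anova_p = aov2$p,
                 detect_early = c(list(k = k1, n = n1),
                                  detection_rate_ci(k1, n1)),
                 detect_late = c(list(k = k2, n = n2),
                                 detection_rate_ci(k2, n2)),
                 chisq_stat = chisq$statistic, chisq_p = chisq$p),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  age_txt <- sprintf("[%s, %s]",
                     format(x$age_range[1]), format(x$age_range[2]))
  cat(sprintf("<subgroup_comparison> %s, age %s, early = tod <= %g\n",
              x$analyte, age_txt, x$tod_cut))
  cat(sprintf("  mean ln titer: early %.4f (n=%d) vs late %.4f (n=%d)\n",
              x$mean_ln_early, x$n_early, x$mean_ln_late, x$n_late))
  cat(sprintf("  difference %.4f -> fold change %.2f, ANOVA p = %.4g\n",
              x$diff, x$fold_change, x$anova_p))
  cat(sprintf("  detection: %.1f%% (%.1f%%, %.1f%%) vs %.1f%% (%.1f%%, %.1f%%), chi-square p = %.4g\n",
              100 * x$detect_early$rate, 100 * x$detect_early$lower,
              100 * x$detect_early$upper, 100 * x$detect_late$rate,
              100 * x$detect_late$lower, 100 * x$detect_late$upper, x$chisq_p))
  invisible(x)
}

#' Check that diabetes duration is balanced across discovered subgroups
#'
#' Reuses the two-group ANOVA with duration as the response: a nonsignificant
#' p suggests the age x time-of-day contrast is not a duration artifact.
#'
#' @param cohort a `cohort_table` with a `duration_years` column.
#' @param subgroups data frame (or list of lists) with columns/fields
#'   `analyte`, `age_lo`, `age_hi`, `tod_cut`.
#' @return data frame with per-subgroup mean durations and ANOVA p-values.
#' @export
duration_balance_check <- function(cohort, subgroups) {
  df <- as.data.frame(cohort)
  if (!"duration_years" %in% names(df)) {
    stop_data("cohort has no duration_years column")
  }
  sg <- as.data.frame(subgroups)
  if (!nrow(sg)) stop_data("no subgroups supplied")
  rows <- lapply(seq_len(nrow(sg)), function(i) {
    s <- sg[i, ]
    sub <- df[df$analyte == s$analyte & df$age_years >= s$age_lo &
                df$age_years <= s$age_hi, , drop = FALSE]
    early <- sub$tod_hour <= s$tod_cut
    if (!nrow(sub) || !any(early) || all(early)) {
      stop_data("subgroup has an empty side; cannot test duration balance")
    }
    a <- anova_two_group(sub$duration_years, early)
    data.frame(analyte = s$analyte, age_lo = s$age_lo, age_hi = s$age_hi,
               tod_cut = s$tod_cut,
               mean_duration_early = mean(sub$duration_years[early]),
               mean_duration_late = mean(sub$duration_years[!early]),
               anova_p = a$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full subgroup-discovery report for one analyte
#'
#' Fits the depth-limited regression tree on ln titers, then turns every
#' time-of-day split into comparison rows. The age bands for a time-of-day
#' node come from the tree's age structure around it: the interval its
#' ancestor age splits impose, refined by any age thresholds the tree placed
#' *inside* that node's subtree (trees often refine age below an hour split;
#' the comparisons are still between early and late sampling within each
#' refined band, run on the raw records). The row with the largest absolute
#' mean ln difference is marked `primary`: the discovery objective is the
#' sampling-time cut creating the greatest mean difference between
#' age/time-of-day subgroups.
#'
#' @param cohort a `cohort_table`.
#' @param analyte analyte to report on.
#' @param ... passed to [fit_cart()] (growth parameters).
#' @return object of class `subgroup_report`: the `tree`, a `comparisons`
#'   list of `subgroup_comparison`s, a `table` data frame with one row per
#'   discovered (age band, hour cut) subgroup, and `primary`, the index of
#'   the greatest-mean-difference row.
#' @export
subgroup_report <- function(cohort, analyte, ...) {
  tree <- fit_cart(cohort, analyte = analyte, ...)
  # age thresholds appearing in a subtree
  subtree_age_thresholds <- function(node) {
    if (node$leaf) return(numeric())
    out <- if (node$split_var == "age_years") node$threshold else numeric()
    c(out, subtree_age_thresholds(node$left), subtree_age_thresholds(node$right))
  }

  comparisons <- list()
  walk <- function(node, age_lo, age_hi, tod_lo, tod_hi) {
    if (node$leaf) return(invisible())
    if (node$split_var == "tod_hour") {
      refine <- sort(unique(subtree_age_thresholds(node)))
      refine <- refine[refine > age_lo & refine < age_hi]
      edges <- c(age_lo, refine, age_hi)
      for (b in seq_len(length(edges) - 1)) {
        cmp <- tryCatch(
          subgroup_compare(cohort, analyte, c(edges[b], edges[b + 1]),
                           node$threshold, tod_range = c(tod_lo, tod_hi)),
          daab_error = function(e) NULL)
        if (is.null(cmp)) next
        lo <- edges[b]; hi <- edges[b + 1]
        cmp$age_label <- sprintf("%s-%s",
                                 if (is.finite(lo)) ceiling(lo) else "",
                                 if (is.finite(hi)) floor(hi) else "")
        comparisons[[length(comparisons) + 1L]] <<- cmp
      }
      walk(node$left, age_lo, age_hi, tod_lo, min(tod_hi, node$threshold))
      walk(node$right, age_lo, age_hi, max(tod_lo, node$threshold), tod_hi)
    } else {
      walk(node$left, age_lo, min(age_hi, node$threshold), tod_lo, tod_hi)
      walk(node$right, max(age_lo, node$threshold), age_hi, tod_lo, tod_hi)
    }
  }
  walk(tree$root, -Inf, Inf, -Inf, Inf)
  tab <- if (length(comparisons)) {
    do.call(rbind, lapply(comparisons, function(cmp) {
      data.frame(analyte = cmp$analyte,
                 age_lo = cmp$age_range[1], age_hi = cmp$age_range[2],
                 tod_cut = cmp$tod_cut,
                 n_early = cmp$n_early, n_late = cmp$n_late,
                 mean_ln_early = cmp$mean_ln_early,
                 mean_ln_late = cmp$mean_ln_late,
                 diff = cmp$diff, fold_change = cmp$fold_change,
                 fold_change_2dp = round(cmp$fold_change, 2),
                 anova_p = cmp$anova_p,
                 rate_early = cmp$detect_early$rate,
                 rate_early_lo = cmp$detect_early$lower,
                 rate_early_hi = cmp$detect_early$upper,
                 rate_late = cmp$detect_late$rate,
                 rate_late_lo = cmp$detect_late$lower,
                 rate_late_hi = cmp$detect_late$upper,
                 chisq_p = cmp$chisq_p,
                 stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  # primary discovery = greatest mean ln difference among the subgroups whose
  # ANOVA reaches 0.05 (only significant subgroups are reported as findings);
  # if none is significant, fall back to the greatest difference overall
  primary <- if (!is.null(tab) && nrow(tab)) {
    sig <- which(tab$anova_p < 0.05)
    if (length(sig)) sig[which.max(abs(tab$diff[sig]))] else which.max(abs(tab$diff))
  } else NA_integer_
  if (!is.null(tab) && nrow(tab)) tab$primary <- seq_len(nrow(tab)) == primary
  structure(list(analyte = analyte, tree = tree, comparisons = comparisons,
                 table = tab, primary = primary),
            class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat(sprintf("<subgroup_report> %s: %d time-of-day subgroup(s)\n",
              x$analyte, length(x$comparisons)))
  print(x$tree)
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}
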