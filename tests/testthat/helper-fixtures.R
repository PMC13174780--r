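# Fixture builders and independent oracles shared across test files.
# Oracles deliberately use different code paths (direct sums, exhaustive
# search) from the implementation they check.

# a tiny fully balanced panel built by hand
make_tiny_panel <- function(n_subjects = 3, schedule = c(0, 4, 8),
                            n_replicates = 2, titer_fun = NULL) {
  if (is.null(titer_fun)) {
    titer_fun <- function(i, t, k) 100 + 10 * i + t + 0.1 * k
  }
  grid <- expand.grid(i = seq_len(n_subjects), t = schedule,
                      k = seq_len(n_replicates))
  titer_panel(data.frame(
    participant_id = sprintf("S%02d", grid$i),
    analyte = "GADA",
    time_h = grid$t,
    replicate = grid$k,
    titer = mapply(titer_fun, grid$i, grid$t, grid$k)
  ), schedule = schedule, n_replicates = n_replicates)
}

# one-analyte panel sim config used throughout
one_analyte_cfg <- function(mesor = 100, amplitude = 0, acrophase = 12,
                            between_sd = 0, tod_sd = 0, cv = 0,
                            n_subjects = 10, seed = 1) {
  panel_sim_config(
    n_subjects = n_subjects,
    analytes = list(panel_analyte_sim("GADA", mesor, amplitude, acrophase,
                                      between_sd, tod_sd, cv)),
    seed = seed)
}

# exhaustive-search split oracle: loops over every candidate midpoint of
# every predictor and computes child SSEs by direct subsetting
oracle_best_split <- function(df, response, predictors, min_bucket = 1) {
  y <- df[[response]]
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  best <- NULL
  for (v in predictors) {
    ux <- sort(unique(df[[v]]))
    if (length(ux) < 2) next
    for (j in seq_len(length(ux) - 1)) {
      thr <- (ux[j] + ux[j + 1]) / 2
      left <- df[[v]] <= thr
      if (sum(left) < min_bucket || sum(!left) < min_bucket) next
      red <- sse(y) - sse(y[left]) - sse(y[!left])
      if (is.null(best) || red > best$reduction + 1e-10) {
        best <- list(var = v, threshold = thr, reduction = red)
      }
    }
  }
  best
}

# direct two-group ANOVA oracle via explicit SSB/SSW
oracle_anova <- function(y1, y2) {
  m <- mean(c(y1, y2))
  ssb <- length(y1) * (mean(y1) - m)^2 + length(y2) * (mean(y2) - m)^2
  ssw <- sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)
  df2 <- length(y1) + length(y2) - 2
  Fst <- ssb / (ssw / df2)
  list(F = Fst, p = pf(Fst, 1, df2, lower.tail = FALSE))
}
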