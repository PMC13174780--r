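# Variance components: frozen hand oracle, aov cross-check, equivariance,
# truncation transparency, simulation unbiasedness.

toy_322_panel <- function() {
  # 3 subjects x 2 timepoints x 2 replicates of small integers; the expected
  # mean squares were hand-computed (and cross-checked against aov):
  #   SS_subject = 200 (MS 100), SS_time(subject) = 8 (MS 8/3), SS_error = 12 (MS 2)
  #   sigma2: between = 73/3, tod = 1/3, assay = 2 -> pct 91.25 / 1.25 / 7.5
  vals <- c(8, 10, 6, 8,  12, 14, 12, 14,  1, 3, 5, 3)
  grid <- expand.grid(k = 1:2, t = c(0, 4), i = 1:3)
  titer_panel(data.frame(participant_id = sprintf("S%d", grid$i),
                         analyte = "IA", time_h = grid$t,
                         replicate = grid$k, titer = vals),
              schedule = c(0, 4), n_replicates = 2)
}

test_that("the 3x2x2 toy table matches the hand-computed EMS oracle", {
  vc <- variance_components(toy_322_panel(), "IA")
  expect_equal(vc$var_between, 73 / 3, tolerance = 1e-12)
  expect_equal(vc$var_tod, 1 / 3, tolerance = 1e-12)
  expect_equal(vc$var_assay, 2, tolerance = 1e-12)
  expect_equal(vc$pct_between, 91.25, tolerance = 1e-10)
  expect_equal(vc$pct_tod, 1.25, tolerance = 1e-10)
  expect_equal(vc$pct_assay, 7.5, tolerance = 1e-10)
  expect_equal(vc$pct_between + vc$pct_tod + vc$pct_assay, 100,
               tolerance = 1e-9)
  expect_length(vc$truncated, 0)
})

test_that("mean squares agree with an independent aov decomposition", {
  p <- gen_panel(one_analyte_cfg(mesor = 50, amplitude = 4, between_sd = 6,
                                 tod_sd = 2, cv = 5, n_subjects = 6, seed = 2))
  vc <- variance_components(p, "GADA")
  df <- as.data.frame(p)
  a <- summary(stats::aov(titer ~ factor(participant_id) +
                            factor(participant_id):factor(time_h), data = df))
  ms <- a[[1]][["Mean Sq"]]
  expect_equal(unname(vc$ms["subject"]), ms[1], tolerance = 1e-8)
  expect_equal(unname(vc$ms["time"]), ms[2], tolerance = 1e-8)
  expect_equal(unname(vc$ms["error"]), ms[3], tolerance = 1e-8)
})

test_that("degenerate inputs take the documented conventions", {
  flat <- make_tiny_panel(titer_fun = function(i, t, k) 7)
  vc <- variance_components(flat, "GADA")
  expect_true(vc$degenerate)
  expect_equal(c(vc$var_between, vc$var_tod, vc$var_assay), c(0, 0, 0))
  expect_equal(c(vc$pct_between, vc$pct_tod, vc$pct_assay), c(100, 0, 0))

  # subjects at distinct constant levels: everything is between-participant
  lvl <- make_tiny_panel(titer_fun = function(i, t, k) 10 * i)
  vc2 <- variance_components(lvl, "GADA")
  expect_equal(vc2$pct_between, 100)

  single_rep <- make_tiny_panel(n_replicates = 1)
  expect_error(variance_components(single_rep, "GADA"),
               class = "daab_data_error")
  expect_error(variance_components(flat, "nope"), class = "daab_data_error")
})

test_that("negative moment estimates are truncated and flagged, never silent", {
  # pure replicate noise: MS_time(subject) < MS_error in expectation, so the
  # tod (and often between) component goes negative before truncation
  set.seed(6)
  p <- make_tiny_panel(n_subjects = 4, schedule = c(0, 4, 8, 12),
                       titer_fun = function(i, t, k) 100 + rnorm(1, 0, 5))
  vc <- variance_components(p, "GADA")
  expect_true(length(vc$truncated) >= 1)
  expect_true(all(c(vc$var_between, vc$var_tod, vc$var_assay) >= 0))
})

test_that("scaling titers by c scales variances by c^2 and fixes percentages", {
  p <- gen_panel(one_analyte_cfg(mesor = 80, amplitude = 5, between_sd = 9,
                                 tod_sd = 3, cv = 4, n_subjects = 5, seed = 14))
  vc1 <- variance_components(p, "GADA")
  df <- as.data.frame(p); df$titer <- df$titer * 3.7
  p2 <- titer_panel(df, schedule = attr(p, "schedule"))
  vc2 <- variance_components(p2, "GADA")
  expect_equal(vc2$var_between, 3.7^2 * vc1$var_between, tolerance = 1e-9)
  expect_equal(vc2$var_tod, 3.7^2 * vc1$var_tod, tolerance = 1e-9)
  expect_equal(vc2$var_assay, 3.7^2 * vc1$var_assay, tolerance = 1e-9)
  expect_equal(vc2$pct_between, vc1$pct_between, tolerance = 1e-9)
})

test_that("estimates are unbiased on generated panels with known components", {
  # truth: between 2500, tod 900; the multiplicative assay noise at CV 2% on
  # a mesor-1000 process has variance cv^2 * E[mu^2]
  M <- 1000; bsd <- 50; tsd <- 30; cv <- 2
  true_assay <- (cv / 100)^2 * (M^2 + bsd^2 + tsd^2)
  est <- matrix(NA_real_, 500, 3)
  for (s in seq_len(500)) {
    p <- gen_panel(one_analyte_cfg(mesor = M, amplitude = 0, between_sd = bsd,
                                   tod_sd = tsd, cv = cv, n_subjects = 30,
                                   seed = s))
    vc <- variance_components(p, "GADA")
    est[s, ] <- c(vc$var_between, vc$var_tod, vc$var_assay)
  }
  expect_equal(mean(est[, 1]), bsd^2, tolerance = 0.05)
  expect_equal(mean(est[, 2]), tsd^2, tolerance = 0.05)
  expect_equal(mean(est[, 3]), true_assay, tolerance = 0.05)
})
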