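# Subgroup comparisons: fold changes, ANOVA, exact intervals, chi-square,
# Spearman, duration balance, full report.

test_that("fold change is exp of the ln difference and inverts ratios", {
  expect_equal(round(fold_change(1.25), 2), 3.49)
  expect_equal(round(fold_change(0.71), 2), 2.03)
  expect_equal(round(fold_change(-0.82), 2), 0.44)
  expect_identical(fold_change(0), 1)
  expect_error(fold_change(Inf), class = "daab_value_error")
  # FC(ln a - ln b) recovers a/b to machine precision
  set.seed(4)
  a <- rlnorm(25, 2, 1); b <- rlnorm(25, 1, 1)
  expect_equal(fold_change(log(a) - log(b)), a / b, tolerance = 1e-12)
})

test_that("subgroup comparison reproduces printed-table arithmetic and the ANOVA oracle", {
  # construct a cohort whose early/late mean ln titers are exactly 5.28/4.03
  early <- 5.28 + c(-0.5, 0, 0.5); late <- 4.03 + c(-0.4, 0, 0.4)
  df <- data.frame(
    participant_id = sprintf("P%d", 1:6),
    age_years = 10, sample_time = c(rep("08:00", 3), rep("10:00", 3)),
    analyte = "IA-2A", titer = exp(c(early, late)), threshold = 13)
  co <- cohort_table(df)
  cmp <- subgroup_compare(co, "IA-2A", c(0, 16), 8)
  expect_equal(cmp$diff, 1.25, tolerance = 1e-12)
  expect_equal(round(cmp$fold_change, 2), 3.49)
  oracle <- oracle_anova(early, late)
  expect_equal(cmp$anova_F, oracle$F, tolerance = 1e-10)
  expect_equal(cmp$anova_p, oracle$p, tolerance = 1e-10)
})

test_that("degenerate two-group ANOVA cases follow the documented conventions", {
  mk <- function(y_early, y_late) {
    n1 <- length(y_early); n2 <- length(y_late)
    cohort_table(data.frame(
      participant_id = sprintf("P%d", seq_len(n1 + n2)),
      age_years = 20,
      sample_time = c(rep("08:00", n1), rep("12:00", n2)),
      analyte = "IA", titer = exp(c(y_early, y_late)), threshold = 0.055))
  }
  # groups {1,3} vs {2,2} on the ln scale: equal means -> F = 0, p = 1
  cmp <- subgroup_compare(mk(c(1, 3), c(2, 2)), "IA", c(0, 99), 8)
  expect_identical(cmp$diff, 0)
  expect_identical(cmp$fold_change, 1)
  expect_identical(cmp$anova_F, 0)
  expect_identical(cmp$anova_p, 1)
  # identical values everywhere
  cmp2 <- subgroup_compare(mk(c(2, 2), c(2, 2)), "IA", c(0, 99), 8)
  expect_identical(cmp2$anova_F, 0)
  expect_identical(cmp2$anova_p, 1)
  # a side with < 2 records is refused
  expect_error(subgroup_compare(mk(1, c(2, 3)), "IA", c(0, 99), 8),
               class = "daab_data_error")
  expect_error(subgroup_compare(mk(c(1, 2), c(2, 3)), "IA", c(0, 99), 20),
               class = "daab_data_error")
})

test_that("a fixed 12-record cohort matches the direct SSB/SSW computation", {
  set.seed(11)
  y_early <- rnorm(5, 3, 1); y_late <- rnorm(7, 2, 1)
  co <- cohort_table(data.frame(
    participant_id = sprintf("P%d", 1:12), age_years = 30,
    sample_time = c(rep("09:00", 5), rep("13:00", 7)),
    analyte = "GADA", titer = exp(c(y_early, y_late)), threshold = 43))
  cmp <- subgroup_compare(co, "GADA", c(0, 99), 9)
  oracle <- oracle_anova(y_early, y_late)
  expect_equal(cmp$anova_F, oracle$F, tolerance = 1e-10)
  expect_equal(cmp$anova_p, oracle$p, tolerance = 1e-10)
})

test_that("exact binomial intervals hit the frozen beta-quantile oracle", {
  expect_equal(detection_rate_ci(0, 10),
               list(rate = 0, lower = 0,
                    upper = qbeta(0.975, 1, 10)))
  ci <- detection_rate_ci(10, 10)
  expect_identical(ci$rate, 1)
  expect_identical(ci$upper, 1)
  ci8 <- detection_rate_ci(8, 10)
  # frozen from the direct beta-quantile evaluation
  expect_equal(ci8$lower, 0.443904537692358, tolerance = 1e-12)
  expect_equal(ci8$upper, 0.974789273673167, tolerance = 1e-12)
  expect_error(detection_rate_ci(3, 0), class = "daab_value_error")
  expect_error(detection_rate_ci(11, 10), class = "daab_value_error")
})

test_that("chi-square matches the direct sum((O-E)^2/E) oracle", {
  eq <- chi_square_detection(10, 20, 10, 20)
  expect_identical(eq$statistic, 0)
  expect_identical(eq$p, 1)
  # frozen: the 2x2 table (29/32 vs 160/252)
  cs <- chi_square_detection(29, 32, 160, 252)
  expect_equal(cs$statistic, 9.39024766501792, tolerance = 1e-10)
  expect_equal(cs$p, 0.00218142734150046, tolerance = 1e-10)
  # group order symmetry
  sw <- chi_square_detection(160, 252, 29, 32)
  expect_equal(sw$statistic, cs$statistic, tolerance = 1e-12)
  # agreement with the standard implementation, both corrections
  ct <- chisq.test(matrix(c(29, 160, 3, 92), 2), correct = FALSE)
  expect_equal(cs$statistic, unname(ct$statistic), tolerance = 1e-10)
  ctY <- chisq.test(matrix(c(29, 160, 3, 92), 2), correct = TRUE)
  csY <- chi_square_detection(29, 32, 160, 252, correct = TRUE)
  expect_equal(csY$statistic, unname(ctY$statistic), tolerance = 1e-10)
  expect_lt(csY$statistic, cs$statistic)
  expect_error(chi_square_detection(0, 10, 0, 20), class = "daab_data_error")
})

test_that("Spearman check matches the rank-then-Pearson oracle", {
  expect_equal(spearman_check(1:10, 10:1)$rho, -1)
  expect_equal(spearman_check(1:10, 10:1)$p, 0)
  expect_equal(spearman_check(1:8, 1:8)$rho, 1)
  # frozen 10-pair tied dataset
  x <- c(3, 7, 7, 2, 9, 5, 5, 5, 10, 1)
  y <- c(12, 8, 9, 14, 4, 9, 11, 6, 3, 13)
  s <- spearman_check(x, y)
  expect_equal(s$rho, -0.898216601953221, tolerance = 1e-12)
  expect_equal(s$p, 0.000414599811011804, tolerance = 1e-10)
  expect_equal(s$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_check(rep(1, 5), 1:5), class = "daab_value_error")
  expect_error(spearman_check(1:4, 1:5), class = "daab_value_error")
})

test_that("duration balance reuses the ANOVA machinery", {
  co <- gen_cohort(cohort_sim_config(n = 300, seed = 15))
  sg <- data.frame(analyte = "IA-2A", age_lo = 0, age_hi = 17.5, tod_cut = 8.5)
  out <- duration_balance_check(co, sg)
  expect_identical(nrow(out), 1L)
  expect_true(out$anova_p >= 0 && out$anova_p <= 1)

  # identical durations everywhere -> F = 0, p = 1
  df <- as.data.frame(co); df$duration_years <- 5
  out2 <- duration_balance_check(cohort_table(df), sg)
  expect_identical(out2$anova_p, 1)

  # a cut with an empty side errors
  sg_bad <- data.frame(analyte = "IA-2A", age_lo = 0, age_hi = 17.5, tod_cut = 20)
  expect_error(duration_balance_check(co, sg_bad), class = "daab_data_error")
  expect_error(duration_balance_check(co[0, ], sg), class = "daab_data_error")
})

test_that("the full subgroup report recovers planted contrasts on a seeded cohort", {
  co <- gen_cohort(cohort_sim_config(seed = 5))
  rep <- subgroup_report(co, "IA-2A")
  expect_s3_class(rep$tree, "cart_tree")
  expect_gte(nrow(rep$table), 1L)
  # the most significant discovered subgroup reflects the planted +1.25
  best <- rep$table[which.min(rep$table$anova_p), ]
  expect_lt(best$anova_p, 0.01)
  expect_gt(best$fold_change, 2)
  expect_equal(best$fold_change, exp(best$diff), tolerance = 1e-12)
  # detection direction agrees with the titer direction for the planted effect
  expect_gt(best$rate_early, best$rate_late)
  expect_true(all(rep$table$rate_early_lo <= rep$table$rate_early))
  expect_true(all(rep$table$rate_early_hi >= rep$table$rate_early))
})
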