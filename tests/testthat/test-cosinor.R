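# Cosinor rhythmometry: exact recovery, frozen oracle, invariances, CIs.

noise_free_obs <- function(M, A, phi, t = seq(0, 24, by = 4)) {
  data.frame(participant_id = "S1", time_h = t,
             value = M + A * cos(2 * pi * (t - phi) / 24))
}

test_that("noise-free cosines are recovered exactly", {
  f <- fit_cosinor(noise_free_obs(2, 1, 0))
  expect_equal(f$mesor, 2, tolerance = 1e-10)
  expect_equal(f$amplitude, 1, tolerance = 1e-10)
  expect_equal(f$acrophase %% 24, 0, tolerance = 1e-8)
  expect_true(f$perfect_fit)
  expect_identical(zero_amplitude_test(f), 0)

  f12 <- fit_cosinor(noise_free_obs(0, 1, 12))
  expect_equal(f12$acrophase, 12, tolerance = 1e-8)
  expect_equal(f12$mesor, 0, tolerance = 1e-10)

  ci <- acrophase_ci(f12)
  expect_equal(ci$lower, 12, tolerance = 1e-6)  # zero-width at phi
  expect_equal(ci$upper, 12, tolerance = 1e-6)
})

test_that("a fixed 14-point dataset reproduces the frozen normal-equations oracle", {
  # expected values computed once by explicitly solving the normal equations
  # and the F = ((RSS0-RSS1)/2)/(RSS1/(n-3)) formula, then frozen
  t <- rep(c(0, 4, 8, 12, 16, 20, 24), 2)
  y <- c(2.1, 3.4, 2.9, 1.2, 0.3, 0.8, 1.9,
         2.4, 3.1, 2.6, 1.5, 0.1, 1.1, 2.2)
  f <- fit_cosinor(data.frame(participant_id = "S1", time_h = t, value = y))
  expect_equal(f$mesor, 1.76388888888889, tolerance = 1e-12)
  expect_equal(f$amplitude, 1.47146731169357, tolerance = 1e-12)
  expect_equal(f$acrophase, 4.80526836565404, tolerance = 1e-10)
  expect_equal(f$rss1, 0.445833333333334, tolerance = 1e-10)
  Fst <- ((f$rss0 - f$rss1) / 2) / (f$rss1 / (length(y) - 3))
  expect_equal(Fst, 164.602002670227, tolerance = 1e-9)
  expect_equal(zero_amplitude_test(f), 6.35466916163176e-09, tolerance = 1e-6)
})

test_that("degenerate designs are rejected", {
  one_t <- data.frame(participant_id = "S1", time_h = rep(4, 6),
                      value = rnorm(6))
  expect_error(fit_cosinor(one_t), class = "daab_data_error")
  two_t <- data.frame(participant_id = "S1", time_h = rep(c(0, 12), 3),
                      value = rnorm(6))
  expect_error(fit_cosinor(two_t), class = "daab_data_error")
  # n = 3: fit works, test refuses
  f3 <- fit_cosinor(data.frame(participant_id = "S1", time_h = c(0, 8, 16),
                               value = c(1, 2, 3)))
  expect_error(zero_amplitude_test(f3), class = "daab_data_error")
  # amplitude exactly zero: acrophase undefined, CI refused
  fl <- fit_cosinor(data.frame(participant_id = "S1",
                               time_h = seq(0, 24, 4),
                               value = rep(5, 7)))
  expect_identical(fl$amplitude, 0)
  expect_true(is.na(fl$acrophase))
  expect_error(acrophase_ci(fl), class = "daab_value_error")
})

test_that("time-shift equivariance and reflection invariance hold", {
  set.seed(10)
  t <- rep(seq(0, 24, by = 4), 3)
  y <- 1.4 * cos(2 * pi * (t - 7) / 24) + rnorm(length(t), 0, 0.4)
  base <- fit_cosinor(data.frame(participant_id = "S1", time_h = t, value = y))
  for (shift in c(3, 11.5, 23)) {
    sh <- fit_cosinor(data.frame(participant_id = "S1", time_h = t + shift,
                                 value = y))
    expect_equal(sh$acrophase, (base$acrophase + shift) %% 24, tolerance = 1e-10)
    expect_equal(sh$amplitude, base$amplitude, tolerance = 1e-10)
    expect_equal(sh$mesor, base$mesor, tolerance = 1e-10)
    expect_equal(sh$p_zero_amplitude, base$p_zero_amplitude, tolerance = 1e-10)
  }
  refl <- fit_cosinor(data.frame(participant_id = "S1", time_h = -t, value = y))
  expect_equal(refl$amplitude, base$amplitude, tolerance = 1e-10)
  expect_equal(refl$acrophase, (-base$acrophase) %% 24, tolerance = 1e-8)
})

test_that("clock formatting carries minutes and validates range", {
  expect_identical(hours_to_clock(9.8), "9:48")
  expect_identical(hours_to_clock(11.2), "11:12")
  expect_identical(hours_to_clock(0), "0:00")
  expect_identical(hours_to_clock(9.9999), "10:00")  # minute carry
  expect_identical(hours_to_clock(23.9999), "0:00")  # wraps past midnight
  expect_error(hours_to_clock(24), class = "daab_value_error")
  expect_error(hours_to_clock(-0.1), class = "daab_value_error")
  expect_equal(clock_to_hours("9:48"), 9.8)
})

test_that("panel-level fit recovers the generating acrophase", {
  # high signal-to-noise: amplitude 30 against tod noise sd 3
  p <- gen_panel(one_analyte_cfg(mesor = 100, amplitude = 30, acrophase = 12,
                                 between_sd = 20, tod_sd = 3, cv = 2,
                                 seed = 31))
  f <- cosinor_panel(p, "GADA")
  expect_equal(f$scale, "z-score")
  expect_equal(f$acrophase, 12, tolerance = 0.5)
  expect_lt(zero_amplitude_test(f), 1e-6)
  raw <- cosinor_panel(p, "GADA", zscore = FALSE)
  expect_equal(raw$scale, "raw")
  expect_equal(raw$amplitude, 30, tolerance = 5)  # amplitude in assay units
})

test_that("delta and subject-bootstrap intervals agree on a seeded panel", {
  p <- gen_panel(one_analyte_cfg(mesor = 100, amplitude = 12, acrophase = 10,
                                 between_sd = 15, tod_sd = 8, cv = 3,
                                 n_subjects = 12, seed = 55))
  f <- cosinor_panel(p, "GADA")
  d <- acrophase_ci(f, method = "delta")
  b <- acrophase_ci(f, method = "bootstrap", n_boot = 2000, seed = 6)
  width <- function(ci) ((ci$upper - ci$lower) %% 24)
  # intervals overlap ...
  expect_lt(max(d$lower, b$lower), min(d$upper, b$upper))
  # ... and widths agree within 30%
  expect_lt(abs(width(d) - width(b)) / width(d), 0.30)
})

test_that("a CI can straddle midnight and carries the wrap flag", {
  set.seed(8)
  t <- rep(seq(0, 24, by = 4), 4)
  y <- 0.8 * cos(2 * pi * (t - 0.5) / 24) + rnorm(length(t), 0, 1.2)
  f <- fit_cosinor(data.frame(participant_id = "S1", time_h = t, value = y))
  ci <- acrophase_ci(f)
  expect_true(ci$wraps)
  expect_gt(ci$lower, ci$upper)
})

test_that("near-zero amplitude flags the interval unreliable", {
  set.seed(13)
  t <- rep(seq(0, 24, by = 4), 3)
  y <- rnorm(length(t))
  f <- fit_cosinor(data.frame(participant_id = "S1", time_h = t, value = y))
  if (f$amplitude > 0) {
    ci <- acrophase_ci(f)
    expect_true(ci$unreliable)
  }
})
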