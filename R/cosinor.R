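# Single-component, fixed 24-hour-period cosinor rhythmometry.
#
# Model: Y(t) = M + A * cos(2*pi*(t - phi)/24), with t in clock hours.
# Fit by the classical linearization Y = M + beta*cos(w t) + gamma*sin(w t),
# w = 2*pi/24, via pooled least squares, so that
#   A   = sqrt(beta^2 + gamma^2)
#   phi = (atan2(gamma, beta) / w) mod 24     (clock time of the fitted peak).
# The population fit is applied to participant z-scored series, which removes
# each participant's mean and scale; a random intercept would be redundant
# there, and a subject-cluster bootstrap is offered for inference robust to
# residual within-subject correlation.

OMEGA24 <- 2 * pi / 24

#' Fit a 24-hour cosinor to pooled observations
#'
#' @param observations data frame with columns `participant_id` (or
#'   `participant`), `time_h` (clock hours; any real values, used modulo the
#'   24-h period) and `value` (typically participant z-scores).
#' @param analyte optional label stored on the fit.
#' @param residual_df residual degrees of freedom for the F test and the
#'   coefficient covariance; default `n - 3`. Participant z-scoring imposes
#'   one linear (centering) constraint per participant, so fits on z-scored
#'   panels use `n - g - 2` for `g` participants ([cosinor_panel()] sets
#'   this automatically); without the correction the zero-amplitude test is
#'   anti-conservative (empirical type-I error ~0.09 instead of ~0.05 at
#'   10 participants x 7 timepoints).
#' @return an object of class `cosinor_fit` with elements `mesor`,
#'   `amplitude`, `acrophase` (clock hours, `NA` when amplitude is exactly 0),
#'   `beta`, `gamma`, `p_zero_amplitude`, `perfect_fit`, `rss0`, `rss1`,
#'   `vcov_bg` (covariance of `(beta, gamma)`), `n_obs`, `n_subjects`, plus
#'   the raw observations for bootstrap reuse.
#' @export
fit_cosinor <- function(observations, analyte = NA_character_,
                        residual_df = NULL) {
  obs <- as.data.frame(observations)
  if (!"value" %in% names(obs)) stop_data("observations need a 'value' column")
  if (!"time_h" %in% names(obs)) stop_data("observations need a 'time_h' column")
  pid <- obs$participant_id %||% obs$participant %||%
    rep("pooled", nrow(obs))
  t <- as.numeric(obs$time_h)
  y <- as.numeric(obs$value)
  if (anyNA(t) || anyNA(y)) stop_data("observations contain missing values")
  if (length(unique(round(t %% 24, 10))) < 3L) {
    stop_data("cosinor needs >= 3 distinct timepoints within the 24-h cycle")
  }

  cw <- cos(OMEGA24 * t)
  sw <- sin(OMEGA24 * t)
  fit <- stats::lm(y ~ cw + sw)
  cf <- stats::coef(fit)
  beta <- unname(cf["cw"])
  gamma <- unname(cf["sw"])
  if (anyNA(c(beta, gamma))) stop_data("rank-deficient design: timepoints do not identify the rhythm")
  A <- sqrt(beta^2 + gamma^2)
  # snap numerically-zero amplitudes (flat series leave ~1e-16 residue)
  if (A <= 1e-10 * max(1, abs(cf[1]))) {
    A <- 0
    beta <- gamma <- 0
  }
  phi <- if (A == 0) NA_real_ else (atan2(gamma, beta) / OMEGA24) %% 24

  n <- length(y)
  rss1 <- sum(stats::resid(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  perfect <- rss1 < .Machine$double.eps * max(1, rss0)
  df_resid <- if (is.null(residual_df)) n - 3L else as.integer(residual_df)
  p <- if (df_resid < 1L) {
    NA_real_  # no residual df: zero_amplitude_test() will refuse
  } else if (perfect) 0 else {
    Fst <- ((rss0 - rss1) / 2) / (rss1 / df_resid)
    stats::pf(Fst, 2, df_resid, lower.tail = FALSE)
  }

  vc <- suppressWarnings(stats::vcov(fit))[c("cw", "sw"), c("cw", "sw")]
  # rescale the lm covariance (which divides RSS by n - 3) onto df_resid
  if (df_resid >= 1L && !perfect) vc <- vc * (n - 3) / df_resid
  if (perfect) vc[] <- 0

  structure(list(analyte = analyte, mesor = unname(cf[1]), amplitude = A,
                 acrophase = phi, beta = beta, gamma = gamma,
                 p_zero_amplitude = unname(p), perfect_fit = perfect,
                 rss0 = rss0, rss1 = rss1, vcov_bg = vc,
                 df_resid = df_resid,
                 n_obs = n, n_subjects = length(unique(pid)),
                 observations = data.frame(participant_id = as.character(pid),
                                           time_h = t, value = y,
                                           stringsAsFactors = FALSE)),
            class = "cosinor_fit")
}

#' Zero-amplitude F test
#'
#' Tests beta = gamma = 0 with F = ((RSS0 - RSS1)/2) / (RSS1/(n-3)).
#' A perfect fit (RSS1 = 0) reports p = 0 with the `perfect_fit` flag set on
#' the fit object.
#'
#' @param fit a `cosinor_fit`.
#' @return p-value in `[0, 1]`.
#' @export
zero_amplitude_test <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (!is.finite(fit$p_zero_amplitude)) {
    stop_data("insufficient residual degrees of freedom (n <= 3)")
  }
  fit$p_zero_amplitude
}

#' Acrophase confidence interval
#'
#' Delta-method interval on the peak clock time from the `(beta, gamma)`
#' covariance, mapped modulo 24 (`wraps = TRUE` when the interval crosses
#' midnight); alternatively a subject-cluster percentile bootstrap
#' (`method = "bootstrap"`) that resamples participants with replacement and
#' refits. When the amplitude is within 2 standard errors of zero the
#' acrophase is weakly identified and the interval is flagged `unreliable`.
#'
#' @param fit a `cosinor_fit`.
#' @param level confidence level (default 0.95).
#' @param method `"delta"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates (bootstrap method only).
#' @param seed RNG seed for the bootstrap.
#' @return list with `lower`, `upper` (clock hours), `wraps`, `unreliable`,
#'   `method`, `se` (delta method only).
#' @export
acrophase_ci <- function(fit, level = 0.95, method = c("delta", "bootstrap"),
                         n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(fit, "cosinor_fit"))
  method <- match.arg(method)
  if (!is.finite(fit$amplitude) || fit$amplitude <= 0) {
    stop_value("acrophase CI requires a positive amplitude estimate")
  }
  A2 <- fit$amplitude^2
  grad_A <- c(fit$beta, fit$gamma) / fit$amplitude
  se_A <- sqrt(drop(t(grad_A) %*% fit$vcov_bg %*% grad_A))
  unreliable <- fit$amplitude < 2 * se_A

  if (method == "delta") {
    # phi = atan2(gamma, beta)/w ; d/dbeta = -gamma/A^2, d/dgamma = beta/A^2
    g <- c(-fit$gamma / A2, fit$beta / A2) / OMEGA24
    se_phi <- sqrt(drop(t(g) %*% fit$vcov_bg %*% g))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- (fit$acrophase - z * se_phi) %% 24
    hi <- (fit$acrophase + z * se_phi) %% 24
    list(lower = lo, upper = hi, wraps = lo > hi, unreliable = unreliable,
         method = "delta", se = se_phi)
  } else {
    obs <- fit$observations
    ids <- unique(obs$participant_id)
    if (length(ids) < 2L) stop_data("subject bootstrap needs >= 2 participants")
    by_id <- split(obs, obs$participant_id)
    phis <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- sample(ids, length(ids), replace = TRUE)
        res <- do.call(rbind, by_id[take])
        f <- tryCatch(fit_cosinor(res), error = function(e) NULL)
        if (is.null(f) || !is.finite(f$acrophase)) NA_real_ else f$acrophase
      }, 0)
    })
    phis <- phis[is.finite(phis)]
    # circular percentile interval centered on the point estimate
    dev <- ((phis - fit$acrophase + 12) %% 24) - 12
    qs <- stats::quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    lo <- (fit$acrophase + qs[1]) %% 24
    hi <- (fit$acrophase + qs[2]) %% 24
    list(lower = lo, upper = hi, wraps = lo > hi, unreliable = unreliable,
         method = "bootstrap", n_boot_used = length(phis))
  }
}

#' Fit a population cosinor to a panel's z-scored series
#'
#' Convenience wrapper: replicate-averages the panel, z-scores each
#' participant's series, converts elapsed hours to clock hours, and fits.
#'
#' @param panel a `titer_panel`.
#' @param analyte analyte to fit.
#' @param zscore z-score each participant's series first (default TRUE, the
#'   population analysis); `FALSE` fits raw replicate-mean titers, in which
#'   case amplitude/MESOR are in assay units.
#' @return a `cosinor_fit` whose `scale` element is `"z-score"` or `"raw"`.
#' @export
cosinor_panel <- function(panel, analyte, zscore = TRUE) {
  means <- replicate_means(panel, analyte)
  start <- attr(panel, "start_clock") %||% panel_start_clock()
  if (zscore) {
    means$value <- stats::ave(means$titer, means$participant_id,
                              FUN = zscore_standardize)
  } else {
    means$value <- means$titer
  }
  means$time_h <- start + means$time_h   # clock hours (24-periodic use)
  g <- length(unique(means$participant_id))
  df_resid <- if (zscore) nrow(means) - g - 2L else NULL
  fit <- fit_cosinor(means[c("participant_id", "time_h", "value")],
                     analyte = analyte, residual_df = df_resid)
  fit$scale <- if (zscore) "z-score" else "raw"
  fit
}

#' @export
print.cosinor_fit <- function(x, digits = 4, ...) {
  phi_txt <- if (is.finite(x$acrophase)) {
    sprintf("%s (%.2f h)", hours_to_clock(x$acrophase), x$acrophase)
  } else "undefined (zero amplitude)"
  cat(sprintf("<cosinor_fit>%s 24-h single-component fit\n",
              if (is.na(x$analyte)) "" else paste0(" ", x$analyte)))
  cat(sprintf("  MESOR %.*g, amplitude %.*g, acrophase %s\n",
              digits, x$mesor, digits, x$amplitude, phi_txt))
  cat(sprintf("  zero-amplitude p = %.3g%s  [n=%d obs, %d subjects]\n",
              x$p_zero_amplitude, if (x$perfect_fit) " (perfect fit)" else "",
              x$n_obs, x$n_subjects))
  invisible(x)
}
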