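# Synthetic longitudinal panel generator.
#
# Generative model per analyte, subject i, timepoint j, replicate k:
#   mu_ij  = (M + b_i) + A * cos(2*pi*(c_j - phi)/24) + u_ij
#   y_ijk  = mu_ij * exp(eps_ijk),   eps ~ Normal(-s^2/2, s^2)
# with c_j the clock hour of draw j, b_i ~ N(0, between_subject_sd^2) the
# subject level, u_ij ~ N(0, tod_extra_sd^2) a non-circadian time-of-day
# disturbance shared by the duplicate assays, and multiplicative log-normal
# replicate noise with coefficient of variation assay_cv_pct (the mean
# correction keeps E[exp(eps)] = 1 so the CV is interpretable). Titers are
# clipped at a small positive floor; clip events are counted, never silent.

#' Simulation settings for one analyte of a longitudinal panel
#'
#' @param analyte analyte name.
#' @param mesor rhythm-adjusted mean M, assay units.
#' @param amplitude circadian amplitude A >= 0, assay units.
#' @param acrophase clock hour of peak, in `[0, 24)`.
#' @param between_subject_sd SD of the subject-level shift, units (>= 0).
#' @param tod_extra_sd SD of the non-circadian per-timepoint disturbance (>= 0).
#' @param assay_cv_pct replicate (intra-assay) CV, percent (>= 0).
#' @return list of class `panel_analyte_sim`.
#' @export
panel_analyte_sim <- function(analyte, mesor, amplitude, acrophase,
                              between_subject_sd, tod_extra_sd, assay_cv_pct) {
  if (amplitude < 0) stop_config("amplitude must be >= 0")
  if (between_subject_sd < 0 || tod_extra_sd < 0 || assay_cv_pct < 0) {
    stop_config("standard deviations and CVs must be >= 0")
  }
  if (acrophase < 0 || acrophase >= 24) stop_config("acrophase must lie in [0, 24)")
  structure(list(analyte = analyte, mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase, between_subject_sd = between_subject_sd,
                 tod_extra_sd = tod_extra_sd, assay_cv_pct = assay_cv_pct),
            class = "panel_analyte_sim")
}

#' Panel simulation configuration
#'
#' Defaults mirror the inpatient diurnal-variation design: 10 participants,
#' draws every 4 h from 09:00 over 24 h (7 timepoints, the last a second
#' 09:00), duplicate assays, five islet autoantibodies whose between-subject
#' spread dominates the circadian and assay components.
#'
#' @param n_subjects number of participants.
#' @param schedule elapsed-hour draw schedule.
#' @param n_replicates replicates per timepoint.
#' @param analytes list of [panel_analyte_sim()] settings.
#' @param start_clock clock hour of the first draw.
#' @param clip_floor positive floor applied after noise (log-safety).
#' @param seed integer seed; fixed seed gives a bit-reproducible panel.
#' @return list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_subjects = 10L,
                             schedule = default_schedule(),
                             n_replicates = 2L,
                             analytes = default_panel_analytes(),
                             start_clock = panel_start_clock(),
                             clip_floor = 1e-6,
                             seed = 1L) {
  if (n_subjects < 1L) stop_config("n_subjects must be >= 1")
  if (n_replicates < 1L) stop_config("n_replicates must be >= 1")
  if (clip_floor <= 0) stop_config("clip_floor must be positive")
  if (inherits(analytes, "panel_analyte_sim")) analytes <- list(analytes)
  nms <- vapply(analytes, `[[`, "", "analyte")
  names(analytes) <- nms
  structure(list(n_subjects = as.integer(n_subjects), schedule = schedule,
                 n_replicates = as.integer(n_replicates), analytes = analytes,
                 start_clock = start_clock, clip_floor = clip_floor,
                 seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Default per-analyte panel simulation settings
#'
#' Chosen so that between-subject differences dominate total variation, the
#' circadian amplitudes are modest, and intra-assay noise is a mid-single-digit
#' to ~8% CV, matching the qualitative structure of radiobinding titers in
#' established type 1 diabetes.
#' @return named list of [panel_analyte_sim()].
#' @export
default_panel_analytes <- function() {
  list(
    panel_analyte_sim("GADA",   mesor = 120, amplitude = 8,   acrophase = 10,
                      between_subject_sd = 70,  tod_extra_sd = 6,
                      assay_cv_pct = 8),
    panel_analyte_sim("IA",     mesor = 12,  amplitude = 2.5, acrophase = 13,
                      between_subject_sd = 7,   tod_extra_sd = 1.5,
                      assay_cv_pct = 8),
    panel_analyte_sim("IA-2A",  mesor = 25,  amplitude = 1.5, acrophase = 11,
                      between_subject_sd = 14,  tod_extra_sd = 1.2,
                      assay_cv_pct = 8),
    panel_analyte_sim("ZnT8RA", mesor = 3,   amplitude = 0.8, acrophase = 12,
                      between_subject_sd = 1.8, tod_extra_sd = 0.3,
                      assay_cv_pct = 8),
    panel_analyte_sim("ZnT8WA", mesor = 2.2, amplitude = 0.6, acrophase = 12,
                      between_subject_sd = 1.3, tod_extra_sd = 0.25,
                      assay_cv_pct = 8)
  )
}

#' Generate a synthetic longitudinal titer panel
#'
#' @param config a [panel_sim_config()].
#' @return a validated `titer_panel`; the number of floor-clipped titers is
#'   recorded in the `"n_clipped"` attribute.
#' @export
gen_panel <- function(config = panel_sim_config()) {
  stopifnot(inherits(config, "panel_sim_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    sched <- config$schedule
    r <- config$n_replicates
    t_clock <- config$start_clock + sched
    ids <- sprintf("S%02d", seq_len(n))
    n_clipped <- 0L
    parts <- lapply(config$analytes, function(a) {
      b_i <- stats::rnorm(n, 0, a$between_subject_sd)
      circ <- a$amplitude * cos(2 * pi * (t_clock - a$acrophase) / 24)
      u_ij <- matrix(stats::rnorm(n * length(sched), 0, a$tod_extra_sd),
                     nrow = n)
      mu <- outer(b_i + a$mesor, circ, `+`) + u_ij        # n x t
      s <- sqrt(log1p((a$assay_cv_pct / 100)^2))
      eps <- array(stats::rnorm(n * length(sched) * r, -s^2 / 2, s),
                   dim = c(n, length(sched), r))
      if (a$assay_cv_pct == 0) eps[] <- 0
      y <- as.vector(array(mu, dim = c(n, length(sched), r)) * exp(eps))
      clip <- y < config$clip_floor
      n_clipped <<- n_clipped + sum(clip)
      y[clip] <- config$clip_floor
      data.frame(
        participant_id = rep(ids, times = length(sched) * r),
        analyte = a$analyte,
        time_h = rep(rep(sched, each = n), times = r),
        replicate = rep(seq_len(r), each = n * length(sched)),
        titer = y,
        stringsAsFactors = FALSE)
    })
    panel <- titer_panel(do.call(rbind, parts), schedule = sched,
                         n_replicates = r, start_clock = config$start_clock)
    attr(panel, "n_clipped") <- n_clipped
    attr(panel, "sim_config") <- config
    panel
  })
}
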