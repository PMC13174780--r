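#' Assay configuration for one analyte
#'
#' Bundles the detection threshold and the laboratory QC coefficients of
#' variation used downstream: the inter-assay CV is the reference against
#' which diurnal CVs are compared, and the intra-assay CV parameterizes the
#' replicate noise of the synthetic generator. Thresholds and CVs are assay
#' properties supplied by the measuring laboratory, never estimated here.
#'
#' @param analyte analyte name, e.g. `"GADA"`.
#' @param detection_threshold positivity threshold in assay units (> 0).
#' @param interassay_cv_pct inter-assay (between-run) QC CV, percent (> 0).
#' @param intraassay_cv_pct intra-assay (within-run) CV, percent (> 0).
#' @return an object of class `analyte_config`.
#' @export
analyte_config <- function(analyte, detection_threshold,
                           interassay_cv_pct, intraassay_cv_pct) {
  if (!is.character(analyte) || length(analyte) != 1L || !nzchar(analyte)) {
    stop_config("'analyte' must be a non-empty string")
  }
  for (nm in c("detection_threshold", "interassay_cv_pct", "intraassay_cv_pct")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_config(sprintf("'%s' must be a single positive number", nm))
    }
  }
  structure(
    list(analyte = analyte,
         detection_threshold = as.numeric(detection_threshold),
         interassay_cv_pct = as.numeric(interassay_cv_pct),
         intraassay_cv_pct = as.numeric(intraassay_cv_pct)),
    class = "analyte_config"
  )
}

#' Default synthetic analyte configurations
#'
#' Intra-assay CVs near threshold are the published radiobinding-assay values
#' (GADA 22.94, IA-2A 29.50, IA 22.23, ZnT8RA 21.02, ZnT8WA 20.38 percent).
#' Detection thresholds and inter-assay CVs are *synthetic stand-ins* chosen
#' to give realistic positivity rates in the simulated cohorts; real analyses
#' must supply their laboratory's values.
#'
#' @return named list of [analyte_config()] objects.
#' @export
default_analyte_configs <- function() {
  cfgs <- list(
    analyte_config("GADA",   detection_threshold = 43,
                   interassay_cv_pct = 15, intraassay_cv_pct = 22.94),
    analyte_config("IA",     detection_threshold = 0.055,
                   interassay_cv_pct = 12, intraassay_cv_pct = 22.23),
    analyte_config("IA-2A",  detection_threshold = 13,
                   interassay_cv_pct = 14, intraassay_cv_pct = 29.50),
    analyte_config("ZnT8RA", detection_threshold = 0.012,
                   interassay_cv_pct = 15, intraassay_cv_pct = 21.02),
    analyte_config("ZnT8WA", detection_threshold = 0.012,
                   interassay_cv_pct = 15, intraassay_cv_pct = 20.38),
    analyte_config("ZnT8A",  detection_threshold = 0.012,
                   interassay_cv_pct = 15, intraassay_cv_pct = 21.02)
  )
  names(cfgs) <- vapply(cfgs, `[[`, "", "analyte")
  cfgs
}

#' Read analyte configurations from a YAML file
#'
#' Expects a top-level `analytes:` list whose entries carry `analyte`,
#' `detection_threshold`, `interassay_cv_pct`, `intraassay_cv_pct`.
#'
#' @param path YAML file path.
#' @return named list of [analyte_config()] objects.
#' @export
read_analyte_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  entries <- raw$analytes %||% raw
  cfgs <- lapply(entries, function(e) {
    analyte_config(e$analyte, e$detection_threshold,
                   e$interassay_cv_pct, e$intraassay_cv_pct)
  })
  names(cfgs) <- vapply(cfgs, `[[`, "", "analyte")
  cfgs
}

#' @export
print.analyte_config <- function(x, ...) {
  cat(sprintf("<analyte_config> %s: threshold %g, inter-assay CV %g%%, intra-assay CV %g%%\n",
              x$analyte, x$detection_threshold,
              x$interassay_cv_pct, x$intraassay_cv_pct))
  invisible(x)
}
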