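# Internal helpers: error classes, seed handling, clock-time parsing.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_daab <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "daab_error")))
}

stop_config <- function(msg, ...) stop_daab(msg, "daab_config_error", ...)
stop_data   <- function(msg, ...) stop_daab(msg, "daab_data_error", ...)
stop_value  <- function(msg, ...) stop_daab(msg, "daab_value_error", ...)

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so library code never
#' perturbs the global RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' 32-bit FNV-1a hash of a string (pure R, exact in doubles)
#' @noRd
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    # xor touches only the low byte since b < 256
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    # modular multiply split into 16-bit halves to stay exact in doubles
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 2^32
  }
  h
}

#' Derive a per-stage RNG substream seed from a run-level seed
#'
#' Keeps derived seeds in `[0, 2^31)` so they are valid R integers.
#' @param seed run-level integer seed.
#' @param stage stage label, e.g. `"simulate_panel"`.
#' @return integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  as.integer(fnv1a32(paste0(stage, "#", format(seed, scientific = FALSE))) %% 2^31)
}

#' Parse "H:MM" / "HH:MM" clock time to decimal hours
#'
#' @param x character vector of clock times.
#' @return numeric hours in `[0, 24)`.
#' @export
clock_to_hours <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop_value(sprintf("unparseable clock time(s): %s",
                       paste(unique(x[bad]), collapse = ", ")))
  }
  hh <- as.numeric(vapply(m, `[`, "", 2L))
  mm <- as.numeric(vapply(m, `[`, "", 3L))
  out_of_range <- hh > 23 | mm > 59
  if (any(out_of_range)) {
    stop_value(sprintf("clock time(s) outside 00:00-23:59: %s",
                       paste(unique(x[out_of_range]), collapse = ", ")))
  }
  hh + mm / 60
}

#' Format decimal hours as a clock string
#'
#' Minutes are rounded; 60 carries to the next hour, and a carry past
#' midnight wraps to "0:00".
#' @param h numeric hours in `[0, 24)`.
#' @return character `"H:MM"`.
#' @examples
#' hours_to_clock(9.8)   # "9:48"
#' hours_to_clock(11.2)  # "11:12"
#' @export
hours_to_clock <- function(h) {
  if (any(!is.finite(h) | h < 0 | h >= 24)) {
    stop_value("hours must lie in [0, 24)")
  }
  hh <- floor(h)
  mm <- round(60 * (h - hh))
  carry <- mm >= 60
  hh[carry] <- hh[carry] + 1
  mm[carry] <- 0
  hh <- hh %% 24
  sprintf("%d:%02d", hh, mm)
}
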