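# Internal helpers shared across modules.

# Calendar origin used when simulated clock-minutes are rendered as timestamps.
SIM_ORIGIN <- as.POSIXct("2020-11-01 00:00:00", tz = "UTC")

MINUTES_PER_DAY <- 1440

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library functions do not
#' perturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Derive a vector of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Round half away from zero
#'
#' The rounding convention used at the reporting boundary for percentages;
#' all internal arithmetic stays at full precision.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

minutes_to_ts <- function(min, origin = SIM_ORIGIN) {
  as.POSIXct(round(as.numeric(min) * 60), origin = origin, tz = "UTC")
}

ts_to_minutes <- function(ts, origin = SIM_ORIGIN) {
  as.numeric(difftime(ts, origin, units = "mins"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}
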