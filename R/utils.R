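# Small shared numeric helpers.

#' Round half away from zero
#'
#' Commercial rounding to `digits` decimal places: exact halves round up
#' (for positive values), unlike [base::round()]'s round-half-even.  Used
#' for all printed summary statistics so that, e.g., a mean of 3.825
#' prints as 3.83.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Truncate to a fixed number of decimal places
#'
#' Drops (never rounds) digits beyond `digits` decimal places.  Some
#' published percentage tables are truncated rather than rounded
#' (e.g. 60/137 = 43.795...% printed as 43.79); this reproduces that
#' convention when requested.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places kept (default 2).
#' @return Truncated numeric vector.
#' @export
trunc_digits <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 1e-9) / p
}

# Apply the configured rounding mode ("round" = half-up, "truncate").
round_mode <- function(x, digits = 2, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "round") round_half_up(x, digits) else trunc_digits(x, digits)
}

# Deterministic per-replicate substream seed derived from (seed, r) so that
# increasing the replicate count never reshuffles earlier replicates.
# Multiplier from the classic Marsaglia congruential generator; modulus keeps
# the result a valid 32-bit R seed.
substream_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(r) * 12345) %% 2147483647)
}

# stopifnot() with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

.datatable.aware <- TRUE
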