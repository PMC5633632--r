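# internal helpers shared across modules

# typed conditions: every user-facing failure is one of these three classes,
# all inheriting "matchrisk_error" so callers can catch the family.
stop_schema <- function(msg, ...) {
  abort(msg, class = c("matchrisk_schema_error", "matchrisk_error"), ...)
}
stop_referential <- function(msg, ...) {
  abort(msg, class = c("matchrisk_referential_error", "matchrisk_error"), ...)
}
stop_validation <- function(msg, ...) {
  abort(msg, class = c("matchrisk_validation_error", "matchrisk_error"), ...)
}

# round half away from zero (base round() is half-to-even, which is wrong for
# reporting percentage likelihoods such as 30.5 -> 31)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# derive a reproducible child seed (< 2^31) from a master seed and a stream id
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009) %% 2147483629) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_date <- function(x) inherits(x, "Date")

assert_date_scalar <- function(x, what) {
  if (!is_date(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("`%s` must be a single non-missing Date", what))
  }
  invisible(x)
}
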