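# internal helpers shared across modules

# round half away from zero (base round() is half-to-even, which does not
# match the integer-percent presentation convention used in the reports)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

expit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (integer && x != floor(x))
    stop_field(field, "must be an integer")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must lie in %s%s, %s%s",
                              if (open_lower) "(" else "[", format(lower),
                              format(upper), if (open_upper) ")" else "]"))
  invisible(x)
}
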