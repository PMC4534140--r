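stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside its admissible range", name, x)
  as.numeric(x)
}

maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(check_count(seed, "seed", min = -.Machine$integer.max))
  invisible(NULL)
}

# Round half away from zero to `digits` decimals (presentation convention for
# descriptive fractions; base round() is half-to-even).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
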