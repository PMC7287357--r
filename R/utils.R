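# internal argument checks shared across modules

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its valid range", name, x),
         call. = FALSE)
  invisible(x)
}

.check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower)
    stop(sprintf("'%s' must be an integer >= %d", name, lower), call. = FALSE)
  as.integer(x)
}

# set the RNG deterministically when a seed is supplied
.maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("'seed' must be a single integer", call. = FALSE)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# derive per-stage seeds from one master seed, kept inside 32-bit range
.derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483587L
}

.skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
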