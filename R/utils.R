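# Internal helpers shared across modules.

# Trapezoidal area under y(x) on an ordered grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Discount weight at time t (weeks) for an annual rate, annual compounding
# mapped onto the weekly scale: v(t) = (1 + r)^(-t/52).
discount_weight <- function(t_weeks, rate) {
  (1 + rate)^(-t_weeks / 52)
}

# Evaluate code with a temporary RNG state so library internals (multi-start
# jitter, synthetic fixtures) never disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Cheap deterministic content hash (polynomial rolling hash mod 2^31-1),
# used only for run provenance, not for security.
content_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% m
  sprintf("%08x", as.integer(h))
}

# stopifnot with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
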