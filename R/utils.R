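# Small numeric helpers shared across modules.

# First index of the maximum / minimum (ties: earliest index wins).
which_max1 <- function(x) which.max(x)
which_min1 <- function(x) which.min(x)

# Indices of strict local maxima / minima of a numeric vector.
# Plateaus: the first sample of a plateau that is higher (lower) than both
# non-plateau neighbours counts as the extremum.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # collapse zero runs: sign of next nonzero difference
  s <- sign(d)
  for (i in seq.int(length(s) - 1L, 1L)) if (s[i] == 0) s[i] <- s[i + 1L]
  idx <- which(diff(s) < 0) + 1L
  idx[idx > 1L & idx < n]
}

local_minima <- function(x) local_maxima(-x)

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

rms <- function(x) sqrt(mean(x^2))

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` runs the expression as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed_if(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
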