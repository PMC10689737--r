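# Independent brute-force oracles and fixture builders. These deliberately
# use naive loop implementations, independent of the package's vectorized
# code paths.

# ibi_series tibble from a vector of interval values (ms)
ibis_from_values <- function(v) {
  bt <- c(0, cumsum(v) / 1000)
  out <- tibble::tibble(beat_time_s = bt, ibi_ms = c(v, NA_real_))
  class(out) <- c("ibi_series", class(out))
  out
}

# sample entropy by explicit template counting, O(n^2)
sampen_brute <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  nt <- n - m
  a <- 0; b <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        b <- b + 1
        if (abs(x[i + m] - x[j + m]) <= r) a <- a + 1
      }
    }
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# PRSA averaged waveform by explicit per-anchor window stacking
prsa_waveform_brute <- function(x, type = c("dec", "acc"), wing = 50) {
  type <- match.arg(type)
  n <- length(x)
  anchors <- c()
  for (i in 2:n) {
    if (type == "dec" && x[i] > x[i - 1]) anchors <- c(anchors, i)
    if (type == "acc" && x[i] < x[i - 1]) anchors <- c(anchors, i)
  }
  anchors <- anchors[anchors > wing & anchors + wing - 1 <= n]
  if (!length(anchors)) return(NULL)
  mat <- matrix(NA_real_, 2 * wing, length(anchors))
  for (j in seq_along(anchors)) {
    mat[, j] <- x[(anchors[j] - wing):(anchors[j] + wing - 1)]
  }
  rowMeans(mat)
}

# heart rate fragmentation indices by explicit run enumeration
hrf_brute <- function(x) {
  s <- sign(diff(x))
  m <- length(s)
  n <- length(x)
  # inflections: strict sign flips between consecutive nonzero increments
  pip <- 0
  for (i in 2:m) if (s[i] * s[i - 1] < 0) pip <- pip + 1
  # segments: walk the sign sequence; zeros are isolated length-1 segments
  seg_lengths <- c()
  i <- 1
  while (i <= m) {
    if (s[i] == 0) {
      seg_lengths <- c(seg_lengths, 1L)
      i <- i + 1
    } else {
      j <- i
      while (j < m && s[j + 1] == s[i]) j <- j + 1
      seg_lengths <- c(seg_lengths, j - i + 1L)
      i <- j + 1
    }
  }
  nz_lengths <- c()
  i <- 1
  while (i <= m) {
    if (s[i] != 0) {
      j <- i
      while (j < m && s[j + 1] == s[i]) j <- j + 1
      nz_lengths <- c(nz_lengths, j - i + 1L)
      i <- j + 1
    } else i <- i + 1
  }
  # alternation runs: maximal stretches of consecutive strict flips
  alt_total <- 0
  i <- 2
  while (i <= m) {
    if (s[i] * s[i - 1] < 0) {
      j <- i
      while (j < m && s[j + 1] * s[j] < 0) j <- j + 1
      run_incr <- (j - i + 1) + 1   # q flips span q+1 increments
      if (run_incr >= 4) alt_total <- alt_total + run_incr
      i <- j + 1
    } else i <- i + 1
  }
  list(
    PIP = 100 * pip / n,
    PSS = 100 * sum(seg_lengths[seg_lengths < 3]) / m,
    PAS = 100 * alt_total / m,
    IALS = if (length(nz_lengths)) 1 / mean(nz_lengths) else NA_real_
  )
}

# symmetric triangular pulse with IT at 0 s, SP at apex_s, FT at 2*apex_s
triangle_pulse <- function(fs = 32, apex_s = 0.5, amp = 1) {
  n_half <- round(apex_s * fs)
  x <- c(seq(0, amp, length.out = n_half + 1),
         seq(amp, 0, length.out = n_half + 1)[-1])
  pulses <- tibble::tibble(
    pulse_idx = 1L, IT = 1L, SP = n_half + 1L, FT = length(x), valid = TRUE
  )
  attr(pulses, "fs") <- fs
  class(pulses) <- c("pulse_set", class(pulses))
  list(x = x, pulses = pulses, fs = fs)
}

# noiseless single-subject record with all stochastic elements disabled
noiseless_params <- function(group = "A", ...) {
  cohort_params(group, noise_sd = 0, artifact_rate = 0, wander_amplitude = 0,
                ...)
}
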