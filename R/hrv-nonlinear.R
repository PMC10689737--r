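#' Poincare-plot features
#'
#' From the scatter of each IBI against its successor: `SD1` (width,
#' short-term variability) is the root-mean-square of the successive
#' differences divided by sqrt(2), making the identity
#' `SD1 = RMSSD / sqrt(2)` exact; `SD2` (length, long-term variability) is
#' the population SD of `(x_i + x_{i+1}) / sqrt(2)`; `S = pi * SD1 * SD2`
#' is the fitted-ellipse area.
#'
#' @param ibis An `ibi_series` with `valid` flags.
#' @return One-row tibble `SD1`, `SD2`, `SD1_SD2`, `S` (ms, ms, -, ms^2).
#' @export
poincare <- function(ibis) {
  out <- tibble::tibble(SD1 = NA_real_, SD2 = NA_real_, SD1_SD2 = NA_real_,
                        S = NA_real_)
  pairs <- successive_pairs(ibis)
  if (length(pairs) < 3) return(out)
  x1 <- ibis$ibi_ms[pairs]
  x2 <- ibis$ibi_ms[pairs + 1L]
  out$SD1 <- rms(x2 - x1) / sqrt(2)
  out$SD2 <- sd_pop((x1 + x2) / sqrt(2))
  out$S <- pi * out$SD1 * out$SD2
  if (out$SD2 > 0) out$SD1_SD2 <- out$SD1 / out$SD2
  out
}

#' Short-term detrended fluctuation analysis exponent
#'
#' Standard DFA: the mean-centred IBI series is integrated; for each box
#' size n in 4..16 beats the integrated profile is split into
#' non-overlapping boxes, each box is linearly detrended and the
#' root-mean-square residual F(n) computed; `alpha1` is the slope of
#' log F(n) on log n. Uncorrelated noise gives alpha1 near 0.5, strongly
#' persistent series exceed 1.
#'
#' @param ibis An `ibi_series` with `valid` flags (or a plain numeric
#'   vector of intervals).
#' @param box_range Box sizes in beats.
#' @param min_beats Minimum number of valid IBIs required.
#' @return `alpha1` (dimensionless), or `NA` if too few beats.
#' @export
dfa_alpha1 <- function(ibis, box_range = 4:16, min_beats = 100) {
  x <- if (is.numeric(ibis)) ibis else ibis$ibi_ms[ibis$valid]
  if (length(x) < min_beats) return(NA_real_)
  y <- cumsum(x - mean(x))
  n_tot <- length(y)
  fn <- vapply(box_range, function(n) {
    n_box <- n_tot %/% n
    if (n_box < 1) return(NA_real_)
    res2 <- 0
    k <- seq_len(n)
    for (b in seq_len(n_box)) {
      seg <- y[((b - 1L) * n + 1L):(b * n)]
      fit <- stats::lm.fit(cbind(1, k), seg)
      res2 <- res2 + sum(fit$residuals^2)
    }
    sqrt(res2 / (n_box * n))
  }, numeric(1))
  ok <- is.finite(fn) & fn > 0
  if (sum(ok) < 3) return(NA_real_)
  unname(stats::coef(stats::lm(log(fn[ok]) ~ log(box_range[ok])))[2])
}

#' Sample entropy
#'
#' `SampEn = -ln(A / B)` where `B` counts pairs of length-`m` templates
#' within Chebyshev distance `r` of each other and `A` the pairs that remain
#' within `r` at length `m + 1`. Self-matches are excluded. `r` defaults to
#' `r_factor` times the series SD; a zero-variance series (degenerate `r`)
#' or `A = 0` yields `NA`.
#'
#' @param x Numeric series (for HRV use, the 4-Hz resampled tachogram).
#' @param m Template length.
#' @param r_factor Tolerance as a multiple of `sd(x)`.
#' @param min_points Minimum series length.
#' @return Sample entropy (dimensionless) or `NA`.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, min_points = 100) {
  n <- length(x)
  if (n < min_points) return(NA_real_)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  r <- r_factor * s

  # close[i, j] <=> |x_i - x_j| <= r ; template matches are running ANDs of
  # diagonals, so count via shifted logical matrices
  close_m <- abs(outer(x, x, "-")) <= r
  n_m <- n - m       # number of (m+1)-length templates
  match_m <- matrix(TRUE, n_m, n_m)
  for (k in 0:(m - 1)) {
    match_m <- match_m & close_m[(1:n_m) + k, (1:n_m) + k]
  }
  match_m1 <- match_m & close_m[(1:n_m) + m, (1:n_m) + m]
  # exclude self-matches; count unordered pairs
  b_count <- (sum(match_m) - n_m) / 2
  a_count <- (sum(match_m1) - n_m) / 2
  if (b_count == 0 || a_count == 0) return(NA_real_)
  -log(a_count / b_count)
}
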