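# Frequency-domain HRV: the IBI tachogram is resampled onto an even 4-Hz
# grid by cubic interpolation (standard HRV practice for unevenly sampled
# beat series), then a Welch PSD is computed and integrated over the
# conventional bands.

#' Resample an IBI tachogram onto an even grid
#'
#' @param beats Tibble `beat_time_s`, `ibi_ms` (e.g. from
#'   [interpolate_ontime()]).
#' @param fs_out Output grid rate, Hz.
#' @return Tibble `time_s`, `ibi_ms` on the even grid.
#' @export
resample_tachogram <- function(beats, fs_out = 4) {
  ok <- !is.na(beats$ibi_ms)
  t <- beats$beat_time_s[ok]
  y <- beats$ibi_ms[ok]
  if (length(t) < 4) stop("too few beats to resample", call. = FALSE)
  grid <- seq(t[1], t[length(t)], by = 1 / fs_out)
  f <- stats::splinefun(t, y, method = "fmm")
  tibble::tibble(time_s = grid, ibi_ms = f(grid))
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-removed segments of `nperseg` samples with 50%
#' overlap, averaged one-sided periodograms. If the series is shorter than
#' one window, the window shrinks to the series length.
#'
#' @param x Evenly sampled series.
#' @param fs Sampling rate of `x`, Hz.
#' @param nperseg Segment length in samples.
#' @return Tibble `f_hz`, `psd` (units of `x` squared per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = length(x)) {
  n <- length(x)
  nper <- min(nperseg, n)
  step <- max(1L, floor(nper / 2))
  starts <- seq.int(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- fs * sum(w^2)
  acc <- NULL
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / scale
    acc <- if (is.null(acc)) p else acc + p
  }
  p <- acc / length(starts)
  half <- seq_len(floor(nper / 2) + 1L)
  p <- p[half]
  # one-sided: double everything except DC (and Nyquist for even nper)
  dbl <- rep(2, length(half)); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[length(half)] <- 1
  tibble::tibble(f_hz = (half - 1L) * fs / nper, psd = p * dbl)
}

#' Frequency-domain HRV features
#'
#' Band powers from the Welch PSD of the 4-Hz resampled IBI tachogram,
#' integrated by the trapezoidal rule: very low frequency (VLF, 0-0.04 Hz),
#' low frequency (LF, 0.04-0.15 Hz) and high frequency (HF, 0.15-0.4 Hz),
#' all in ms^2; normalized powers `LFnu = LF/(LF+HF)`,
#' `HFnu = HF/(LF+HF)`; and the LF/HF ratio. Welch windows are 5 min with
#' 50% overlap (for the package's 5-min segments this is a single window).
#' When total LF+HF power is numerically zero the normalized powers and the
#' ratio are undefined and returned as `NA`.
#'
#' @param beats Gap-filled beat series (see [interpolate_ontime()]).
#' @param fs_resample Tachogram grid rate, Hz.
#' @param window_s Welch window length, s.
#' @return One-row tibble `VLF`, `LF`, `HF`, `LFnu`, `HFnu`, `LF_HF`.
#' @export
frequency_domain <- function(beats, fs_resample = 4, window_s = 300) {
  out <- tibble::tibble(VLF = NA_real_, LF = NA_real_, HF = NA_real_,
                        LFnu = NA_real_, HFnu = NA_real_, LF_HF = NA_real_)
  usable <- attr(beats, "usable")
  if (!is.null(usable) && !usable) return(out)
  grid <- tryCatch(resample_tachogram(beats, fs_resample),
                   error = function(e) NULL)
  if (is.null(grid) || nrow(grid) < 4 * 60 * fs_resample) return(out)

  psd <- welch_psd(grid$ibi_ms, fs_resample,
                   nperseg = round(window_s * fs_resample))
  band_power <- function(lo, hi) {
    sel <- psd$f_hz >= lo & psd$f_hz <= hi
    if (sum(sel) < 2) return(0)
    pracma::trapz(psd$f_hz[sel], psd$psd[sel])
  }
  out$VLF <- band_power(0, 0.04)
  out$LF <- band_power(0.04, 0.15)
  out$HF <- band_power(0.15, 0.4)
  tot <- out$LF + out$HF
  if (is.finite(tot) && tot > .Machine$double.eps * 100) {
    out$LFnu <- out$LF / tot
    out$HFnu <- out$HF / tot
    if (out$HF > 0) out$LF_HF <- out$LF / out$HF
  }
  out
}
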