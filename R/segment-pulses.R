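# Pulse segmentation by the two-moving-average / systolic-block scheme of
# Elgendi et al. (2013), with onset troughs taken between consecutive
# systolic peaks. Published defaults: squared clipped signal after a
# 0.5-8 Hz band-pass; peak moving average W1 = 111 ms, beat moving average
# W2 = 667 ms, offset beta = 0.02 * mean of the squared signal.

moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

#' Detect systolic-peak candidate blocks (Elgendi two moving averages)
#'
#' @param x Filtered PPG signal.
#' @param fs Sampling rate, Hz.
#' @param w1_ms,w2_ms Peak and beat moving-average durations, ms.
#' @param beta Offset fraction of the mean squared signal.
#' @return Integer vector of systolic peak sample indices (1-based).
#' @keywords internal
elgendi_peaks <- function(x, fs, w1_ms = 111, w2_ms = 667, beta = 0.02) {
  bp <- signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bp, x))
  y[y < 0] <- 0
  y <- y^2

  w1 <- round(w1_ms / 1000 * fs)
  w2 <- round(w2_ms / 1000 * fs)
  ma_peak <- moving_average(y, w1)
  ma_beat <- moving_average(y, w2)
  thr1 <- ma_beat + beta * mean(y)
  boi <- !is.na(ma_peak) & !is.na(ma_beat) & ma_peak > thr1

  r <- rle(boi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= w1
  peaks <- integer(0)
  for (j in which(keep)) {
    blk <- starts[j]:ends[j]
    peaks <- c(peaks, blk[which_max1(x[blk])])
  }
  peaks
}

#' Segment a filtered PPG signal into pulses
#'
#' Systolic-peak candidate blocks are found with the two-moving-average
#' scheme; the onset trough of each pulse is the signal minimum between
#' consecutive peaks. Pulses run trough to trough, so the final trough of
#' pulse k is the initial trough of pulse k+1. Pulses overlapping any
#' masked (artifact) sample are dropped.
#'
#' @param x Filtered PPG signal at `fs`.
#' @param fs Sampling rate, Hz.
#' @param mask Optional logical artifact mask aligned with `x` (`TRUE` =
#'   artifact), or an `artifact_mask` from [detect_artifacts()].
#' @return Tibble of class `pulse_set`: columns `pulse_idx`, `IT`, `SP`,
#'   `FT` (global 1-based sample indices) and `valid`. Attribute `"fs"`.
#' @export
segment_pulses <- function(x, fs, mask = NULL) {
  if (inherits(mask, "artifact_mask")) mask <- mask$mask
  if (!is.null(mask) && length(mask) != length(x)) {
    stop("`mask` must be aligned with the signal", call. = FALSE)
  }
  peaks <- elgendi_peaks(x, fs)
  out <- if (length(peaks) < 2) {
    tibble::tibble(pulse_idx = integer(0), IT = integer(0), SP = integer(0),
                   FT = integer(0), valid = logical(0))
  } else {
    troughs <- integer(length(peaks) - 1L)
    for (j in seq_len(length(peaks) - 1L)) {
      seg <- peaks[j]:peaks[j + 1L]
      troughs[j] <- seg[which_min1(x[seg])]
    }
    # pulses between consecutive troughs; SP = peak inside
    n_p <- length(troughs) - 1L
    if (n_p < 1) {
      tibble::tibble(pulse_idx = integer(0), IT = integer(0), SP = integer(0),
                     FT = integer(0), valid = logical(0))
    } else {
      it <- troughs[seq_len(n_p)]
      ft <- troughs[seq_len(n_p) + 1L]
      sp <- peaks[seq_len(n_p) + 1L]  # the peak between trough j and j+1
      keep <- rep(TRUE, n_p)
      if (!is.null(mask)) {
        cum <- cumsum(mask)
        n_masked <- cum[ft] - ifelse(it > 1L, cum[it - 1L], 0L)
        keep <- n_masked == 0L
      }
      tibble::tibble(
        pulse_idx = seq_len(sum(keep)),
        IT = it[keep], SP = sp[keep], FT = ft[keep],
        valid = (it < sp & sp < ft)[keep]
      )
    }
  }
  attr(out, "fs") <- fs
  class(out) <- c("pulse_set", class(out))
  out
}

#' Interbeat intervals from pulse onsets
#'
#' IBIs are the trough-to-trough distances of consecutive detected pulses.
#'
#' @param pulses A `pulse_set` from [segment_pulses()].
#' @param fs Sampling rate, Hz.
#' @return An `ibi_series` tibble (`beat_time_s`, `ibi_ms`): one row per
#'   complete pulse, with `beat_time_s` the onset-trough time and `ibi_ms`
#'   the trough-to-trough interval of that pulse. Dropped pulses leave time
#'   gaps (`beat_time_s[i] + ibi_ms[i]/1000 < beat_time_s[i+1]`), which
#'   downstream consumers treat as discontinuities.
#' @export
ibis_from_pulses <- function(pulses, fs = attr(pulses, "fs")) {
  if (!nrow(pulses)) {
    out <- tibble::tibble(beat_time_s = numeric(0), ibi_ms = numeric(0))
  } else {
    out <- tibble::tibble(
      beat_time_s = (pulses$IT - 1L) / fs,
      ibi_ms = (pulses$FT - pulses$IT) / fs * 1000
    )
  }
  class(out) <- c("ibi_series", class(out))
  out
}
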