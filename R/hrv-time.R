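#' Flag unreliable interbeat intervals
#'
#' An IBI is invalid if it lies outside 0.3-2.4 s or differs by more than
#' 20% from the preceding valid IBI. The 20% comparison always uses the most
#' recent valid interval, so one ectopic-like outlier does not invalidate
#' the beats that follow it.
#'
#' @param ibis An `ibi_series` tibble (`beat_time_s`, `ibi_ms`).
#' @param range_ms Valid IBI range, ms.
#' @param max_rel_change Maximum allowed relative change from the preceding
#'   valid IBI.
#' @return `ibis` with a logical `valid` column (rows with `NA` intervals
#'   are invalid).
#' @export
#' @examples
#' ib <- tibble::tibble(beat_time_s = c(0, .8, 1.8, 2.6),
#'                      ibi_ms = c(800, 1000, 800, NA))
#' filter_ibis(ib)$valid
filter_ibis <- function(ibis, range_ms = c(300, 2400), max_rel_change = 0.2) {
  v <- ibis$ibi_ms
  if (sum(!is.na(v)) < 2) stop("need at least 2 IBIs", call. = FALSE)
  valid <- logical(length(v))
  last_valid <- NA_real_
  for (i in seq_along(v)) {
    if (is.na(v[i]) || v[i] < range_ms[1] || v[i] > range_ms[2]) {
      valid[i] <- FALSE
      next
    }
    if (is.na(last_valid) || abs(v[i] - last_valid) / last_valid <= max_rel_change) {
      valid[i] <- TRUE
      last_valid <- v[i]
    } else {
      valid[i] <- FALSE
    }
  }
  ibis$valid <- valid
  if (!any(valid)) warning("all IBIs invalid; segment unusable", call. = FALSE)
  ibis
}

# Indices of successive valid IBI pairs: rows i where both i and i+1 are
# valid and contiguous in time (no dropped pulse between them).
successive_pairs <- function(ibis, tol_s = 1e-6) {
  v <- ibis$valid
  n <- nrow(ibis)
  if (n < 2) return(integer(0))
  i <- seq_len(n - 1L)
  contig <- abs(ibis$beat_time_s[i] + ibis$ibi_ms[i] / 1000 -
                  ibis$beat_time_s[i + 1L]) < tol_s + 1e-9 * ibis$beat_time_s[i + 1L]
  contig[is.na(contig)] <- FALSE
  which(v[i] & v[i + 1L] & contig)
}

#' Time-domain HRV features
#'
#' * `meanHR`: 60000 / mean IBI, bpm.
#' * `SDNN`: standard deviation of the valid IBIs, ms.
#' * `RMSSD`: root mean square of successive differences over contiguous
#'   valid pairs, ms.
#' * `pNN50`: percentage of successive differences strictly greater than
#'   50 ms.
#' * `kurtosis`, `skewness`: shape of the IBI distribution.
#'
#' The population (divide-by-n) standard deviation is used throughout the
#' package, which makes the Poincare identity `SD1 = RMSSD / sqrt(2)` exact.
#'
#' @param ibis An `ibi_series` with a `valid` column (see [filter_ibis()]).
#' @return One-row tibble `meanHR`, `SDNN`, `RMSSD`, `pNN50`, `kurtosis`,
#'   `skewness`; features that cannot be computed are `NA`.
#' @export
time_domain <- function(ibis) {
  x <- ibis$ibi_ms[ibis$valid]
  out <- tibble::tibble(meanHR = NA_real_, SDNN = NA_real_, RMSSD = NA_real_,
                        pNN50 = NA_real_, kurtosis = NA_real_,
                        skewness = NA_real_)
  if (length(x) >= 2) {
    out$meanHR <- 60000 / mean(x)
    out$SDNN <- sd_pop(x)
    out$kurtosis <- e1071::kurtosis(x)
    out$skewness <- e1071::skewness(x)
  }
  pairs <- successive_pairs(ibis)
  if (length(pairs) >= 2) {
    d <- ibis$ibi_ms[pairs + 1L] - ibis$ibi_ms[pairs]
    out$RMSSD <- rms(d)
    out$pNN50 <- 100 * mean(abs(d) > 50)
  }
  out
}

#' Reconstruct missing beats by on-time quadratic interpolation
#'
#' Beats bounding invalid intervals are treated as missing. For each gap
#' between valid beats, the number of missing beats is estimated from the
#' local mean interval, beat numbers are assigned, and the missing
#' timestamps are obtained from a quadratic least-squares fit of time
#' against beat number through the two valid beats on each side of the gap.
#' The reconstructed, evenly indexed beat sequence is what the
#' frequency-domain and sample-entropy computations consume.
#'
#' @param ibis An `ibi_series` with a `valid` column.
#' @param max_gap_s Gaps longer than this make the series unusable for
#'   continuous-signal features (attribute `usable` is set to `FALSE`).
#' @return Tibble `beat_time_s`, `ibi_ms`, `interpolated` (logical), with
#'   attribute `usable`.
#' @export
interpolate_ontime <- function(ibis, max_gap_s = 10) {
  # beats that start or end a valid interval are trusted
  v <- ibis$valid
  n <- nrow(ibis)
  end_times <- ibis$beat_time_s + ibis$ibi_ms / 1000
  keep_t <- sort(c(ibis$beat_time_s[v], end_times[v]))
  # merge beats that coincide up to floating-point noise (an interval's end
  # and the next interval's start are the same physical beat)
  if (length(keep_t) > 1) {
    keep_t <- keep_t[c(TRUE, diff(keep_t) > 1e-4)]
  }
  if (length(keep_t) < 4) {
    stop("need at least 4 valid beats for on-time interpolation", call. = FALSE)
  }

  gaps <- diff(keep_t)
  local_ibi <- stats::median(ibis$ibi_ms[v]) / 1000
  usable <- !any(gaps > max_gap_s)

  # assign beat numbers: each gap spans round(gap / local_ibi) intervals
  steps <- pmax(1L, as.integer(round(gaps / local_ibi)))
  num <- c(0L, cumsum(steps))

  miss_t <- numeric(0)
  for (j in which(steps > 1L)) {
    k_miss <- (num[j] + 1L):(num[j + 1L] - 1L)
    lo <- max(1L, j - 1L); hi <- min(length(keep_t), j + 2L)
    kk <- num[lo:hi]; tt <- keep_t[lo:hi]
    fit <- if (length(kk) >= 3) {
      stats::lm.fit(cbind(1, kk, kk^2), tt)$coefficients
    } else {
      c(stats::lm.fit(cbind(1, kk), tt)$coefficients, 0)
    }
    fit[is.na(fit)] <- 0
    miss_t <- c(miss_t, fit[1] + fit[2] * k_miss + fit[3] * k_miss^2)
  }

  all_t <- sort(c(keep_t, miss_t))
  out <- tibble::tibble(
    beat_time_s = all_t[-length(all_t)],
    ibi_ms = diff(all_t) * 1000,
    interpolated = !(all_t[-length(all_t)] %in% keep_t)
  )
  attr(out, "usable") <- usable
  out
}
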