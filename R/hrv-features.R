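#' All 30 HRV features for one segment
#'
#' Runs the time-domain, frequency-domain, non-linear (Poincare, DFA,
#' sample entropy), PRSA and fragmentation analyses on one segment's IBI
#' series and returns them as a single row. Intervals are first screened
#' with [filter_ibis()] unless a `valid` column is already present; the
#' frequency-domain and sample-entropy computations use the gap-filled
#' on-time beat sequence resampled at 4 Hz.
#'
#' @param ibis An `ibi_series` tibble.
#' @param fs_resample Tachogram grid rate for the continuous-signal
#'   features, Hz.
#' @return One-row tibble with the 30 columns of [hrv_feature_names].
#' @export
#' @examples
#' p <- cohort_params("A")
#' ib <- generate_ibi_series(p, 300, seed = 7)
#' hrv_features(ib)
hrv_features <- function(ibis, fs_resample = 4) {
  if (!"valid" %in% names(ibis)) ibis <- filter_ibis(ibis)

  td <- time_domain(ibis)
  pc <- poincare(ibis)

  cont <- tryCatch(interpolate_ontime(ibis), error = function(e) NULL)
  fd <- if (is.null(cont)) {
    tibble::tibble(VLF = NA_real_, LF = NA_real_, HF = NA_real_,
                   LFnu = NA_real_, HFnu = NA_real_, LF_HF = NA_real_)
  } else {
    frequency_domain(cont, fs_resample)
  }
  samp <- NA_real_
  if (!is.null(cont) && isTRUE(attr(cont, "usable"))) {
    grid <- tryCatch(resample_tachogram(cont, fs_resample),
                     error = function(e) NULL)
    if (!is.null(grid)) samp <- sample_entropy(grid$ibi_ms)
  }

  dplyr::bind_cols(
    td[, c("meanHR", "SDNN", "RMSSD", "pNN50", "kurtosis", "skewness")],
    fd,
    pc[, c("SD1", "SD2", "SD1_SD2", "S")],
    tibble::tibble(alpha1 = dfa_alpha1(ibis), SampEn = samp),
    prsa(ibis),
    fragmentation(ibis)
  )
}
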