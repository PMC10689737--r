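#' Cohort parameter sets for the synthetic PPG generator
#'
#' Builds the parameter list describing one simulated cohort. The defaults
#' for `group = "B"` (the pregnant-like cohort) shift the non-pregnant-like
#' defaults in the directions reported for healthy pregnancy during sleep:
#' higher mean heart rate (+12 bpm), a shorter systolic upstroke fraction
#' (-20%) and reduced short-term variability (-40% RMSSD target).
#'
#' @param group `"A"` (non-pregnant-like) or `"B"` (pregnant-like).
#' @param n_subjects Number of subjects to simulate in the cohort.
#' @param mean_hr Cohort mean heart rate, bpm.
#' @param hr_sd_between_subjects Between-subject SD of mean heart rate, bpm.
#' @param rmssd_target Target RMSSD of the interbeat-interval series, ms.
#' @param lf_hf_ratio_target Target ratio of low- to high-frequency IBI
#'   modulation power (dimensionless).
#' @param resp_rate Respiratory modulation frequency, Hz (in the 0.15-0.4 Hz
#'   high-frequency band).
#' @param spd_fraction Fraction of the pulse period occupied by the systolic
#'   upstroke (0-1); the systolic peak of the pulse template sits here.
#' @param diastolic_peak_relative_amplitude Diastolic component amplitude as
#'   a fraction of the systolic component (0-1).
#' @param diastolic_peak_delay Centre of the diastolic component as a
#'   fraction of the pulse period; must exceed `spd_fraction`.
#' @param pulse_amplitude Pulse amplitude in arbitrary units.
#' @param noise_sd SD of additive white measurement noise (same units).
#' @param wander_amplitude Amplitude of slow (< 0.05 Hz) baseline wander.
#' @param artifact_rate Expected motion-artifact bursts per hour.
#' @param artifact_duration Duration of each artifact burst, s.
#' @param recording_hours Length of each simulated night, h.
#' @param fs Sampling rate, Hz (32 or 128).
#' @param age_mean,age_sd Cohort age distribution, years.
#'
#' @return A list of class `cohort_params`.
#' @export
#' @examples
#' cohort_params("A", n_subjects = 2, recording_hours = 0.5)
cohort_params <- function(group = c("A", "B"),
                          n_subjects = 20,
                          mean_hr = NULL,
                          hr_sd_between_subjects = 4,
                          rmssd_target = NULL,
                          lf_hf_ratio_target = NULL,
                          resp_rate = 0.25,
                          spd_fraction = NULL,
                          diastolic_peak_relative_amplitude = 0.35,
                          diastolic_peak_delay = 0.62,
                          pulse_amplitude = 1,
                          noise_sd = 0.05,
                          wander_amplitude = 0.08,
                          artifact_rate = 2,
                          artifact_duration = 8,
                          recording_hours = 8,
                          fs = 32,
                          age_mean = NULL,
                          age_sd = 3) {
  group <- match.arg(group)
  # Cohort B mirrors the direction of the largest pregnancy effects:
  # higher HR, shorter systolic phase, reduced beat-to-beat variability.
  if (is.null(mean_hr)) mean_hr <- if (group == "A") 62 else 74
  if (is.null(rmssd_target)) rmssd_target <- if (group == "A") 42 else 25.2
  if (is.null(lf_hf_ratio_target)) lf_hf_ratio_target <- if (group == "A") 1 else 2
  if (is.null(spd_fraction)) spd_fraction <- if (group == "A") 0.33 else 0.264
  if (is.null(age_mean)) age_mean <- if (group == "A") 25 else 31

  stopifnot(spd_fraction > 0, spd_fraction < 1, fs > 0,
            recording_hours > 0, artifact_duration > 0)
  if (mean_hr <= 0) stop("`mean_hr` must be positive", call. = FALSE)

  structure(list(
    group = group, n_subjects = n_subjects, mean_hr = mean_hr,
    hr_sd_between_subjects = hr_sd_between_subjects,
    rmssd_target = rmssd_target, lf_hf_ratio_target = lf_hf_ratio_target,
    resp_rate = resp_rate, spd_fraction = spd_fraction,
    diastolic_peak_relative_amplitude = diastolic_peak_relative_amplitude,
    diastolic_peak_delay = diastolic_peak_delay,
    pulse_amplitude = pulse_amplitude, noise_sd = noise_sd,
    wander_amplitude = wander_amplitude, artifact_rate = artifact_rate,
    artifact_duration = artifact_duration, recording_hours = recording_hours,
    fs = fs, age_mean = age_mean, age_sd = age_sd
  ), class = "cohort_params")
}

#' Generate a synthetic interbeat-interval series
#'
#' Interbeat intervals (IBIs) are modelled as a mean level plus two
#' sinusoidal modulations - one in the low-frequency band (0.04-0.15 Hz)
#' and one at the respiratory rate in the high-frequency band (0.15-0.4 Hz) -
#' plus white jitter. Component amplitudes are solved so that the expected
#' RMSSD of the series equals `rmssd_target` and the ratio of LF to HF
#' sinusoid power equals `lf_hf_ratio_target`: the jitter contributes 30%
#' of the squared RMSSD budget and the two sinusoids the remaining 70%.
#'
#' @param params A [cohort_params()] list (fields `mean_hr`, `rmssd_target`,
#'   `lf_hf_ratio_target`, `resp_rate` are used).
#' @param duration_s Length of the series to generate, s (> 60).
#' @param seed Optional integer seed; fixed seed gives a bit-identical series.
#' @param lf_freq Low-frequency modulation frequency, Hz.
#'
#' @return A tibble of class `ibi_series` with columns `beat_time_s` (trough
#'   times, s) and `ibi_ms` (interval to the next beat, ms); the last beat
#'   closes the final interval and carries `NA` in `ibi_ms`.
#' @export
#' @examples
#' ib <- generate_ibi_series(cohort_params("A"), duration_s = 300, seed = 1)
#' mean(ib$ibi_ms, na.rm = TRUE)
generate_ibi_series <- function(params, duration_s, seed = NULL,
                                lf_freq = 0.095) {
  if (params$mean_hr <= 0) stop("`mean_hr` must be positive", call. = FALSE)
  if (duration_s <= 60) stop("`duration_s` must exceed 60 s", call. = FALSE)

  t_bar <- 60 / params$mean_hr          # mean IBI, s
  r <- params$rmssd_target              # ms
  f_lf <- lf_freq
  f_hf <- params$resp_rate
  ratio <- params$lf_hf_ratio_target

  # RMSSD contribution of a sinusoid of amplitude A at frequency f sampled
  # every t_bar seconds is sqrt(2) * A * |sin(pi f t_bar)|; contributions of
  # independent components add in quadrature. White jitter sd sigma
  # contributes sqrt(2) * sigma.
  if (r > 0) {
    g_lf <- 2 * sin(pi * f_lf * t_bar)^2
    g_hf <- 2 * sin(pi * f_hf * t_bar)^2
    # A_lf^2 = ratio * A_hf^2 (equal LF/HF power ratio of the sinusoids)
    a_hf <- sqrt(0.7 * r^2 / (g_hf + ratio * g_lf))
    a_lf <- sqrt(ratio) * a_hf
    sigma <- sqrt(0.15) * r
  } else {
    a_hf <- a_lf <- sigma <- 0
  }

  with_seed_if(seed, {
    phi_lf <- stats::runif(1, 0, 2 * pi)
    phi_hf <- stats::runif(1, 0, 2 * pi)
    n_max <- ceiling(duration_s / t_bar * 1.6) + 16L
    jitter <- if (sigma > 0) stats::rnorm(n_max, 0, sigma) else numeric(n_max)

    beat_t <- numeric(n_max)
    ibi <- numeric(n_max)
    t <- 0
    i <- 0L
    while (t < duration_s && i < n_max) {
      i <- i + 1L
      beat_t[i] <- t
      ibi_ms <- 1000 * t_bar +
        a_lf * sin(2 * pi * f_lf * t + phi_lf) +
        a_hf * sin(2 * pi * f_hf * t + phi_hf) +
        jitter[i]
      ibi_ms <- max(ibi_ms, 300)   # generator bound: keep IBIs physiological
      ibi[i] <- ibi_ms
      t <- t + ibi_ms / 1000
    }
    out <- tibble::tibble(
      beat_time_s = c(beat_t[seq_len(i)], t),
      ibi_ms = c(ibi[seq_len(i)], NA_real_)
    )
    class(out) <- c("ibi_series", class(out))
    out
  })
}
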