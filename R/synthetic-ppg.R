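#' Synthesize a PPG recording from an interbeat-interval series
#'
#' Renders one pulse-template period per beat, rescaled in time to the
#' beat's interbeat interval, then adds slow baseline wander (< 0.05 Hz),
#' white measurement noise and motion-artifact bursts (high-amplitude
#' broadband noise over logged windows). Artifact burst count is a Poisson
#' draw at `artifact_rate` per hour; start times are uniform over the
#' recording. Every beat time and artifact window is logged as ground truth.
#'
#' @param ibis An `ibi_series` tibble from [generate_ibi_series()].
#' @param params A [cohort_params()] list; template, noise and artifact
#'   fields are used.
#' @param seed Optional integer seed for noise and artifact placement.
#'
#' @return A list with elements
#'   * `record`: tibble `time_s`, `ppg` plus attributes `fs`;
#'   * `ground_truth`: list with `beat_times_s`, `ibi_ms`,
#'     `artifact_windows` (tibble `start_s`, `end_s`) and `duration_s`.
#' @export
#' @examples
#' p <- cohort_params("A", noise_sd = 0, artifact_rate = 0, wander_amplitude = 0)
#' ib <- generate_ibi_series(p, 120, seed = 1)
#' rec <- synthesize_ppg(ib, p, seed = 1)
#' str(rec$record)
synthesize_ppg <- function(ibis, params, seed = NULL) {
  if (!nrow(ibis) || all(is.na(ibis$ibi_ms))) {
    stop("empty IBI series", call. = FALSE)
  }
  fs <- params$fs
  if (!fs %in% c(32, 128)) stop("`fs` must be 32 or 128 Hz", call. = FALSE)

  tmpl <- synthesize_pulse_template(
    spd_fraction = params$spd_fraction,
    diastolic_peak_relative_amplitude = params$diastolic_peak_relative_amplitude,
    diastolic_peak_delay = params$diastolic_peak_delay,
    n_samples = 64
  )
  f <- attr(tmpl, "fun")

  beats <- ibis$beat_time_s[!is.na(ibis$ibi_ms)]
  durs <- ibis$ibi_ms[!is.na(ibis$ibi_ms)] / 1000
  t_end <- beats[length(beats)] + durs[length(durs)]
  t <- seq(0, t_end - 1 / fs, by = 1 / fs)

  # map each sample to its beat and evaluate the continuous template at the
  # within-beat phase
  k <- findInterval(t, beats)
  k[k < 1L] <- 1L
  u <- (t - beats[k]) / durs[k]
  u <- pmin(pmax(u, 0), 1)
  x <- params$pulse_amplitude * f(u)

  noisy <- with_seed_if(seed, {
    gt_windows <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
    if (params$wander_amplitude > 0) {
      phi <- stats::runif(2, 0, 2 * pi)
      x <- x + params$wander_amplitude *
        (sin(2 * pi * 0.015 * t + phi[1]) + 0.5 * sin(2 * pi * 0.04 * t + phi[2]))
    }
    if (params$noise_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, params$noise_sd)
    }
    if (params$artifact_rate > 0) {
      n_art <- stats::rpois(1, params$artifact_rate * t_end / 3600)
      if (n_art > 0) {
        starts <- sort(stats::runif(n_art, 0, max(t_end - params$artifact_duration, 0)))
        ends <- pmin(starts + params$artifact_duration, t_end)
        gt_windows <- tibble::tibble(start_s = starts, end_s = ends)
        for (j in seq_len(n_art)) {
          idx <- which(t >= starts[j] & t < ends[j])
          x[idx] <- x[idx] +
            stats::runif(length(idx), -5, 5) * params$pulse_amplitude
        }
      }
    }
    list(x = x, windows = gt_windows)
  })
  x <- noisy$x
  gt_windows <- noisy$windows

  record <- tibble::tibble(time_s = t, ppg = x)
  attr(record, "fs") <- fs
  list(
    record = record,
    ground_truth = list(
      beat_times_s = beats,
      ibi_ms = durs * 1000,
      artifact_windows = gt_windows,
      duration_s = t_end
    )
  )
}

#' Generate a synthetic 30-s epoch hypnogram
#'
#' Sleep stages over the night are drawn from a first-order Markov chain on
#' the labels `N1/N2` (light sleep), `N3` (deep sleep), `REM` and `Wake`,
#' with self-transition probabilities high enough to give realistic dwell
#' times and a stationary distribution ordered N1/N2 > N3 > REM.
#'
#' @param duration_h Recording length in hours (> 0).
#' @param seed Optional integer seed.
#' @param transition Optional 4x4 row-stochastic matrix with dimnames over
#'   `c("N1/N2", "N3", "REM", "Wake")`, overriding the default chain.
#'
#' @return Tibble with columns `epoch` (0-based index), `start_s`, `stage`
#'   (factor). The hypnogram covers the full recording: `ceiling(h*3600/30)`
#'   epochs.
#' @export
#' @examples
#' h <- generate_hypnogram(8, seed = 1)
#' table(h$stage)
generate_hypnogram <- function(duration_h, seed = NULL, transition = NULL) {
  if (duration_h <= 0) stop("`duration_h` must be positive", call. = FALSE)
  stages <- c("N1/N2", "N3", "REM", "Wake")
  if (is.null(transition)) {
    transition <- hypnogram_transition_matrix()
  }
  stopifnot(all(dim(transition) == c(4, 4)))
  n <- ceiling(duration_h * 3600 / 30)
  with_seed_if(seed, {
    s <- integer(n)
    s[1] <- 4L  # nights start awake
    for (i in seq_len(n - 1L)) {
      s[i + 1L] <- sample.int(4L, 1L, prob = transition[s[i], ])
    }
    tibble::tibble(
      epoch = seq_len(n) - 1L,
      start_s = (seq_len(n) - 1L) * 30,
      stage = factor(stages[s], levels = stages)
    )
  })
}

#' @rdname generate_hypnogram
#' @export
hypnogram_transition_matrix <- function() {
  stages <- c("N1/N2", "N3", "REM", "Wake")
  m <- matrix(c(
    # to: N1/N2   N3     REM    Wake
    0.920, 0.040, 0.025, 0.015,  # from N1/N2
    0.100, 0.890, 0.005, 0.005,  # from N3
    0.080, 0.005, 0.900, 0.015,  # from REM
    0.120, 0.005, 0.010, 0.865   # from Wake
  ), nrow = 4, byrow = TRUE, dimnames = list(stages, stages))
  m
}
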