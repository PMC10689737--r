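#' Simulate one subject-night
#'
#' Draws subject-level physiology (mean heart rate, RMSSD target, systolic
#' fraction, age) around the cohort parameters, then generates the IBI
#' series, the PPG record and a hypnogram for one night.
#'
#' @param params A [cohort_params()] list.
#' @param subject_id Identifier stored in the output.
#' @param night Night index (second nights can apply a parameter shift via
#'   `night_shift`).
#' @param seed Integer seed; the whole subject-night is reproducible from it.
#' @param night_shift Named list of additive shifts applied to subject-level
#'   parameters on nights > 1 (default: `mean_hr + 3` bpm, `rmssd_target *
#'   0.9`), standing in for progressing gestation in cohort B.
#'
#' @return A one-row tibble with list-columns `record`, `hypnogram`,
#'   `ground_truth`, `subject_params` and scalar metadata columns.
#' @export
simulate_subject <- function(params, subject_id, night = 1L, seed = 1L,
                             night_shift = list(mean_hr = 3, rmssd_scale = 0.9)) {
  seeds <- derive_seeds(seed, 4L)
  subj <- with_seed_if(seeds[1], {
    p <- params
    p$mean_hr <- stats::rnorm(1, params$mean_hr, params$hr_sd_between_subjects)
    p$mean_hr <- max(p$mean_hr, 40)
    p$rmssd_target <- max(stats::rnorm(1, params$rmssd_target,
                                       0.12 * params$rmssd_target), 5)
    p$spd_fraction <- min(max(stats::rnorm(1, params$spd_fraction, 0.02), 0.15), 0.6)
    p$age <- round(stats::rnorm(1, params$age_mean, params$age_sd))
    p
  })
  if (night > 1L) {
    subj$mean_hr <- subj$mean_hr + night_shift$mean_hr
    subj$rmssd_target <- subj$rmssd_target * night_shift$rmssd_scale
  }

  duration_s <- params$recording_hours * 3600
  ibis <- generate_ibi_series(subj, duration_s, seed = seeds[2])
  rec <- synthesize_ppg(ibis, subj, seed = seeds[3])
  hyp <- generate_hypnogram(params$recording_hours, seed = seeds[4])

  tibble::tibble(
    subject_id = subject_id,
    group = params$group,
    night = as.integer(night),
    age = subj$age,
    fs = params$fs,
    record = list(rec$record),
    hypnogram = list(hyp),
    ground_truth = list(rec$ground_truth),
    subject_params = list(subj)
  )
}

#' Simulate a two-cohort PPG study
#'
#' Generates `n_subjects` subject-nights for each of the two cohorts
#' (non-pregnant-like `A` and pregnant-like `B`) with known ground truth.
#' All randomness flows from the single `seed`.
#'
#' @param params_a,params_b [cohort_params()] for the two cohorts; defaults
#'   are the package's study conditions.
#' @param seed Master integer seed.
#' @param nights Number of nights to simulate per subject of cohort B
#'   (cohort A always gets one night, matching a single-visit control group).
#'
#' @return Tibble with one row per subject-night (see [simulate_subject()]).
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohorts(
#'   cohort_params("A", n_subjects = 2, recording_hours = 0.2),
#'   cohort_params("B", n_subjects = 2, recording_hours = 0.2),
#'   seed = 1
#' )
#' }
simulate_cohorts <- function(params_a = cohort_params("A"),
                             params_b = cohort_params("B"),
                             seed = 1L,
                             nights = 1L) {
  n_total <- params_a$n_subjects + params_b$n_subjects * nights
  seeds <- derive_seeds(seed, n_total)
  rows <- list()
  k <- 0L
  for (i in seq_len(params_a$n_subjects)) {
    k <- k + 1L
    rows[[k]] <- simulate_subject(params_a, sprintf("A%02d", i), 1L, seeds[k])
  }
  for (i in seq_len(params_b$n_subjects)) {
    subj_seed_row <- k + 1L
    for (nt in seq_len(nights)) {
      k <- k + 1L
      # same subject seed across nights so night 2 is the same physiology
      # with the gestational shift applied
      rows[[k]] <- simulate_subject(params_b, sprintf("B%02d", i), nt,
                                    seeds[subj_seed_row])
    }
  }
  dplyr::bind_rows(rows)
}
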