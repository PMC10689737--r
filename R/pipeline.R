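#' Cut a recording into candidate 5-minute segments
#'
#' Full-night mode tiles consecutive 300-s windows from the start of the
#' recording. Stage mode first finds maximal runs of at least
#' `segment_s / 30` consecutive 30-s hypnogram epochs of the target stage
#' and tiles 300-s windows within each run, so every segment contains data
#' from exactly one sleep stage; Wake is never a target stage.
#'
#' @param duration_s Recording length, s.
#' @param hypnogram Tibble from [generate_hypnogram()] (required for stage
#'   mode).
#' @param stage `"full"` for whole-night segments, or one of `"N1/N2"`,
#'   `"N3"`, `"REM"`.
#' @param segment_s Segment length, s.
#' @return Tibble `start_s`, `end_s`, `stage`.
#' @export
#' @examples
#' window_segments(8 * 3600)
window_segments <- function(duration_s, hypnogram = NULL, stage = "full",
                            segment_s = 300) {
  if (identical(stage, "full")) {
    n <- floor(duration_s / segment_s)
    starts <- (seq_len(n) - 1L) * segment_s
    return(tibble::tibble(start_s = starts, end_s = starts + segment_s,
                          stage = "full"))
  }
  if (identical(stage, "Wake")) {
    stop("Wake is not a valid target stage", call. = FALSE)
  }
  if (is.null(hypnogram)) stop("stage mode needs a hypnogram", call. = FALSE)
  epochs_needed <- segment_s / 30
  r <- rle(as.character(hypnogram$stage))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (j in which(r$values == stage & r$lengths >= epochs_needed)) {
    run_start <- hypnogram$start_s[starts[j]]
    run_len <- r$lengths[j] * 30
    n <- floor(run_len / segment_s)
    s0 <- run_start + (seq_len(n) - 1L) * segment_s
    rows[[length(rows) + 1L]] <-
      tibble::tibble(start_s = s0, end_s = s0 + segment_s, stage = stage)
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          stage = character(0))
  }
  # clip to the recording
  dplyr::filter(out, .data$end_s <= duration_s)
}

#' Segment quality gate
#'
#' A segment is accepted iff strictly less than `max_fraction` of its
#' samples were removed as motion artifacts AND strictly less than
#' `max_fraction` of its IBIs are invalid.
#'
#' @param mask Logical artifact mask for the segment's samples.
#' @param ibi_valid Logical validity flags for the segment's IBIs.
#' @param max_fraction Rejection threshold (default 20%).
#' @return List `accepted`, `fraction_masked`, `fraction_invalid_ibis`.
#' @export
quality_gate <- function(mask, ibi_valid, max_fraction = 0.2) {
  fm <- if (length(mask)) mean(mask) else 1
  fi <- if (length(ibi_valid)) mean(!ibi_valid) else 1
  list(accepted = fm < max_fraction && fi < max_fraction,
       fraction_masked = fm, fraction_invalid_ibis = fi)
}

#' Extract the 67-feature vector for every accepted segment of one record
#'
#' Runs the full single-record pipeline: preprocessing (band-pass filter,
#' SII artifact mask), pulse segmentation and fiducial detection, IBI
#' screening, segment windowing (whole night and/or per sleep stage), the
#' 20% quality gates, and HRV + morphology feature extraction per accepted
#' segment.
#'
#' @param record Tibble `time_s`, `ppg` (attribute `fs`), or a numeric
#'   vector with `fs` given.
#' @param fs Sampling rate of `record`, Hz.
#' @param hypnogram Optional hypnogram tibble for stage-stratified segments.
#' @param stages Character vector of segment streams to extract: any of
#'   `"full"`, `"N1/N2"`, `"N3"`, `"REM"`.
#' @param metadata Optional named list (e.g. subject id, group, age, night)
#'   bound to every output row.
#' @param segment_s Segment length, s.
#' @return Tibble: one row per candidate segment with metadata columns,
#'   `stage`, `start_s`, `accepted`, `fraction_masked`,
#'   `fraction_invalid_ibis`, `n_pulses` and the 67 feature columns
#'   (`NA`-filled for rejected segments).
#' @export
extract_features <- function(record, fs = attr(record, "fs"),
                             hypnogram = NULL, stages = "full",
                             metadata = NULL, segment_s = 300) {
  x_raw <- if (is.data.frame(record)) record$ppg else as.numeric(record)
  if (is.null(fs)) stop("`fs` must be supplied", call. = FALSE)
  prep <- preprocess_record(x_raw, fs)
  xf <- prep$signal
  fs <- prep$fs
  mask <- prep$artifacts$mask
  duration_s <- length(xf) / fs

  derivs <- pulse_derivatives(xf, fs)
  pulses <- detect_pulses(xf, fs, mask)
  ibis_all <- filter_ibis(ibis_from_pulses(pulses, fs))
  per_pulse_all <- pulse_morphology(pulses, xf, fs, derivs)

  pulse_start <- ibis_all$beat_time_s
  rows <- list()
  for (stage in stages) {
    segs <- window_segments(duration_s, hypnogram, stage, segment_s)
    for (k in seq_len(nrow(segs))) {
      s0 <- segs$start_s[k]; s1 <- segs$end_s[k]
      samp <- (floor(s0 * fs) + 1L):min(floor(s1 * fs), length(xf))
      in_seg <- which(pulse_start >= s0 & pulse_start < s1)
      ib <- ibis_all[in_seg, ]
      gate <- quality_gate(mask[samp], ib$valid)

      meta <- tibble::as_tibble(c(
        metadata,
        list(stage = stage, start_s = s0, accepted = gate$accepted,
             fraction_masked = gate$fraction_masked,
             fraction_invalid_ibis = gate$fraction_invalid_ibis)
      ))
      if (!gate$accepted || !nrow(ib)) {
        feats <- tibble::as_tibble(stats::setNames(
          as.list(rep(NA_real_, length(all_feature_names))), all_feature_names))
        feats$n_pulses <- length(in_seg)
      } else {
        hrv <- hrv_features(ib)
        pp <- per_pulse_all[per_pulse_all$pulse_idx %in% pulses$pulse_idx[in_seg], ]
        morph <- aggregate_segment_morphology(pp)
        feats <- dplyr::bind_cols(hrv, morph)
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(meta, feats)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  class(out) <- c("feature_table", class(out))
  out
}

#' Feature table for a whole simulated study
#'
#' Maps [extract_features()] over every subject-night of a
#' [simulate_cohorts()] tibble and binds the accepted-segment rows.
#'
#' @param cohort Tibble from [simulate_cohorts()].
#' @param stages Segment streams to extract (see [extract_features()]).
#' @param keep_rejected Keep rows for rejected segments (default drops
#'   them).
#' @return A `feature_table` tibble, one row per (accepted) segment.
#' @export
extract_cohort_features <- function(cohort, stages = "full",
                                    keep_rejected = FALSE) {
  rows <- purrr::pmap(
    list(cohort$record, cohort$hypnogram, cohort$subject_id, cohort$group,
         cohort$night, cohort$age, cohort$fs),
    function(rec, hyp, sid, grp, night, age, fs) {
      extract_features(
        rec, fs = fs, hypnogram = hyp, stages = stages,
        metadata = list(subject_id = sid, group = grp, night = night,
                        age = age)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (!keep_rejected) out <- dplyr::filter(out, .data$accepted)
  class(out) <- c("feature_table", class(out))
  out
}
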