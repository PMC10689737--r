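#' Read and write PPG records, hypnograms and feature tables
#'
#' Records are stored as a CSV (`time_s,ppg`) with a JSON sidecar holding
#' the metadata (subject id, group, age, sampling rate, night index);
#' hypnograms as CSV (`epoch_index,stage`); ground truth (beat times,
#' artifact windows) as JSON; feature tables as tidy CSV with one row per
#' segment and missing values as empty cells.
#'
#' @param record Tibble `time_s`, `ppg`.
#' @param path Path of the signal CSV; the sidecar uses the same path with
#'   extension `.json`.
#' @param metadata Named list written to the sidecar (must include `fs`).
#' @return `write_*` return `path` invisibly; `read_ppg_record` returns the
#'   record tibble with attributes `fs` and `metadata`.
#' @name ppg_io
NULL

#' @rdname ppg_io
#' @export
write_ppg_record <- function(record, path, metadata = list(fs = attr(record, "fs"))) {
  readr::write_csv(tibble::as_tibble(record[, c("time_s", "ppg")]), path)
  jsonlite::write_json(metadata, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ppg_io
#' @export
read_ppg_record <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  attr(rec, "fs") <- if (!is.null(meta$fs)) as.numeric(meta$fs) else NULL
  attr(rec, "metadata") <- meta
  rec
}

#' @rdname ppg_io
#' @param hypnogram Tibble from [generate_hypnogram()].
#' @export
write_hypnogram <- function(hypnogram, path) {
  readr::write_csv(
    tibble::tibble(epoch_index = hypnogram$epoch,
                   stage = as.character(hypnogram$stage)),
    path
  )
  invisible(path)
}

#' @rdname ppg_io
#' @export
read_hypnogram <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    epoch = as.integer(df$epoch_index),
    start_s = as.integer(df$epoch_index) * 30,
    stage = factor(df$stage, levels = c("N1/N2", "N3", "REM", "Wake"))
  )
}

#' @rdname ppg_io
#' @param ground_truth Ground-truth list from [synthesize_ppg()].
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(
    list(
      beat_times_s = ground_truth$beat_times_s,
      ibi_ms = ground_truth$ibi_ms,
      artifact_windows = ground_truth$artifact_windows,
      duration_s = ground_truth$duration_s
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname ppg_io
#' @param features A `feature_table`.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(tibble::as_tibble(features), path, na = "")
  invisible(path)
}

#' @rdname ppg_io
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("feature_table", class(out))
  out
}
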