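#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a feature ranking
#'
#' @param x A `ppg_ranking` from [rank_features()].
#' @param ... Unused.
#' @return The popularity tibble (`feature`, `borda`, `mean_rank`) with a
#'   `top` flag.
#' @export
tidy.ppg_ranking <- function(x, ...) {
  dplyr::mutate(x$popularity, top = .data$feature %in% x$top)
}

#' @rdname tidy.ppg_ranking
#' @export
glance.ppg_ranking <- function(x, ...) {
  tibble::tibble(
    feature_set = x$feature_set,
    n_segments = x$n_used,
    n_repeats = max(x$rankings$repeat_id),
    depth = max(x$rankings$rank),
    top_feature = x$top[1]
  )
}

#' Tidy an incremental evaluation curve
#'
#' @param x A `ppg_eval_curve` from [evaluate_incremental()].
#' @param ... Unused.
#' @return The curve as a plain tibble.
#' @export
tidy.ppg_eval_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.ppg_eval_curve
#' @export
glance.ppg_eval_curve <- function(x, ...) {
  best <- which.max(x$auroc_mean)
  tibble::tibble(
    stratification = x$stratification[1],
    best_feature_count = x$feature_count[best],
    best_auroc = x$auroc_mean[best],
    auroc_at_full = x$auroc_mean[nrow(x)]
  )
}
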