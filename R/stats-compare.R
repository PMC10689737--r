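#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with mid-ranks for ties: the probability
#' that a random positive scores above a random negative.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical or 0/1 vector; `TRUE`/1 is the positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's d with a bootstrap confidence interval
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled sample SD; the 95% CI is the percentile bootstrap over `n_boot`
#' resamples of each group.
#'
#' @param x,y Numeric samples for the two groups.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return List `d`, `ci_lower`, `ci_upper`.
#' @export
cohens_d <- function(x, y, n_boot = 2000, conf = 0.95, seed = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  d_fun <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    if (!is.finite(sp) || sp == 0) return(NA_real_)
    (mean(a) - mean(b)) / sp
  }
  d <- d_fun(x, y)
  if (is.na(d)) return(list(d = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_))
  boots <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(i) {
      d_fun(sample(x, replace = TRUE), sample(y, replace = TRUE))
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(d = d, ci_lower = qs[1], ci_upper = qs[2])
}

#' Compare features between two groups
#'
#' For every feature column: two-sided Mann-Whitney U p-value, Cohen's d
#' (group `a` minus group `b`) with a 95% bootstrap CI, and group medians
#' with interquartile ranges. Segments are the sampling unit.
#'
#' @param features A `feature_table` (or any data frame of segments).
#' @param group_col Column holding the two group labels.
#' @param feature_cols Feature columns to compare (default: every
#'   catalogued feature present).
#' @param group_a Label treated as the first group (d > 0 means larger in
#'   `group_a`); default is the first level encountered.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Seed for the bootstrap.
#' @return Tibble: `feature`, `cohens_d`, `ci_lower`, `ci_upper`,
#'   `mann_whitney_p`, `median_a`, `iqr_a`, `median_b`, `iqr_b`, `n_a`,
#'   `n_b`.
#' @export
group_compare <- function(features, group_col = "group",
                          feature_cols = NULL, group_a = NULL,
                          n_boot = 2000, seed = 1L) {
  g <- features[[group_col]]
  if (is.null(group_a)) group_a <- unique(g)[1]
  labs <- unique(g)
  if (length(labs) != 2) stop("need exactly two groups", call. = FALSE)
  group_b <- setdiff(labs, group_a)
  if (is.null(feature_cols)) {
    feature_cols <- intersect(all_feature_names, names(features))
  }
  seeds <- derive_seeds(seed, length(feature_cols))

  purrr::map2_dfr(feature_cols, seeds, function(fc, sd_i) {
    xa <- features[[fc]][g == group_a]
    xb <- features[[fc]][g == group_b]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (!length(xa) || !length(xb)) {
      return(tibble::tibble(
        feature = fc, cohens_d = NA_real_, ci_lower = NA_real_,
        ci_upper = NA_real_, mann_whitney_p = NA_real_,
        median_a = NA_real_, iqr_a = NA_real_, median_b = NA_real_,
        iqr_b = NA_real_, n_a = length(xa), n_b = length(xb)
      ))
    }
    p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
    dd <- cohens_d(xa, xb, n_boot = n_boot, seed = sd_i)
    tibble::tibble(
      feature = fc, cohens_d = dd$d, ci_lower = dd$ci_lower,
      ci_upper = dd$ci_upper, mann_whitney_p = p,
      median_a = stats::median(xa), iqr_a = stats::IQR(xa),
      median_b = stats::median(xb), iqr_b = stats::IQR(xb),
      n_a = length(xa), n_b = length(xb)
    )
  })
}

#' Compare features between two recording nights of one cohort
#'
#' Same machinery as [group_compare()], applied to the night-1 vs night-2
#' segments of a single cohort (e.g. to assess progressing gestation).
#'
#' @param features A `feature_table` containing a `night` column.
#' @param nights The two night indices to compare (d > 0 means larger on
#'   the first).
#' @inheritParams group_compare
#' @return Same schema as [group_compare()].
#' @export
condition_compare <- function(features, nights = c(1L, 2L),
                              feature_cols = NULL, n_boot = 2000, seed = 1L) {
  sub <- dplyr::filter(features, .data$night %in% nights)
  if (!all(nights %in% sub$night)) stop("both nights must be present", call. = FALSE)
  group_compare(sub, group_col = "night", feature_cols = feature_cols,
                group_a = nights[1], n_boot = n_boot, seed = seed)
}

#' Per-feature linear trend on age
#'
#' If a subject contributes multiple segments, their feature values are
#' first averaged so each subject enters once; then an ordinary
#' least-squares regression of the feature on age gives the slope and its
#' two-sided p-value.
#'
#' @param features A `feature_table` with `subject_id` and `age` columns.
#' @param feature_cols Features to test (default: all catalogued features
#'   present).
#' @return Tibble `feature`, `slope`, `p_value`, `n_subjects`.
#' @export
age_trend <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(all_feature_names, names(features))
  }
  per_subj <- features |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      age = .data$age[1],
      dplyr::across(dplyr::all_of(feature_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  if (nrow(per_subj) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (stats::var(per_subj$age) == 0) {
    stop("ages are constant; trend undefined", call. = FALSE)
  }
  purrr::map_dfr(feature_cols, function(fc) {
    ok <- is.finite(per_subj[[fc]])
    if (sum(ok) < 3) {
      return(tibble::tibble(feature = fc, slope = NA_real_,
                            p_value = NA_real_, n_subjects = sum(ok)))
    }
    fit <- stats::lm(per_subj[[fc]][ok] ~ per_subj$age[ok])
    sm <- summary(fit)$coefficients
    tibble::tibble(feature = fc, slope = sm[2, 1], p_value = sm[2, 4],
                   n_subjects = sum(ok))
  })
}
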