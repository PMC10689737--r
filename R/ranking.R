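# Stepwise-forward feature ranking and incremental logistic-regression
# evaluation. Folds are stratified by class (or grouped by participant),
# features are z-scored with training-fold statistics only, and models are
# unpenalized logistic regressions scored by validation AUROC.

# stratified k-fold assignment; returns integer fold id per row
stratified_folds <- function(y, k, seed) {
  with_seed_if(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# grouped k-fold: all rows of a group share a fold; groups balanced by class
grouped_folds <- function(y, groups, k, seed) {
  with_seed_if(seed, {
    gtab <- tibble::tibble(group = groups, y = y) |>
      dplyr::distinct(.data$group, .keep_all = TRUE)
    fold_of <- integer(nrow(gtab))
    for (cl in unique(gtab$y)) {
      idx <- sample(which(gtab$y == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold_of[match(groups, gtab$group)]
  })
}

# logistic regression on z-scored training features; returns validation scores
logistic_val_scores <- function(X_tr, y_tr, X_va) {
  mu <- colMeans(X_tr)
  sdv <- apply(X_tr, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Z_tr <- sweep(sweep(X_tr, 2, mu), 2, sdv, "/")
  Z_va <- sweep(sweep(X_va, 2, mu), 2, sdv, "/")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Z_tr), y_tr, family = stats::binomial())
  )
  drop(cbind(1, Z_va) %*% fit$coefficients)
}

# mean validation AUROC of a feature subset over the folds
cv_auroc <- function(X, y, fold) {
  k <- max(fold)
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    va <- fold == f
    if (length(unique(y[va])) < 2 || length(unique(y[!va])) < 2) next
    sc <- logistic_val_scores(X[!va, , drop = FALSE], y[!va],
                              X[va, , drop = FALSE])
    aucs[f] <- auroc(sc, y[va])
  }
  aucs
}

#' Rank features by stepwise forward selection under cross-validation
#'
#' Within each of `n_repeats` independently reshuffled stratified
#' `n_folds`-fold cross-validations, features are ranked by greedy forward
#' selection: at each step the candidate whose addition maximizes the mean
#' validation AUROC of a logistic regression over the folds is appended to
#' the ranking. Popularity across the repeats is aggregated by Borda count
#' (rank r in a depth-L ranking scores L - r + 1 points); the `top_n` most
#' popular features form the final list, with ties broken by mean rank and
#' then name. Rows with missing values in any candidate feature are dropped
#' (with a message).
#'
#' @param features A `feature_table` with a two-level label column.
#' @param label_col Column with the class labels; the second sorted level is
#'   the positive class.
#' @param feature_set `"hrv"`, `"morph"` or `"combined"` (see
#'   [feature_pool()]; `PWD` is never a candidate for morph/combined), or a
#'   character vector of feature names.
#' @param n_folds,n_repeats Cross-validation geometry.
#' @param max_rank Depth of each repeat's ranking.
#' @param top_n Size of the final popularity list.
#' @param seed Master seed; fixed seed gives identical rankings.
#' @return Object of class `ppg_ranking`: list with `rankings` (tibble
#'   `repeat_id`, `rank`, `feature`), `popularity` (tibble `feature`,
#'   `borda`, `mean_rank`), `top` (character), `feature_set`, `n_used`.
#' @export
rank_features <- function(features, label_col = "group",
                          feature_set = "combined", n_folds = 7,
                          n_repeats = 7, max_rank = 10, top_n = 10,
                          seed = 1L) {
  pool <- if (length(feature_set) == 1 &&
              feature_set %in% c("hrv", "morph", "combined")) {
    feature_pool(feature_set)
  } else {
    feature_set
  }
  pool <- intersect(pool, names(features))
  df <- features[, c(label_col, pool)]
  complete <- stats::complete.cases(df)
  if (!all(complete)) {
    message(sum(!complete), " segments dropped for missing candidate features")
    df <- df[complete, ]
  }
  y <- as.integer(factor(df[[label_col]])) - 1L
  X <- as.matrix(df[, pool])
  max_rank <- min(max_rank, length(pool))

  seeds <- derive_seeds(seed, n_repeats)
  rankings <- purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
    fold <- stratified_folds(y, n_folds, seeds[rep_i])
    selected <- character(0)
    remaining <- pool
    for (step in seq_len(max_rank)) {
      score <- vapply(remaining, function(fc) {
        mean(cv_auroc(X[, c(selected, fc), drop = FALSE], y, fold),
             na.rm = TRUE)
      }, numeric(1))
      best <- remaining[which_max1(score)]
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
    }
    tibble::tibble(repeat_id = rep_i, rank = seq_along(selected),
                   feature = selected)
  })

  popularity <- rankings |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(borda = sum(max_rank - .data$rank + 1L),
                     mean_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$borda), .data$mean_rank, .data$feature)

  structure(list(
    rankings = rankings,
    popularity = popularity,
    top = utils::head(popularity$feature, top_n),
    feature_set = if (length(feature_set) == 1) feature_set else "custom",
    n_used = nrow(df)
  ), class = "ppg_ranking")
}

#' @export
print.ppg_ranking <- function(x, ...) {
  cat("Stepwise-forward feature ranking (", x$feature_set, " set, n = ",
      x$n_used, " segments)\n", sep = "")
  cat("Top features by popularity:\n")
  print(utils::head(x$popularity, length(x$top)))
  invisible(x)
}

#' Incremental AUROC evaluation of the top-ranked features
#'
#' For k = 1..length(top): a logistic regression on the first k ranked
#' features, evaluated by AUROC on the left-out folds of `n_repeats`
#' reshuffled `n_folds`-fold cross-validations. Folds are either stratified
#' over segments or grouped per participant (all of a subject's segments in
#' the same fold). Folds whose held-out part contains a single class are
#' skipped.
#'
#' @param features A `feature_table`.
#' @param top Ordered character vector of features (e.g. `$top` of
#'   [rank_features()]).
#' @param label_col Class label column.
#' @param stratification `"segment"` or `"participant"`.
#' @param subject_col Subject identifier column (participant mode).
#' @param n_folds,n_repeats Cross-validation geometry.
#' @param seed Master seed.
#' @return Tibble of class `ppg_eval_curve`: `feature_count`, `auroc_mean`,
#'   `auroc_sd`, `n_folds_used`, `stratification`, `feature_added`.
#' @export
evaluate_incremental <- function(features, top, label_col = "group",
                                 stratification = c("segment", "participant"),
                                 subject_col = "subject_id", n_folds = 7,
                                 n_repeats = 7, seed = 1L) {
  stratification <- match.arg(stratification)
  df <- features[, c(label_col,
                     if (stratification == "participant") subject_col, top)]
  complete <- stats::complete.cases(df)
  df <- df[complete, ]
  y <- as.integer(factor(df[[label_col]])) - 1L
  X <- as.matrix(df[, top, drop = FALSE])

  seeds <- derive_seeds(seed, n_repeats)
  folds <- lapply(seq_len(n_repeats), function(rep_i) {
    if (stratification == "segment") {
      stratified_folds(y, n_folds, seeds[rep_i])
    } else {
      grouped_folds(y, df[[subject_col]], n_folds, seeds[rep_i])
    }
  })

  out <- purrr::map_dfr(seq_along(top), function(k) {
    aucs <- unlist(lapply(folds, function(fold) {
      cv_auroc(X[, seq_len(k), drop = FALSE], y, fold)
    }))
    tibble::tibble(
      feature_count = k,
      auroc_mean = mean(aucs, na.rm = TRUE),
      auroc_sd = stats::sd(aucs, na.rm = TRUE),
      n_folds_used = sum(is.finite(aucs)),
      stratification = stratification,
      feature_added = top[k]
    )
  })
  class(out) <- c("ppg_eval_curve", class(out))
  out
}
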