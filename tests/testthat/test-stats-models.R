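test_that("AUROC agrees with an independent implementation and flips with labels", {
  skip_if_not_installed("pROC")
  set.seed(1)
  sc <- rnorm(200)
  y <- sc + rnorm(200) > 0
  ours <- auroc(sc, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(auroc(sc, !y), 1 - ours, tolerance = 1e-12)
})

test_that("group comparison recovers standardized mean differences", {
  set.seed(20)
  df <- tibble::tibble(
    group = rep(c("A", "B"), each = 200),
    meanHR = c(rnorm(200, 1, 1), rnorm(200, 0, 1))
  )
  gc <- group_compare(df, feature_cols = "meanHR", group_a = "A",
                      n_boot = 500, seed = 3)
  expect_equal(gc$cohens_d, 1, tolerance = 0.2)
  expect_lt(gc$mann_whitney_p, 1e-10)
  expect_true(gc$ci_lower <= gc$cohens_d && gc$cohens_d <= gc$ci_upper)

  # swapping group roles flips d, keeps p
  gc2 <- group_compare(df, feature_cols = "meanHR", group_a = "B",
                       n_boot = 500, seed = 3)
  expect_equal(gc2$cohens_d, -gc$cohens_d, tolerance = 1e-12)
  expect_equal(gc2$mann_whitney_p, gc$mann_whitney_p, tolerance = 1e-12)

  # identical groups: d = 0, p near 1
  df0 <- tibble::tibble(group = rep(c("A", "B"), each = 50),
                        meanHR = rep(rnorm(50), 2))
  gc0 <- group_compare(df0, feature_cols = "meanHR", n_boot = 200, seed = 1)
  expect_equal(gc0$cohens_d, 0)
  expect_gt(gc0$mann_whitney_p, 0.9)
})

test_that("forward selection finds a perfectly separating feature first", {
  set.seed(4)
  n <- 140
  df <- tibble::tibble(
    group = rep(c("A", "B"), each = n / 2),
    SPD = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 5, 0.3)),  # separates
    SDNN = rnorm(n), RMSSD = rnorm(n), PIP = rnorm(n)
  )
  rk <- rank_features(df, feature_set = c("SPD", "SDNN", "RMSSD", "PIP"),
                      n_folds = 5, n_repeats = 3, seed = 5)
  first <- dplyr::filter(rk$rankings, rank == 1)
  expect_true(all(first$feature == "SPD"))
  expect_identical(rk$top[1], "SPD")

  # determinism under a fixed seed
  rk2 <- rank_features(df, feature_set = c("SPD", "SDNN", "RMSSD", "PIP"),
                       n_folds = 5, n_repeats = 3, seed = 5)
  expect_identical(rk$rankings, rk2$rankings)
  expect_identical(rk$top, rk2$top)
})

test_that("PWD is never a ranking candidate for morph or combined sets", {
  expect_false("PWD" %in% feature_pool("morph"))
  expect_false("PWD" %in% feature_pool("combined"))
  expect_true("PWD" %in% morph_feature_names)
  expect_identical(length(feature_pool("hrv")), 30L)
})

test_that("incremental evaluation is at chance on pure noise", {
  set.seed(6)
  n <- 280
  df <- tibble::tibble(
    group = sample(rep(c("A", "B"), each = n / 2)),
    subject_id = rep(sprintf("s%02d", 1:28), each = 10),
    f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n)
  )
  ev <- evaluate_incremental(df, c("f1", "f2", "f3"), n_folds = 7,
                             n_repeats = 3, seed = 7)
  expect_true(all(abs(ev$auroc_mean - 0.5) < 0.1))
  expect_s3_class(ev, "ppg_eval_curve")
  expect_identical(ev$feature_count, 1:3)
})

test_that("participant-grouped folds keep each subject's segments together", {
  set.seed(8)
  n_subj <- 14
  df <- tibble::tibble(
    group = rep(c("A", "B"), each = n_subj / 2 * 20),
    subject_id = rep(sprintf("s%02d", 1:n_subj), each = 20),
    f1 = rnorm(n_subj * 20) + rep(rnorm(n_subj, sd = 2), each = 20)
  )
  y <- as.integer(factor(df$group)) - 1L
  ev_seg <- evaluate_incremental(df, "f1", n_folds = 7, n_repeats = 3,
                                 stratification = "segment", seed = 9)
  ev_par <- evaluate_incremental(df, "f1", n_folds = 7, n_repeats = 3,
                                 stratification = "participant", seed = 9)
  # strong between-subject variance inflates the grouped-CV spread
  expect_gte(ev_par$auroc_sd, ev_seg$auroc_sd)
})

test_that("age trends are recovered by per-subject regression", {
  set.seed(10)
  ages <- sample(20:40, 30, replace = TRUE)
  df <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:30), each = 2),
    age = rep(ages, each = 2),
    SPD = 2 * rep(ages, each = 2) + rnorm(60, 0, 0.01)
  )
  tr <- age_trend(df, feature_cols = "SPD")
  expect_equal(tr$slope, 2, tolerance = 0.05 / 2)
  expect_lt(tr$p_value, 1e-10)

  # averaging: a subject with segments 10 and 14 contributes 12
  df2 <- tibble::tibble(subject_id = c("a", "a", "b", "c"),
                        age = c(30, 30, 25, 35),
                        SPD = c(10, 14, 5, 7))
  per <- df2 |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(age = age[1], SPD = mean(SPD))
  expect_equal(per$SPD[per$subject_id == "a"], 12)
  expect_silent(age_trend(df2, feature_cols = "SPD"))

  expect_error(age_trend(dplyr::mutate(df2, age = 30), feature_cols = "SPD"),
               "constant")
})

test_that("night-to-night comparison mirrors the group comparison schema", {
  set.seed(11)
  df <- tibble::tibble(
    night = rep(c(1L, 2L), each = 100),
    meanHR = c(rnorm(100, 75), rnorm(100, 80))
  )
  cc <- condition_compare(df, feature_cols = "meanHR", n_boot = 200, seed = 1)
  gc <- group_compare(dplyr::rename(df, group = night),
                      feature_cols = "meanHR", group_a = 1L,
                      n_boot = 200, seed = 1)
  expect_identical(names(cc), names(gc))
  expect_lt(cc$cohens_d, 0)  # night 2 has the higher heart rate

  df1 <- dplyr::filter(df, night == 1)
  expect_error(condition_compare(df1, feature_cols = "meanHR"), "night")
})

test_that("tidiers and plots return the documented shapes", {
  set.seed(12)
  df <- tibble::tibble(
    group = rep(c("A", "B"), each = 60),
    f1 = c(rnorm(60), rnorm(60, 3)), f2 = rnorm(120)
  )
  rk <- rank_features(df, feature_set = c("f1", "f2"), n_folds = 4,
                      n_repeats = 2, seed = 1)
  td <- tidy(rk)
  expect_true(all(c("feature", "borda", "mean_rank", "top") %in% names(td)))
  gl <- glance(rk)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$top_feature, rk$top[1])

  ev <- evaluate_incremental(df, rk$top, n_folds = 4, n_repeats = 2, seed = 1)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_identical(glance(ev)$best_auroc, max(ev$auroc_mean))

  p <- cohort_params("A")
  ib <- filter_ibis(generate_ibi_series(p, 120, seed = 1))
  expect_s3_class(autoplot(ib), "ggplot")
})
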