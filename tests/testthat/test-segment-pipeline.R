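test_that("segment windowing follows the tiling rules", {
  # 8-h full-night recording: 96 candidate segments
  segs <- window_segments(8 * 3600)
  expect_identical(nrow(segs), 96L)
  expect_true(all(segs$end_s - segs$start_s == 300))
  expect_true(all(diff(segs$start_s) == 300))

  # stage mode: runs shorter than 10 epochs yield nothing
  mk_hyp <- function(stages) tibble::tibble(
    epoch = seq_along(stages) - 1L,
    start_s = (seq_along(stages) - 1L) * 30,
    stage = factor(stages, levels = c("N1/N2", "N3", "REM", "Wake"))
  )
  h7 <- mk_hyp(c(rep("Wake", 5), rep("N3", 7), rep("Wake", 5)))
  expect_identical(nrow(window_segments(17 * 30, h7, "N3")), 0L)

  # a 25-epoch run gives floor(750/300) = 2 segments
  h25 <- mk_hyp(c(rep("Wake", 4), rep("N3", 25), rep("N1/N2", 4)))
  s25 <- window_segments(33 * 30, h25, "N3")
  expect_identical(nrow(s25), 2L)
  expect_equal(s25$start_s, c(4 * 30, 4 * 30 + 300))

  # Wake is never a target stage
  expect_error(window_segments(3600, h25, "Wake"), "Wake")
})

test_that("quality gate applies strict 20% thresholds", {
  clean <- quality_gate(rep(FALSE, 9600), rep(TRUE, 300))
  expect_true(clean$accepted)

  # 70 s of artifact in 300 s = 23.3% masked: rejected
  m <- rep(FALSE, 300 * 32); m[seq_len(70 * 32)] <- TRUE
  expect_false(quality_gate(m, rep(TRUE, 300))$accepted)

  # 19% masked and 19% invalid: both strictly below, accepted
  m19 <- rep(FALSE, 1000); m19[seq_len(190)] <- TRUE
  v19 <- rep(TRUE, 1000); v19[seq_len(190)] <- FALSE
  expect_true(quality_gate(m19, v19)$accepted)

  # exactly 20% is rejected
  m20 <- rep(FALSE, 1000); m20[seq_len(200)] <- TRUE
  expect_false(quality_gate(m20, rep(TRUE, 100))$accepted)
})

test_that("extract_features emits the full 67-feature catalogue", {
  p <- noiseless_params(mean_hr = 60, rmssd_target = 25, recording_hours = 1 / 6)
  subj <- simulate_subject(p, "S1", seed = 3)
  ft <- extract_features(subj$record[[1]], fs = 32,
                         metadata = list(subject_id = "S1"))
  expect_identical(nrow(ft), 2L)  # 10 min -> two 5-min segments
  expect_true(all(ft$accepted))
  expect_identical(intersect(all_feature_names, names(ft)), all_feature_names)
  expect_length(intersect(all_feature_names, names(ft)), 67L)

  # meanHR within 0.5 bpm of the generator ground truth
  gt_hr <- 60000 / mean(subj$ground_truth[[1]]$ibi_ms)
  expect_lt(max(abs(ft$meanHR - gt_hr)), 0.5)
})

test_that("feature extraction is deterministic", {
  p <- noiseless_params(recording_hours = 1 / 6)
  subj <- simulate_subject(p, "S1", seed = 9)
  f1 <- extract_features(subj$record[[1]], fs = 32)
  f2 <- extract_features(subj$record[[1]], fs = 32)
  expect_identical(f1, f2)
})

test_that("stage-stratified extraction uses only single-stage runs", {
  p <- cohort_params("A", recording_hours = 1, artifact_rate = 0)
  subj <- simulate_subject(p, "S1", seed = 13)
  hyp <- subj$hypnogram[[1]]
  ft <- extract_features(subj$record[[1]], fs = 32, hypnogram = hyp,
                         stages = c("full", "N1/N2"))
  expect_true(all(c("full", "N1/N2") %in% ft$stage |
                    all(ft$stage == "full")))
  # every stage-mode segment lies inside one same-stage epoch run
  st <- ft[ft$stage == "N1/N2", ]
  if (nrow(st)) {
    for (i in seq_len(nrow(st))) {
      ep <- hyp$stage[hyp$start_s >= st$start_s[i] &
                        hyp$start_s < st$start_s[i] + 300]
      expect_true(all(ep == "N1/N2"))
    }
  }
})

test_that("segments with heavy artifacts are gated out", {
  p <- cohort_params("A", recording_hours = 1 / 6, noise_sd = 0.02,
                     artifact_rate = 0)
  subj <- simulate_subject(p, "S1", seed = 17)
  rec <- subj$record[[1]]
  # inject a 70-s burst into the first segment
  idx <- which(rec$time_s >= 100 & rec$time_s < 170)
  set.seed(1)
  rec$ppg[idx] <- rec$ppg[idx] + runif(length(idx), -5, 5)
  ft <- extract_features(rec, fs = 32)
  expect_false(ft$accepted[1])
  expect_gt(ft$fraction_masked[1], 0.2)
  expect_true(ft$accepted[2])
})

test_that("record and feature-table round trips preserve data", {
  p <- noiseless_params(recording_hours = 1 / 6)
  subj <- simulate_subject(p, "S1", seed = 21)
  tmp <- withr::local_tempdir()
  rp <- file.path(tmp, "rec.csv")
  write_ppg_record(subj$record[[1]], rp,
                   metadata = list(fs = 32, subject_id = "S1", group = "A"))
  back <- read_ppg_record(rp)
  expect_equal(back$ppg, subj$record[[1]]$ppg, tolerance = 1e-12)
  expect_equal(attr(back, "fs"), 32)

  hp <- file.path(tmp, "hyp.csv")
  write_hypnogram(subj$hypnogram[[1]], hp)
  hback <- read_hypnogram(hp)
  expect_identical(as.character(hback$stage),
                   as.character(subj$hypnogram[[1]]$stage))

  ft <- extract_features(subj$record[[1]], fs = 32,
                         metadata = list(subject_id = "S1"))
  fp <- file.path(tmp, "features.csv")
  write_feature_table(ft, fp)
  fback <- read_feature_table(fp)
  expect_equal(fback$meanHR, ft$meanHR, tolerance = 1e-9)
  expect_identical(nrow(fback), nrow(ft))
})
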