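test_that("degenerate generator yields exactly constant IBIs", {
  p <- cohort_params("A", mean_hr = 60, rmssd_target = 0)
  ib <- generate_ibi_series(p, 120, seed = 1)
  expect_true(all(ib$ibi_ms[!is.na(ib$ibi_ms)] == 1000))
})

test_that("IBI generator hits its mean and RMSSD targets", {
  p <- cohort_params("A", mean_hr = 75, rmssd_target = 40)
  ib <- generate_ibi_series(p, 600, seed = 42)
  expect_equal(mean(ib$ibi_ms, na.rm = TRUE), 800, tolerance = 0.02)
  v <- ib$ibi_ms[!is.na(ib$ibi_ms)]
  rmssd <- sqrt(mean(diff(v)^2))  # independent time-domain formula
  expect_lt(abs(rmssd - 40) / 40, 0.15)
})

test_that("generator is deterministic and validates parameters", {
  p <- cohort_params("A")
  expect_identical(generate_ibi_series(p, 120, seed = 7),
                   generate_ibi_series(p, 120, seed = 7))
  bad <- p; bad$mean_hr <- -10
  expect_error(generate_ibi_series(bad, 120, seed = 1), "mean_hr")
  expect_error(generate_ibi_series(p, 30, seed = 1), "duration")
})

test_that("pulse template honours its landmark contracts", {
  # single-component case: symmetric bell peaking at spd_fraction
  w <- synthesize_pulse_template(0.4, 0, n_samples = 200)
  expect_equal(which.max(w) - 1, 0.4 * 200, tolerance = 1 / 200 * 2)
  expect_equal(which.min(w), 1L)

  # boundary contract
  w16 <- synthesize_pulse_template(0.3, 0.4, 0.6, n_samples = 16)
  expect_length(w16, 16L)
  expect_equal(which.min(w16), 1L)

  # diastolic component before systolic is a parameter error
  expect_error(synthesize_pulse_template(0.5, 0.4, 0.3), "diastolic")
})

test_that("template second derivative has its deepest trough then a notch max", {
  w <- synthesize_pulse_template(0.3, 0.4, 0.6, n_samples = 400)
  d2 <- attr(w, "deriv2")
  u <- seq(0, 1, length.out = 2001)
  d2u <- d2(u)
  u_b2 <- u[which.min(d2u)]
  # deepest trough of the analytic second derivative sits at the systolic bell
  expect_lt(abs(u_b2 - 0.3), 0.05)
  # a local maximum (the e-wave / notch) exists between the two components
  between <- u > u_b2 & u < 0.6
  expect_gt(max(d2u[between]), d2u[which.min(abs(u - u_b2))])
})

test_that("noiseless constant-IBI record is exactly periodic", {
  p <- noiseless_params(mean_hr = 60, rmssd_target = 0)
  ib <- generate_ibi_series(p, 120, seed = 1)
  rec <- synthesize_ppg(ib, p, seed = 1)
  x <- rec$record$ppg
  expect_equal(x[33:(length(x))], x[1:(length(x) - 32)], tolerance = 1e-12)
})

test_that("artifact windows are logged and reproducible", {
  p <- cohort_params("A", artifact_rate = 6, recording_hours = 1,
                     noise_sd = 0.02)
  ib <- generate_ibi_series(p, 3600, seed = 2)
  rec1 <- synthesize_ppg(ib, p, seed = 9)
  rec2 <- synthesize_ppg(ib, p, seed = 9)
  expect_identical(rec1$ground_truth$artifact_windows,
                   rec2$ground_truth$artifact_windows)
  expect_identical(rec1$record, rec2$record)
  n_art <- nrow(rec1$ground_truth$artifact_windows)
  expect_gte(n_art, 1)
  expect_true(all(rec1$ground_truth$artifact_windows$end_s <=
                    rec1$ground_truth$duration_s))
})

test_that("synthesize_ppg rejects empty input", {
  p <- cohort_params("A")
  empty <- tibble::tibble(beat_time_s = numeric(0), ibi_ms = numeric(0))
  expect_error(synthesize_ppg(empty, p), "empty")
})

test_that("hypnograms cover the night with realistic stage prevalence", {
  h <- generate_hypnogram(8, seed = 1)
  expect_identical(nrow(h), 960L)

  # expected stage shares over repeated nights follow the chain's
  # stationary distribution: N1/N2 > N3 > REM
  shares <- sapply(1:100, function(s) {
    h <- generate_hypnogram(1, seed = s)
    table(h$stage)[c("N1/N2", "N3", "REM")] / nrow(h)
  })
  m <- rowMeans(shares)
  expect_gt(m["N1/N2"], m["N3"])
  expect_gt(m["N3"], m["REM"])

  # independent oracle: stationary distribution of the transition matrix
  P <- hypnogram_transition_matrix()
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  expect_gt(v[1], v[2])  # N1/N2 > N3
  expect_gt(v[2], v[3])  # N3 > REM
})

test_that("an all-wake hypnogram yields no sleep segments", {
  allwake <- diag(4)[c(4, 4, 4, 4), ]
  dimnames(allwake) <- dimnames(hypnogram_transition_matrix())
  h <- generate_hypnogram(8, seed = 1, transition = allwake)
  for (st in c("N1/N2", "N3", "REM")) {
    expect_identical(nrow(window_segments(8 * 3600, h, st)), 0L)
  }
})

test_that("subject simulation is reproducible end to end", {
  p <- cohort_params("A", recording_hours = 0.1)
  s1 <- simulate_subject(p, "A01", seed = 5)
  s2 <- simulate_subject(p, "A01", seed = 5)
  expect_identical(s1$record, s2$record)
  expect_identical(s1$hypnogram, s2$hypnogram)
  expect_identical(s1$ground_truth, s2$ground_truth)
})
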