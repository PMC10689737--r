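test_that("IBI screening applies the range and 20% rules", {
  # 25% jump invalidates the middle interval; the 20% comparison then uses
  # the last valid interval
  ib <- filter_ibis(ibis_from_values(c(800, 1000, 800)))
  expect_identical(ib$valid[1:3], c(TRUE, FALSE, TRUE))

  # 18.75% change is allowed
  ib <- filter_ibis(ibis_from_values(c(800, 950)))
  expect_identical(ib$valid[1:2], c(TRUE, TRUE))

  # range rule
  ib <- filter_ibis(ibis_from_values(c(250, 800)))
  expect_identical(ib$valid[1:2], c(FALSE, TRUE))
  ib <- filter_ibis(ibis_from_values(c(800, 2500, 800)))
  expect_false(ib$valid[2])
})

test_that("on-time interpolation restores deleted beats", {
  # identity when nothing is missing
  ib <- filter_ibis(ibis_from_values(rep(1000, 50)))
  out <- interpolate_ontime(ib)
  expect_false(any(out$interpolated))
  expect_equal(out$ibi_ms, rep(1000, 50), tolerance = 1e-12)

  # one beat deleted from a constant train: restored within 1 ms
  bt <- seq(0, 49) * 1
  bt_miss <- bt[-25]
  ib <- tibble::tibble(beat_time_s = bt_miss,
                       ibi_ms = c(diff(bt_miss) * 1000, NA))
  ib <- filter_ibis(ib)
  out <- interpolate_ontime(ib)
  restored <- out$beat_time_s[out$interpolated]
  expect_length(restored, 1L)
  expect_lt(abs(restored - bt[25]) * 1000, 1)

  # two adjacent deletions in a linear IBI ramp: restored within 5 ms
  ibi_ramp <- seq(800, 800 + 59 * 4, by = 4)
  bt <- c(0, cumsum(ibi_ramp)) / 1000
  keep <- setdiff(seq_along(bt), c(30, 31))
  ibm <- tibble::tibble(beat_time_s = bt[keep],
                        ibi_ms = c(diff(bt[keep]) * 1000, NA))
  ibm <- filter_ibis(ibm)
  out <- interpolate_ontime(ibm)
  restored <- out$beat_time_s[out$interpolated]
  expect_length(restored, 2L)
  expect_lt(max(abs(restored - bt[c(30, 31)])) * 1000, 5)

  # long gaps mark the series unusable for continuous features
  bt_gap <- c(seq(0, 20), seq(35, 55))
  ibg <- filter_ibis(tibble::tibble(beat_time_s = bt_gap,
                                    ibi_ms = c(diff(bt_gap) * 1000, NA)))
  expect_false(attr(interpolate_ontime(ibg), "usable"))
})

test_that("time-domain features match hand values", {
  ib <- filter_ibis(ibis_from_values(rep(1000, 20)))
  td <- time_domain(ib)
  expect_equal(td$meanHR, 60)
  expect_equal(td$SDNN, 0)
  expect_equal(td$RMSSD, 0)
  expect_equal(td$pNN50, 0)

  ib <- filter_ibis(ibis_from_values(c(800, 850, 800, 850)))
  td <- time_domain(ib)
  expect_equal(td$RMSSD, 50)
  expect_equal(td$pNN50, 0)  # strict inequality: diffs equal 50, not > 50

  ib <- filter_ibis(ibis_from_values(c(800, 851, 800, 851)))
  expect_equal(time_domain(ib)$pNN50, 100)
})

test_that("frequency features concentrate single-tone power correctly", {
  mk <- function(f, dur = 300) {
    t <- 0; bt <- c(); v <- c()
    while (t < dur) {
      bt <- c(bt, t); ib <- 1000 + 50 * sin(2 * pi * f * t)
      v <- c(v, ib); t <- t + ib / 1000
    }
    filter_ibis(ibis_from_values(v))
  }
  fd <- frequency_domain(interpolate_ontime(mk(0.1)))
  expect_gt(fd$LFnu, 0.9)
  expect_equal(fd$LFnu + fd$HFnu, 1)

  fd <- frequency_domain(interpolate_ontime(mk(0.25)))
  expect_gt(fd$HFnu, 0.9)
  expect_equal(fd$LFnu + fd$HFnu, 1)

  # constant IBIs: no oscillatory power, ratio undefined
  fd0 <- frequency_domain(interpolate_ontime(
    filter_ibis(ibis_from_values(rep(1000, 400)))))
  expect_lt(fd0$LF + fd0$HF, 1e-6)
  expect_true(is.na(fd0$LF_HF))
})

test_that("Poincare features obey their algebraic identities", {
  ib <- filter_ibis(ibis_from_values(c(800, 850, 800, 850)))
  pc <- poincare(ib)
  expect_equal(pc$SD1, 50 / sqrt(2))
  expect_equal(pc$S, pi * pc$SD1 * pc$SD2)

  pc0 <- poincare(filter_ibis(ibis_from_values(rep(900, 10))))
  expect_equal(pc0$SD1, 0)
  expect_equal(pc0$SD2, 0)
  expect_equal(pc0$S, 0)

  # SD1 = RMSSD / sqrt(2) on arbitrary series
  set.seed(8)
  for (i in 1:10) {
    v <- 800 + cumsum(rnorm(60, 0, 15))
    ib <- filter_ibis(ibis_from_values(v))
    expect_lt(abs(poincare(ib)$SD1 - time_domain(ib)$RMSSD / sqrt(2)), 1e-9)
  }
})

test_that("DFA alpha1 matches the analytic white-noise expectation", {
  # exact DFA-1 expectation for uncorrelated noise:
  # E[F^2(n)] = sigma^2 (n^2 - 4) / (15 n); the implied slope over boxes
  # 4..16 is ~0.583 (the asymptotic 0.5 holds only for large boxes)
  ns <- 4:16
  theory_slope <- unname(stats::coef(
    stats::lm(log(sqrt((ns^2 - 4) / (15 * ns))) ~ log(ns)))[2])
  a <- vapply(1:20, function(s) {
    set.seed(s)
    dfa_alpha1(rnorm(1000, 1000, 30))
  }, numeric(1))
  expect_equal(mean(a), theory_slope, tolerance = 0.05 / theory_slope)

  set.seed(21)
  white <- rnorm(1000, 1000, 30)
  walk <- 1000 + cumsum(rnorm(1000, 0, 5))
  expect_gt(dfa_alpha1(walk), 1)
  expect_gt(dfa_alpha1(walk), dfa_alpha1(white))
  # invariant to adding a constant
  expect_equal(dfa_alpha1(white + 500), dfa_alpha1(white))
  expect_true(is.na(dfa_alpha1(rnorm(50))))
})

test_that("sample entropy matches the brute-force oracle exactly", {
  set.seed(31)
  x <- rnorm(200, 1000, 25)
  expect_identical(sample_entropy(x), sampen_brute(x))

  # strictly periodic period-2 series: every match extends
  xp <- rep(c(900, 1000), 60)
  expect_equal(sample_entropy(xp), 0)

  # affine invariance
  expect_equal(sample_entropy(3 * x + 100), sample_entropy(x))
  expect_true(is.na(sample_entropy(rep(1, 200))))
})

test_that("PRSA matches the brute-force oracle and hand values", {
  # constant series: no anchors, all features missing
  expect_true(all(is.na(prsa(rep(1000, 200)))))

  # alternating series: averaged deceleration waveform gives DC = 0
  xa <- rep(c(800, 900), 120)
  expect_equal(prsa(xa)$DC, 0)

  # waveform equals the naive anchor-stacking oracle on a random series
  set.seed(41)
  x <- 900 + cumsum(rnorm(500, 0, 10))
  dec_anchors <- which(diff(x) > 0) + 1L
  dec_anchors <- dec_anchors[dec_anchors > 50 & dec_anchors + 49 <= length(x)]
  expect_equal(prsa_waveform(x, dec_anchors, 50),
               prsa_waveform_brute(x, "dec", 50), tolerance = 1e-12)

  # features derived from that waveform
  pr <- prsa(x)
  Xd <- prsa_waveform_brute(x, "dec", 50)
  k <- seq(-50, 49)
  expect_equal(pr$DC, (Xd[k == 0] + Xd[k == 1] - Xd[k == -1] - Xd[k == -2]) / 4)
  imm <- Xd[k >= -5 & k <= 4]
  expect_equal(pr$IDR, max(imm) - min(imm))
  expect_equal(pr$ADR, mean(Xd[k < 0]) - mean(Xd[k >= 0]))
})

test_that("fragmentation indices match the run-length oracle", {
  # strictly increasing: one long run
  inc <- seq(800, 800 + 49 * 2, by = 2)
  fr <- fragmentation(inc)
  expect_equal(fr$PIP, 0)
  expect_equal(fr$IALS, 1 / 49)
  expect_equal(fr$PSS, 0)

  # perfectly alternating
  alt <- rep(c(800, 900), 25)
  fr <- fragmentation(alt)
  expect_gt(fr$PIP, 90)
  expect_equal(fr$PAS, 100)

  # all increments zero
  fr0 <- fragmentation(rep(1000, 30))
  expect_equal(fr0$PIP, 0)
  expect_equal(fr0$PSS, 100)
  expect_equal(fr0$PAS, 0)
  expect_true(is.na(fr0$IALS))

  # random series vs brute force
  set.seed(51)
  for (i in 1:5) {
    v <- 900 + round(cumsum(rnorm(80, 0, 12)))
    fr <- fragmentation(v)
    or <- hrf_brute(v)
    expect_equal(fr$PIP, or$PIP)
    expect_equal(fr$PSS, or$PSS)
    expect_equal(fr$PAS, or$PAS)
    expect_equal(fr$IALS, or$IALS)
  }
})

test_that("HRV features are invariant to a global time shift", {
  p <- cohort_params("A")
  ib <- generate_ibi_series(p, 300, seed = 61)
  h1 <- hrv_features(ib)
  ib2 <- ib; ib2$beat_time_s <- ib2$beat_time_s + 1234
  h2 <- hrv_features(ib2)
  expect_equal(h1, h2, tolerance = 1e-9)
})

test_that("the HRV wrapper emits all 30 catalogued features", {
  p <- cohort_params("A")
  ib <- generate_ibi_series(p, 300, seed = 71)
  h <- hrv_features(ib)
  expect_identical(names(h), hrv_feature_names)
  core <- setdiff(hrv_feature_names, c("LF_HF"))
  expect_true(all(!is.na(h[, core])))
})
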