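# Pulse-wave morphology features. Time intervals come from fiducial index
# differences over fs; areas are trapezoidal integrals above the straight
# baseline joining the IT and FT amplitudes; widths at x% of the pulse
# amplitude use linear sub-sample interpolation of the level crossings.

# time of the level crossing nearest the systolic peak on the rising
# (dir = 1) or falling (dir = -1) edge; idx are global indices
level_crossing <- function(x, level, sp, bound, dir) {
  if (dir > 0) {
    rng <- sp:bound   # scan left from SP towards IT
    below <- which(x[rng] < level)
    if (!length(below)) return(NA_real_)
    j <- rng[below[1L]]          # first sample below the level, left of SP
    hi <- j + 1L                 # x[hi] >= level > x[j]
    j + (level - x[j]) / (x[hi] - x[j]) - 1  # 0-based fractional index
  } else {
    rng <- sp:bound   # scan right from SP towards FT
    below <- which(x[rng] < level)
    if (!length(below)) return(NA_real_)
    j <- rng[below[1L]]          # first sample below the level, right of SP
    lo <- j - 1L                 # x[lo] >= level > x[j]
    lo + (x[lo] - level) / (x[lo] - x[j]) - 1
  }
}

#' Morphology features for each pulse
#'
#' Computes the 37 pulse-wave morphology features (see
#' [morph_feature_names]) per valid pulse. Features whose derivative
#' landmark is missing are `NA` for that pulse; the rest are still
#' computed. Angles are measured on the amplitude-normalized pulse (pulse
#' wave amplitude scaled to 1) so they do not depend on signal units.
#'
#' @param pulses A `pulse_set` with fiducial columns (see
#'   [detect_pulses()]).
#' @param x The filtered signal.
#' @param fs Sampling rate, Hz.
#' @param derivs Optional precomputed [pulse_derivatives()].
#' @return Tibble with `pulse_idx` plus the 37 feature columns, one row per
#'   valid pulse.
#' @export
pulse_morphology <- function(pulses, x, fs = attr(pulses, "fs"),
                             derivs = NULL) {
  if (!"a1" %in% names(pulses)) {
    stop("run detect_pulses()/locate_derivative_fiducials() first", call. = FALSE)
  }
  if (is.null(derivs)) derivs <- pulse_derivatives(x, fs)
  d1 <- derivs$d1; d2 <- derivs$d2

  rows <- vector("list", nrow(pulses))
  for (i in seq_len(nrow(pulses))) {
    if (!pulses$valid[i]) next
    it <- pulses$IT[i]; sp <- pulses$SP[i]; ft <- pulses$FT[i]
    a1 <- pulses$a1[i]; b1 <- pulses$b1[i]
    a2 <- pulses$a2[i]; b2 <- pulses$b2[i]; e2 <- pulses$e2[i]

    f <- stats::setNames(rep(NA_real_, length(morph_feature_names)),
                         morph_feature_names)

    pwa <- x[sp] - x[it]
    f["PWA"] <- pwa
    f["PWD"] <- (ft - it) / fs
    f["SPD"] <- (sp - it) / fs
    f["DPD"] <- (ft - sp) / fs

    if (!is.na(a1)) {
      f["t_a1"] <- (a1 - it) / fs
      f["t_s"] <- (sp - a1) / fs
      f["MSV"] <- d1[a1]
      if (!is.na(b1)) f["t_a1b1"] <- (b1 - a1) / fs
    }
    if (!is.na(a2) && !is.na(b2)) {
      f["t_a2b2"] <- (b2 - a2) / fs
      f["b2_amplitude"] <- abs(d2[b2])
      if (abs(d2[a2]) > 0) f["b2_a2"] <- abs(d2[b2]) / abs(d2[a2])
      if (!is.na(e2)) {
        f["t_b2e2"] <- (e2 - b2) / fs
        if (abs(d2[a2]) > 0) f["e2_a2"] <- abs(d2[e2]) / abs(d2[a2])
      }
    }

    # areas above the IT-FT baseline
    seg <- it:ft
    base <- x[it] + (x[ft] - x[it]) * (seg - it) / (ft - it)
    xa <- x[seg] - base
    tt <- (seg - it) / fs
    f["AUC_total"] <- pracma::trapz(tt, xa)
    f["AUC1"] <- pracma::trapz(tt[seg <= sp], xa[seg <= sp])
    f["AUC2"] <- pracma::trapz(tt[seg >= sp], xa[seg >= sp])

    f["mean_V"] <- mean(d1[seg])
    qs <- stats::quantile(d1[seg], c(0.1, 0.9), names = FALSE)
    f["IDR_V"] <- qs[2] - qs[1]
    f["mean_Acc"] <- mean(d2[seg])
    f["SFV"] <- d1[it]
    f["EDV"] <- d1[ft]
    if (!is.na(f["MSV"]) && is.finite(f["mean_V"]) && f["mean_V"] != 0) {
      f["pulsatility_index"] <- (f["MSV"] - f["EDV"]) / f["mean_V"]
    }

    # widths at 10/25/50/60% of PWA above the IT amplitude
    for (lv in c(10, 25, 50, 60)) {
      level <- x[it] + lv / 100 * pwa
      tr <- level_crossing(x, level, sp, it, dir = 1)
      tf <- level_crossing(x, level, sp, ft, dir = -1)
      if (!is.na(tr) && !is.na(tf)) {
        sw <- (sp - 1 - tr) / fs
        dw <- (tf - (sp - 1)) / fs
        if (sw > 0) f[sprintf("DW%d_SW%d", lv, lv)] <- dw / sw
      }
    }

    pwd <- f[["PWD"]]
    f["t_s_PWD"] <- f[["t_s"]] / pwd
    f["t_a1_PWD"] <- f[["t_a1"]] / pwd
    f["t_a1b1_PWD"] <- f[["t_a1b1"]] / pwd
    f["t_a2b2_PWD"] <- f[["t_a2b2"]] / pwd
    f["t_b2e2_PWD"] <- f[["t_b2e2"]] / pwd
    f["SPD_PWD"] <- f[["SPD"]] / pwd
    f["SP_SPD"] <- x[sp] / f[["SPD"]]

    f["slope_IT_SP"] <- (x[sp] - x[it]) / f[["SPD"]]
    f["slope_SP_FT"] <- (x[ft] - x[sp]) / f[["DPD"]]
    if (pwa > 0) {
      f["alpha_angle"] <- atan((x[sp] - x[it]) / pwa / f[["SPD"]]) * 180 / pi
      f["gamma_angle"] <- atan((x[ft] - x[sp]) / pwa / f[["DPD"]]) * 180 / pi
    }

    rows[[i]] <- tibble::as_tibble_row(c(pulse_idx = pulses$pulse_idx[i], f))
  }
  dplyr::bind_rows(rows)
}

#' Aggregate per-pulse morphology over a segment
#'
#' Per-feature arithmetic mean over the segment's valid pulses, ignoring
#' missing per-pulse values. Segments with fewer than `min_pulses` valid
#' pulses yield all-`NA` morphology.
#'
#' @param per_pulse Output of [pulse_morphology()].
#' @param min_pulses Minimum number of valid pulses.
#' @return One-row tibble of the 37 features plus `n_pulses`.
#' @export
aggregate_segment_morphology <- function(per_pulse, min_pulses = 10) {
  out <- stats::setNames(
    as.list(rep(NA_real_, length(morph_feature_names))), morph_feature_names
  )
  n <- nrow(per_pulse)
  if (!is.null(per_pulse) && n >= min_pulses) {
    for (nm in morph_feature_names) {
      v <- per_pulse[[nm]]
      out[[nm]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  dplyr::bind_cols(tibble::as_tibble(out), tibble::tibble(n_pulses = n))
}
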