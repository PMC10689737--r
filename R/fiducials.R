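# Fiducial points on the pulse wave and its derivatives (naming follows the
# PPG literature): a1/b1 on the first derivative (velocity); a2/b2/e2 on the
# second derivative (acceleration), where a2 is the early acceleration
# maximum, b2 the deepest acceleration trough and e2 the local acceleration
# maximum at the notch between systolic and diastolic peaks.

#' Signal derivatives for fiducial detection
#'
#' First derivative by central differences; the second derivative is the
#' central difference of the 3-point-smoothed first derivative. At 32 Hz,
#' raw second differences are too noisy for landmark detection, hence the
#' light smoothing.
#'
#' @param x Filtered PPG signal.
#' @param fs Sampling rate, Hz.
#' @return List with `d1`, `d2` (same length as `x`, units amplitude/s and
#'   amplitude/s^2).
#' @export
pulse_derivatives <- function(x, fs) {
  n <- length(x)
  if (n < 5) stop("signal too short for derivatives", call. = FALSE)
  d1 <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * fs
  d1s <- as.numeric(stats::filter(d1, rep(1 / 3, 3), sides = 2))
  d1s[1] <- d1[1]; d1s[n] <- d1[n]
  d2 <- c(d1s[2] - d1s[1], (d1s[3:n] - d1s[1:(n - 2)]) / 2,
          d1s[n] - d1s[n - 1]) * fs
  list(d1 = d1, d2 = d2)
}

#' Locate derivative fiducial points for each pulse
#'
#' For every valid pulse: `a1` is the first-derivative maximum in
#' `(IT, SP)`; `b1` the first local minimum of the first derivative after
#' `a1`; `a2` the first local maximum of the second derivative after `IT`;
#' `b2` the global minimum of the second derivative in `(a2, FT)`; `e2` the
#' first local maximum of the second derivative after `b2` (the notch
#' between systolic and diastolic peaks); `EDV` the first-derivative value
#' at the final trough. Landmarks that cannot be found are `NA`; the pulse
#' stays valid as long as IT, SP and FT are present. Ties and plateaus
#' resolve to the earliest index.
#'
#' @param pulses A `pulse_set` from [segment_pulses()].
#' @param x The filtered signal the pulses were segmented from.
#' @param fs Sampling rate, Hz.
#' @param derivs Optional precomputed [pulse_derivatives()] (computed once
#'   and shared by all consumers).
#' @return `pulses` with integer columns `a1`, `b1`, `a2`, `b2`, `e2`
#'   (global sample indices) and numeric `EDV`.
#' @export
locate_derivative_fiducials <- function(pulses, x, fs = attr(pulses, "fs"),
                                        derivs = NULL) {
  if (is.null(derivs)) derivs <- pulse_derivatives(x, fs)
  d1 <- derivs$d1; d2 <- derivs$d2
  n <- nrow(pulses)
  a1 <- b1 <- a2 <- b2 <- e2 <- rep(NA_integer_, n)
  edv <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    if (!pulses$valid[i]) next
    it <- pulses$IT[i]; sp <- pulses$SP[i]; ft <- pulses$FT[i]

    # a1: max of d1 strictly inside the upstroke
    up <- if (sp - it >= 2L) (it + 1L):(sp - 1L) else it:sp
    a1[i] <- up[which_max1(d1[up])]

    # b1: first local minimum of d1 after a1 (within the pulse)
    if (ft - a1[i] >= 2L) {
      seg <- a1[i]:ft
      mins <- local_minima(d1[seg])
      if (length(mins)) b1[i] <- seg[mins[1L]]
    }

    # a2: first local maximum of d2 after IT
    if (ft - it >= 2L) {
      seg <- it:ft
      maxs <- local_maxima(d2[seg])
      if (length(maxs)) a2[i] <- seg[maxs[1L]]
    }

    # b2: global minimum of d2 in (a2, FT)
    if (!is.na(a2[i]) && ft - a2[i] >= 2L) {
      seg <- (a2[i] + 1L):(ft - 1L)
      b2[i] <- seg[which_min1(d2[seg])]
    }

    # e2: first local maximum of d2 after b2 (before the final trough,
    # whose junction curvature would otherwise dominate)
    if (!is.na(b2[i]) && ft - b2[i] >= 3L) {
      seg <- b2[i]:(ft - 1L)
      maxs <- local_maxima(d2[seg])
      if (length(maxs)) e2[i] <- seg[maxs[1L]]
    }

    edv[i] <- d1[ft]
  }

  pulses$a1 <- a1; pulses$b1 <- b1; pulses$a2 <- a2
  pulses$b2 <- b2; pulses$e2 <- e2; pulses$EDV <- edv
  pulses
}

#' Refine systolic peaks against the second-derivative notch point e2
#'
#' Point e2 marks the notch between the systolic and diastolic peaks. A
#' candidate systolic peak at or after e2 has caught the diastolic peak; it
#' is redefined as the signal maximum between the initial trough and e2.
#' Pulses without a detectable e2 are kept unchanged. The operation is
#' idempotent.
#'
#' @param pulses Output of [locate_derivative_fiducials()].
#' @param x The filtered signal.
#' @return `pulses` with corrected `SP`.
#' @export
refine_systolic_peak <- function(pulses, x) {
  if (!"e2" %in% names(pulses)) {
    stop("run locate_derivative_fiducials() first", call. = FALSE)
  }
  bad <- which(pulses$valid & !is.na(pulses$e2) & pulses$SP >= pulses$e2)
  for (i in bad) {
    seg <- pulses$IT[i]:pulses$e2[i]
    pulses$SP[i] <- seg[which_max1(x[seg])]
    pulses$valid[i] <- pulses$IT[i] < pulses$SP[i] & pulses$SP[i] < pulses$FT[i]
  }
  pulses
}

#' Segment pulses and locate all fiducial points
#'
#' Convenience wrapper: [segment_pulses()], then derivative fiducials,
#' systolic-peak refinement against e2, and a final fiducial pass so that
#' a1/b1 are consistent with the refined systolic peak.
#'
#' @inheritParams segment_pulses
#' @return A `pulse_set` tibble with all fiducial columns.
#' @export
detect_pulses <- function(x, fs, mask = NULL) {
  pulses <- segment_pulses(x, fs, mask)
  if (!nrow(pulses)) {
    for (col in c("a1", "b1", "a2", "b2", "e2")) pulses[[col]] <- integer(0)
    pulses$EDV <- numeric(0)
    return(pulses)
  }
  derivs <- pulse_derivatives(x, fs)
  pulses <- locate_derivative_fiducials(pulses, x, fs, derivs)
  pulses <- refine_systolic_peak(pulses, x)
  locate_derivative_fiducials(pulses, x, fs, derivs)
}
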