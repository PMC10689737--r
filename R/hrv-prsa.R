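#' Phase-rectified signal averaging (PRSA) features
#'
#' Anchor points are beats whose IBI exceeds the previous one
#' (decelerations) or falls below it (accelerations). Around every anchor
#' with a full 50-beat wing on each side, the IBI series is aligned at the
#' anchor (k = 0) and averaged into the PRSA waveform X(k), k in -50..49.
#' From each waveform:
#' * capacity `DC`/`AC` = `(X(0) + X(1) - X(-1) - X(-2)) / 4` (the quarter
#'   formula of the PRSA literature), ms;
#' * immediate response `IDR`/`IAR` = max - min of X over k in -5..4, ms;
#' * response slope `SDR`/`SAR` = least-squares slope of X over k in -5..4,
#'   ms per beat;
#' * average response `ADR`/`AAR` = mean of the 50 values preceding the
#'   anchor minus mean of the 50 values from the anchor on, ms.
#'
#' A series with no qualifying anchors (e.g. constant IBIs) yields `NA`s.
#'
#' @param ibis An `ibi_series` with `valid` flags (or a numeric vector of
#'   intervals).
#' @param wing Beats required on each side of an anchor.
#' @return One-row tibble `DC`, `AC`, `IDR`, `IAR`, `SDR`, `SAR`, `ADR`,
#'   `AAR`.
#' @export
prsa <- function(ibis, wing = 50) {
  x <- if (is.numeric(ibis)) ibis else ibis$ibi_ms[ibis$valid]
  out <- tibble::tibble(DC = NA_real_, AC = NA_real_, IDR = NA_real_,
                        IAR = NA_real_, SDR = NA_real_, SAR = NA_real_,
                        ADR = NA_real_, AAR = NA_real_)
  n <- length(x)
  if (n < 2 * wing + 2) return(out)

  feats <- function(anchors) {
    anchors <- anchors[anchors > wing & anchors + wing - 1 <= n]
    if (!length(anchors)) return(NULL)
    X <- prsa_waveform(x, anchors, wing)
    k <- seq(-wing, wing - 1L)
    at <- function(kk) X[match(kk, k)]
    imm <- X[k >= -5 & k <= 4]
    list(
      cap = (at(0) + at(1) - at(-1) - at(-2)) / 4,
      idr = max(imm) - min(imm),
      sdr = unname(stats::coef(stats::lm(imm ~ seq(-5, 4)))[2]),
      adr = mean(X[k < 0]) - mean(X[k >= 0])
    )
  }

  dec <- feats(which(diff(x) > 0) + 1L)
  acc <- feats(which(diff(x) < 0) + 1L)
  if (!is.null(dec)) {
    out$DC <- dec$cap; out$IDR <- dec$idr; out$SDR <- dec$sdr; out$ADR <- dec$adr
  }
  if (!is.null(acc)) {
    out$AC <- acc$cap; out$IAR <- acc$idr; out$SAR <- acc$sdr; out$AAR <- acc$adr
  }
  out
}

#' Averaged PRSA waveform
#'
#' @param x Numeric IBI series.
#' @param anchors Anchor indices into `x` (each with full wings).
#' @param wing Wing length in beats.
#' @return Numeric vector X(k) for k in `-wing .. wing - 1`, with X(0) the
#'   mean IBI at the anchors.
#' @export
prsa_waveform <- function(x, anchors, wing = 50) {
  offs <- seq(-wing, wing - 1L)
  mat <- vapply(anchors, function(a) x[a + offs], numeric(length(offs)))
  rowMeans(mat)
}

#' Heart rate fragmentation indices
#'
#' Computed on the sign sequence of the IBI increments (delta NN): a zero
#' increment terminates a run and is not an inflection.
#' * `PIP`: inflection points (strict sign flips between consecutive nonzero
#'   increments) as a percentage of the number of IBIs.
#' * `PSS`: percentage of increments lying in segments (maximal
#'   constant-sign runs; zero increments count as length-1 segments) of
#'   length < 3.
#' * `PAS`: percentage of increments lying in alternation segments (maximal
#'   runs of consecutive sign flips) of length >= 4.
#' * `IALS`: inverse of the mean length of the maximal nonzero-sign runs
#'   (`NA` when no nonzero increments exist).
#'
#' @param ibis An `ibi_series` with `valid` flags (or a numeric vector).
#' @param min_beats Minimum number of valid IBIs.
#' @return One-row tibble `PIP`, `PAS`, `PSS`, `IALS` (percent, percent,
#'   percent, 1/beats).
#' @export
fragmentation <- function(ibis, min_beats = 20) {
  x <- if (is.numeric(ibis)) ibis else ibis$ibi_ms[ibis$valid]
  out <- tibble::tibble(PIP = NA_real_, PAS = NA_real_, PSS = NA_real_,
                        IALS = NA_real_)
  n <- length(x)
  if (n < min_beats) return(out)
  s <- sign(diff(x))
  m <- length(s)

  # inflection points: strict flips between consecutive nonzero signs
  flips <- s[-m] * s[-1] < 0
  out$PIP <- 100 * sum(flips) / n

  # maximal constant-sign runs (zeros split into length-1 segments)
  r <- rle(s)
  seg_len <- unlist(lapply(seq_along(r$lengths), function(j) {
    if (r$values[j] == 0) rep(1L, r$lengths[j]) else r$lengths[j]
  }))
  out$PSS <- 100 * sum(seg_len[seg_len < 3]) / m
  nz <- seg_len[unlist(lapply(seq_along(r$lengths), function(j) {
    if (r$values[j] == 0) rep(FALSE, r$lengths[j]) else TRUE
  }))]
  out$IALS <- if (length(nz)) 1 / mean(nz) else NA_real_

  # alternation segments: maximal runs of consecutive strict flips; a run of
  # q consecutive flips spans q + 1 increments
  if (any(flips)) {
    fr <- rle(flips)
    alt_lens <- fr$lengths[fr$values] + 1L
    out$PAS <- 100 * sum(alt_lens[alt_lens >= 4]) / m
  } else {
    out$PAS <- 0
  }
  out
}
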