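#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an incremental AUROC curve
#'
#' AUROC (mean over the cross-validation folds, with a +/- 1 SD ribbon)
#' against the number of top-ranked features in the logistic model.
#'
#' @param object A `ppg_eval_curve` from [evaluate_incremental()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppg_eval_curve <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_count,
                                   y = .data$auroc_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$auroc_mean - .data$auroc_sd,
                                      ymax = .data$auroc_mean + .data$auroc_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$feature_count) +
    ggplot2::labs(x = "Number of features", y = "AUROC",
                  title = sprintf("Incremental classification (%s folds)",
                                  df$stratification[1])) +
    ggplot2::theme_minimal()
}

#' Plot an interbeat-interval tachogram
#'
#' @param object An `ibi_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ibi_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if ("valid" %in% names(df)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beat_time_s,
                                          y = .data$ibi_ms,
                                          colour = .data$valid))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beat_time_s,
                                          y = .data$ibi_ms))
  }
  p + ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Time (s)", y = "IBI (ms)") +
    ggplot2::theme_minimal()
}

#' Plot one pulse with its fiducial points
#'
#' Shows the filtered pulse waveform with the initial trough (IT), systolic
#' peak (SP) and final trough (FT), and the derivative landmarks a1/b1
#' (first derivative) and a2/b2/e2 (second derivative) marked on their
#' respective traces.
#'
#' @param x Filtered PPG signal.
#' @param pulses A `pulse_set` with fiducial columns.
#' @param pulse_idx Which pulse to plot.
#' @param fs Sampling rate, Hz.
#' @return A ggplot object.
#' @export
plot_pulse_fiducials <- function(x, pulses, pulse_idx = 1,
                                 fs = attr(pulses, "fs")) {
  p <- pulses[pulses$pulse_idx == pulse_idx, ]
  if (!nrow(p)) stop("pulse not found", call. = FALSE)
  derivs <- pulse_derivatives(x, fs)
  seg <- p$IT:p$FT
  t0 <- (p$IT - 1) / fs
  df <- tibble::tibble(
    time_s = rep((seg - 1) / fs - t0, 3),
    value = c(x[seg], derivs$d1[seg] / fs, derivs$d2[seg] / fs^2),
    trace = rep(c("PPG", "1st derivative", "2nd derivative"),
                each = length(seg))
  )
  df$trace <- factor(df$trace, levels = unique(df$trace))
  marks <- tibble::tibble(
    name = c("IT", "SP", "FT", "a1", "b1", "a2", "b2", "e2"),
    idx = c(p$IT, p$SP, p$FT, p$a1, p$b1, p$a2, p$b2, p$e2),
    trace = factor(c("PPG", "PPG", "PPG", "1st derivative", "1st derivative",
                     "2nd derivative", "2nd derivative", "2nd derivative"),
                   levels = levels(df$trace))
  )
  marks <- marks[!is.na(marks$idx), ]
  marks$time_s <- (marks$idx - 1) / fs - t0
  marks$value <- ifelse(marks$trace == "PPG", x[marks$idx],
                        ifelse(marks$trace == "1st derivative",
                               derivs$d1[marks$idx] / fs,
                               derivs$d2[marks$idx] / fs^2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks, colour = "red") +
    ggplot2::geom_text(data = marks, ggplot2::aes(label = .data$name),
                       vjust = -0.8, size = 3) +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time within pulse (s)", y = NULL) +
    ggplot2::theme_minimal()
}
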