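#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   labs scale_fill_viridis_c facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a recording's traces
#'
#' @param object An [lfp_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lfp_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(as.data.frame(object)),
                              -"time_s", names_to = "channel",
                              values_to = "uV")
  ggplot(long, aes(.data$time_s, .data$uV)) +
    geom_line(linewidth = 0.2) +
    facet_wrap(~channel, ncol = 1) +
    labs(x = "time (s)", y = expression(paste(mu, "V"))) +
    theme_minimal()
}

#' Plot a PSD in dB
#'
#' @param object An `lfp_psd`.
#' @param ... Unused.
#' @export
autoplot.lfp_psd <- function(object, ...) {
  ggplot(as_tibble(as.data.frame(object)),
         aes(.data$frequency, .data$power_db)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "power (dB)") +
    theme_minimal()
}

#' Plot a spectrogram as a time-frequency heatmap
#'
#' @param object An `lfp_spectrogram`.
#' @param ... Unused.
#' @export
autoplot.lfp_spectrogram <- function(object, ...) {
  ggplot(as_tibble(as.data.frame(object)),
         aes(.data$start_s, .data$frequency, fill = .data$power_db)) +
    geom_tile() +
    scale_fill_viridis_c(name = "dB") +
    labs(x = "window start (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Plot a detrended spectrum with its aperiodic fit
#'
#' @param object A `detrended_psd` (see [detrend()]).
#' @param ... Unused.
#' @export
autoplot.detrended_psd <- function(object, ...) {
  fit <- attr(object, "fit")
  df <- as_tibble(as.data.frame(object))
  df$model <- aperiodic_model(df$frequency, fit$k, fit$x, fit$b)
  long <- tidyr::pivot_longer(df, c("log10_power", "model", "residual"),
                              names_to = "component")
  ggplot(long, aes(.data$frequency, .data$value, colour = .data$component)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "log10 power") +
    theme_minimal()
}

#' Plot window rejection statistics
#'
#' Per-window z-scores with the Grubbs threshold band; rejected windows
#' highlighted.
#'
#' @param x A `grubbs_result`.
#' @return A ggplot.
#' @export
plot_rejection <- function(x) {
  thr <- attr(x, "z_threshold")
  ggplot(as_tibble(as.data.frame(x)),
         aes(.data$window, .data$z, colour = .data$rejected)) +
    geom_point() +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    labs(x = "window", y = "z-score",
         title = sprintf("Grubbs rejection (%s), |z| > %.3f", attr(x, "basis"), thr)) +
    theme_minimal()
}
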