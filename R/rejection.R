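#' Grubbs outlier threshold
#'
#' Critical absolute z-score of the Grubbs test for `N` observations at
#' significance `alpha`: with `t` the upper `alpha/(2N)` quantile of the
#' t-distribution on `N - 2` degrees of freedom and `g = t^2`,
#' `z_threshold = ((N - 1) / sqrt(N)) * sqrt(g / (N - 2 + g))`.
#' The threshold adapts to the number of spectrogram windows, which matters
#' when recordings of different lengths are compared.
#'
#' @param N Number of windows (>= 3).
#' @param alpha Significance level (default 0.05).
#' @return The critical |z| value.
#' @examples
#' grubbs_threshold(10)   # ~2.290
#' @export
grubbs_threshold <- function(N, alpha = 0.05) {
  if (N < 3) abort("Grubbs test needs N >= 3 windows.",
                   class = "lfpclean_invalid_argument")
  t_crit <- qt(1 - alpha / (2 * N), df = N - 2)
  g <- t_crit^2
  ((N - 1) / sqrt(N)) * sqrt(g / (N - 2 + g))
}

new_grubbs_result <- function(stat, z, rejected, threshold, alpha, basis,
                              pretest_rejected = integer(0)) {
  new_tibble(tibble(window = seq_along(stat), statistic = stat, z = z,
                    rejected = rejected),
             z_threshold = threshold, alpha = alpha,
             n_windows = length(stat), basis = basis,
             pretest_rejected = pretest_rejected,
             class = "grubbs_result")
}

grubbs_on_statistic <- function(stat, alpha, basis,
                                pretest_rejected = integer(0)) {
  n <- length(stat)
  valid <- setdiff(seq_len(n), pretest_rejected)
  z <- rep(NA_real_, n)
  rejected <- rep(FALSE, n)
  rejected[pretest_rejected] <- TRUE
  threshold <- NA_real_
  if (length(valid) >= 3) {
    s <- sd(stat[valid])
    threshold <- grubbs_threshold(length(valid), alpha)
    if (is.finite(s) && s > 0) {
      z[valid] <- (stat[valid] - mean(stat[valid])) / s
      rejected[valid] <- abs(z[valid]) > threshold
    } else {
      z[valid] <- 0   # all statistics equal: nothing to reject
    }
  }
  new_grubbs_result(stat, z, rejected, threshold, alpha, basis,
                    pretest_rejected)
}

#' Reject spectrogram windows by inter-window correlation
#'
#' Each window's dB PSD over the broadband range (default 4-75 Hz) is
#' Pearson-correlated with every other window; the per-window statistic is
#' its mean correlation with the rest. Statistics are z-scored across
#' windows and windows with `|z|` above the Grubbs threshold are rejected.
#' Windows with zero variance over the band are auto-rejected before the
#' test, with a warning. Because Pearson correlation ignores additive dB
#' offsets, a broadband level shift alone does not trip this filter — which
#' is why the low-frequency power filter exists.
#'
#' @param sg An `lfp_spectrogram` (see [short_time_spectrogram()]).
#' @param band Broadband range in Hz (default `c(4, 75)`).
#' @param alpha Grubbs significance level (default 0.05).
#' @return Tibble of class `grubbs_result` with columns `window`,
#'   `statistic`, `z`, `rejected`; attributes `z_threshold`, `alpha`,
#'   `basis = "correlation"`.
#' @export
correlation_outliers <- function(sg, band = c(4, 75), alpha = 0.05) {
  m <- spectrogram_matrix(sg, "power_db")
  freqs <- attr(m, "frequencies")
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) abort("`band` lies outside the frequency grid.",
                       class = "lfpclean_invalid_argument")
  m <- m[sel, , drop = FALSE]
  nw <- ncol(m)
  if (nw < 3) abort("need at least 3 windows.",
                    class = "lfpclean_invalid_argument")
  degenerate <- which(apply(m, 2, sd) == 0)
  if (length(degenerate)) {
    warn(sprintf("%d window(s) with zero variance over the band auto-rejected.",
                 length(degenerate)))
  }
  cm <- suppressWarnings(cor(m))
  cm[!is.finite(cm)] <- 0
  stat <- (colSums(cm) - diag(cm)) / (nw - 1)  # mean r with the other windows
  grubbs_on_statistic(stat, alpha, "correlation", pretest_rejected = degenerate)
}

#' Reject spectrogram windows by mean low-frequency power
#'
#' Transients (movement, interictal discharges, stimulation edges) load the
#' bottom of the spectrum; the per-window statistic is the mean dB power
#' over 0-5.3 Hz by default, z-scored and tested two-sided against the
#' Grubbs threshold, so windows with anomalously high *or* low
#' low-frequency power are rejected.
#'
#' @inheritParams correlation_outliers
#' @param band Low-frequency range in Hz (default `c(0, 5.3)`).
#' @export
lowfreq_power_outliers <- function(sg, band = c(0, 5.3), alpha = 0.05) {
  m <- spectrogram_matrix(sg, "power_db")
  freqs <- attr(m, "frequencies")
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) abort("`band` lies outside the frequency grid.",
                       class = "lfpclean_invalid_argument")
  if (ncol(m) < 3) abort("need at least 3 windows.",
                         class = "lfpclean_invalid_argument")
  stat <- colMeans(m[sel, , drop = FALSE])
  grubbs_on_statistic(stat, alpha, "lowfreq_power")
}

#' Background PSD by outlier rejection and averaging
#'
#' Applies the correlation and/or low-frequency-power Grubbs filters (each
#' on the full window set), takes the union of their rejections, averages
#' the surviving windows in linear power (an average of power estimates is
#' itself a power estimate; averaging in dB would bias low), and converts
#' to dB.
#'
#' @param sg An `lfp_spectrogram`.
#' @param use_correlation,use_lowfreq Enable each filter (defaults TRUE).
#' @param alpha Grubbs significance level for both filters.
#' @param band_corr,band_lowfreq Bands for the two filters.
#' @return An `lfp_psd` with attributes `kept_windows`, `rejected_windows`,
#'   `background_method = "mean_of_kept"` and the per-filter results in
#'   `filter_results`.
#' @export
background_psd <- function(sg, use_correlation = TRUE, use_lowfreq = TRUE,
                           alpha = 0.05, band_corr = c(4, 75),
                           band_lowfreq = c(0, 5.3)) {
  nw <- attr(sg, "n_windows")
  filters <- list()
  rejected <- integer(0)
  if (use_correlation && nw >= 3) {
    filters$correlation <- correlation_outliers(sg, band_corr, alpha)
    rejected <- union(rejected, which(filters$correlation$rejected))
  }
  if (use_lowfreq && nw >= 3) {
    filters$lowfreq <- lowfreq_power_outliers(sg, band_lowfreq, alpha)
    rejected <- union(rejected, which(filters$lowfreq$rejected))
  }
  kept <- setdiff(seq_len(nw), rejected)
  if (!length(kept)) {
    abort("all windows rejected; relax `alpha` or inspect the recording.",
          class = "lfpclean_all_rejected")
  }
  pm <- spectrogram_matrix(sg, "power")
  p <- rowMeans(pm[, kept, drop = FALSE])
  new_psd(attr(pm, "frequencies"), p, attr(sg, "params"),
          extra_attrs = list(kept_windows = kept,
                             rejected_windows = sort(rejected),
                             background_method = "mean_of_kept",
                             filter_results = filters))
}

#' Background PSD from the first principal component
#'
#' Each window's dB PSD over the band is centered by subtracting its own
#' mean; the first principal component across windows then captures the
#' spectral shape common to (most of) the windows — the background. The
#' component is sign-oriented to correlate positively with the mean dB PSD
#' and least-squares scaled and shifted onto it; bins outside the band are
#' filled from the mean dB PSD.
#'
#' @param sg An `lfp_spectrogram` with at least 2 windows.
#' @param band Analysis band in Hz (default `c(4, 75)`).
#' @return An `lfp_psd` with `background_method = "pca_first_component"`.
#' @export
pca_background <- function(sg, band = c(4, 75)) {
  nw <- attr(sg, "n_windows")
  if (nw < 2) abort("PCA background needs at least 2 windows.",
                    class = "lfpclean_invalid_argument")
  m <- spectrogram_matrix(sg, "power_db")
  freqs <- attr(m, "frequencies")
  sel <- freqs >= band[1] & freqs <= band[2]
  mb <- m[sel, , drop = FALSE]
  centered <- sweep(mb, 2, colMeans(mb))      # normalize each window by its mean
  sv <- svd(t(centered), nu = 0, nv = 1)
  pc1 <- sv$v[, 1]
  mean_db <- rowMeans(mb)
  if (cor(pc1, mean_db) < 0) pc1 <- -pc1      # orient with the mean PSD
  fit <- stats::lm.fit(cbind(1, pc1), mean_db)
  bg_band <- fit$coefficients[1] + fit$coefficients[2] * pc1
  bg_db <- rowMeans(m)
  bg_db[sel] <- bg_band
  new_psd(freqs, 10^(bg_db / 10), attr(sg, "params"),
          extra_attrs = list(kept_windows = seq_len(nw),
                             background_method = "pca_first_component",
                             pc1 = pc1, band = band))
}
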