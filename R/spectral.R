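#' Window-length and frequency-resolution arithmetic
#'
#' The three resolution quantities that govern the choice of analysis window
#' for LFP spectra, plus the Slepian taper-count rule:
#'
#' * `min_frequency(fs, N)` — lowest observable frequency of a segment of
#'   `N` samples: one full period must fit, so `1/T = fs/N`.
#' * `fft_resolution(fs, nfft)` — DFT bin spacing `fs/nfft`.
#' * `hanning_halfbandwidth(fs, nfft)` — effective smoothing of a Hann
#'   window: main-lobe half-bandwidth `2 fs / nfft` (main lobe width is
#'   twice that).
#' * `n_tapers(T, W_hz)` — number of Slepian tapers supported by a
#'   time-half-bandwidth product `TW`: `floor(2 T W) - 1`.
#'
#' @param fs Sampling rate in Hz.
#' @param N Window length in samples.
#' @param nfft DFT length in samples.
#' @param T_sec Window length in seconds.
#' @param W_hz Half-bandwidth in Hz.
#' @return A single number (Hz, or a taper count).
#' @examples
#' min_frequency(250, 256)        # ~1 Hz
#' hanning_halfbandwidth(250, 256) # ~2 Hz
#' n_tapers(2, 1)                 # 3 tapers
#' @export
min_frequency <- function(fs, N) {
  assert_positive_scalar(fs, "fs"); assert_positive_scalar(N, "N")
  fs / N
}

#' @rdname min_frequency
#' @export
fft_resolution <- function(fs, nfft) {
  assert_positive_scalar(fs, "fs"); assert_positive_scalar(nfft, "nfft")
  fs / nfft
}

#' @rdname min_frequency
#' @export
hanning_halfbandwidth <- function(fs, nfft) {
  assert_positive_scalar(fs, "fs"); assert_positive_scalar(nfft, "nfft")
  2 * fs / nfft
}

#' @rdname min_frequency
#' @export
n_tapers <- function(T_sec, W_hz) {
  assert_positive_scalar(T_sec, "T_sec"); assert_positive_scalar(W_hz, "W_hz")
  tw <- T_sec * W_hz
  if (tw < 1) {
    abort("time-half-bandwidth product T*W must be >= 1 for a valid taper.",
          class = "lfpclean_invalid_argument")
  }
  as.integer(floor(2 * tw) - 1)
}

#' Spectral estimation parameters
#'
#' Bundles the window length, DFT length, overlap and method. For the
#' multitaper method the taper count is derived from the taper-count rule;
#' the default half-bandwidth is held at 1 Hz when the Hann half-bandwidth
#' of the same window would fall below 1 Hz, trading unneeded resolution for
#' extra tapers (and hence lower PSD variance).
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param window_sec Analysis window length in seconds (default 2).
#' @param nfft DFT length; default next power of two at or above the window
#'   length in samples.
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @param method `"multitaper"` (default) or `"hanning_welch"`.
#' @param half_bandwidth Multitaper half-bandwidth in Hz; default
#'   `max(1, hanning_halfbandwidth(fs, nfft))`.
#' @param detrend Per-segment detrending before tapering: `"linear"`
#'   (default), `"constant"`, or `"none"`. Steep 1/f spectra put large
#'   slow excursions inside each analysis window; removing the per-segment
#'   linear trend keeps their sidelobe leakage from biasing the estimate.
#' @return A list of class `spectral_params` including the derived
#'   `window_length`, `n_tapers` and frequency grid spacing.
#' @export
spectral_params <- function(sampling_rate, window_sec = 2, nfft = NULL,
                            overlap = 0.5,
                            method = c("multitaper", "hanning_welch"),
                            half_bandwidth = NULL,
                            detrend = c("linear", "constant", "none")) {
  assert_positive_scalar(sampling_rate, "sampling_rate")
  method <- match.arg(method)
  detrend <- match.arg(detrend)
  N <- round(window_sec * sampling_rate)
  nfft <- nfft %||% 2^ceiling(log2(N))
  if (nfft < N) abort("`nfft` must be >= the window length in samples.",
                      class = "lfpclean_invalid_argument")
  if (overlap < 0 || overlap >= 1) {
    abort("`overlap` must lie in [0, 1).", class = "lfpclean_invalid_argument")
  }
  hb <- NULL; k <- NULL
  if (method == "multitaper") {
    hb <- half_bandwidth %||% max(1, hanning_halfbandwidth(sampling_rate, nfft))
    k <- n_tapers(N / sampling_rate, hb)
  }
  structure(list(sampling_rate = sampling_rate,
                 window_length = as.integer(N),
                 window_sec = N / sampling_rate,
                 nfft = as.integer(nfft), overlap = overlap,
                 method = method, half_bandwidth = hb,
                 n_tapers = k, detrend = detrend,
                 resolution = sampling_rate / nfft),
            class = "spectral_params")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `k` DPSS tapers of length `n` with half-bandwidth `w` in
#' cycles/sample, computed as eigenvectors of the standard symmetric
#' tridiagonal matrix; unit-energy normalized. Cached per parameter set.
#'
#' @param n Taper length in samples.
#' @param w Half-bandwidth in cycles per sample (`0 < w < 0.5`).
#' @param k Number of tapers.
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, w, k) {
  stopifnot(n >= 2, w > 0, w < 0.5, k >= 1, k <= n)
  key <- sprintf("dpss_%d_%.10g_%d", n, w, k)
  if (!is.null(the[[key]])) return(the[[key]])
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  t <- 1:(n - 1)
  diag_off <- t * (n - t) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diag_main
  A[cbind(t, t + 1)] <- diag_off
  A[cbind(t + 1, t)] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # unit energy; deterministic sign (largest-magnitude element positive)
  v <- apply(v, 2, function(col) {
    col <- col / sqrt(sum(col^2))
    col * sign(col[which.max(abs(col))])
  })
  the[[key]] <- v
  v
}

# split a record into overlapped segment start indices
segment_starts <- function(n, N, overlap) {
  step <- max(1L, as.integer(round(N * (1 - overlap))))
  if (n < N) abort(
    sprintf("recording (%d samples) shorter than one window (%d samples).", n, N),
    class = "lfpclean_too_short")
  starts <- seq(1L, n - N + 1L, by = step)
  list(starts = starts, step = step)
}

# one-sided PSD of a single tapered segment; density-normalized so that
# sum(psd) * fs/nfft ~ segment variance; symmetric zero-padding to nfft
tapered_periodogram <- function(x, taper, nfft, fs) {
  xt <- x * taper
  pad <- nfft - length(xt)
  if (pad > 0) xt <- c(numeric(floor(pad / 2)), xt, numeric(ceiling(pad / 2)))
  X <- fft(xt)[seq_len(nfft %/% 2 + 1)]
  p <- (Mod(X)^2) / (fs * sum(taper^2))
  # double interior bins for the one-sided density
  scale <- rep(2, length(p)); scale[1] <- 1
  if (nfft %% 2 == 0) scale[length(p)] <- 1
  p * scale
}

new_psd <- function(freqs, power, params, extra_attrs = list()) {
  out <- new_tibble(tibble(frequency = freqs, power = power,
                           power_db = 10 * log10(pmax(power, .Machine$double.xmin))),
                    params = params, class = "lfp_psd")
  for (nm in names(extra_attrs)) attr(out, nm) <- extra_attrs[[nm]]
  out
}

psd_core <- function(x, params, starts = NULL) {
  fs <- params$sampling_rate; N <- params$window_length
  nfft <- params$nfft
  if (is.null(starts)) starts <- segment_starts(length(x), N, params$overlap)$starts
  if (params$method == "hanning_welch") {
    tapers <- matrix(hann_window(N), ncol = 1)
  } else {
    tapers <- dpss_tapers(N, params$half_bandwidth / fs, params$n_tapers)
  }
  acc <- numeric(nfft %/% 2 + 1)
  dt <- params$detrend %||% "linear"
  tt <- seq_len(N)
  for (s in starts) {
    seg <- x[s:(s + N - 1L)]
    if (dt == "constant") {
      seg <- seg - mean(seg)
    } else if (dt == "linear") {
      seg <- stats::lm.fit(cbind(1, tt), seg)$residuals
    }
    for (j in seq_len(ncol(tapers))) {
      acc <- acc + tapered_periodogram(seg, tapers[, j], nfft, fs)
    }
  }
  acc / (length(starts) * ncol(tapers))
}

resolve_channel <- function(rec, channel) {
  labels <- channel_labels(rec)
  channel <- channel %||% labels[1]
  if (is.numeric(channel)) channel <- labels[channel]
  stopifnot(channel %in% labels)
  channel
}

#' Welch power spectral density (Hann windows)
#'
#' Hann-windowed overlapped segments, symmetrically zero-padded to `nfft`,
#' magnitude-squared, one-sided density-normalized (uV^2/Hz) and averaged.
#'
#' @param rec An [lfp_recording()].
#' @param params A [spectral_params()]; method is forced to
#'   `"hanning_welch"`. If missing, defaults for the recording's rate.
#' @param channel Channel label or index (default first channel).
#' @return A tibble of class `lfp_psd` with columns `frequency`, `power`,
#'   `power_db`.
#' @export
welch_psd <- function(rec, params = NULL, channel = NULL) {
  params <- params %||% spectral_params(sampling_rate(rec), method = "hanning_welch")
  params$method <- "hanning_welch"
  channel <- resolve_channel(rec, channel)
  x <- channel_matrix(rec, channel)[, 1]
  p <- psd_core(x, params)
  new_psd(seq(0, params$nfft %/% 2) * params$sampling_rate / params$nfft, p, params)
}

#' Multitaper power spectral density
#'
#' Per-taper Slepian periodograms averaged with equal weights; for records
#' longer than one window, overlapped windows are additionally averaged
#' (Welch-style). One-sided, density-normalized.
#'
#' @inheritParams welch_psd
#' @export
multitaper_psd <- function(rec, params = NULL, channel = NULL) {
  params <- params %||% spectral_params(sampling_rate(rec), method = "multitaper")
  if (params$method != "multitaper") {
    params <- spectral_params(params$sampling_rate,
                              window_sec = params$window_sec, nfft = params$nfft,
                              overlap = params$overlap, method = "multitaper")
  }
  channel <- resolve_channel(rec, channel)
  x <- channel_matrix(rec, channel)[, 1]
  p <- psd_core(x, params)
  new_psd(seq(0, params$nfft %/% 2) * params$sampling_rate / params$nfft, p, params)
}

#' Short-time spectrogram
#'
#' Splits the recording into overlapped windows (default 2 s, 50% overlap)
#' and transforms each with the chosen method (default multitaper with 1 Hz
#' half-bandwidth, hence 3 tapers), yielding a time-ordered sequence of PSD
#' windows.
#'
#' @inheritParams welch_psd
#' @return A long tibble of class `lfp_spectrogram` with columns `window`,
#'   `start_sample`, `start_s`, `frequency`, `power`, `power_db`.
#' @export
short_time_spectrogram <- function(rec, params = NULL, channel = NULL) {
  params <- params %||% spectral_params(sampling_rate(rec), window_sec = 2,
                                        overlap = 0.5, method = "multitaper",
                                        half_bandwidth = 1)
  channel <- resolve_channel(rec, channel)
  x <- channel_matrix(rec, channel)[, 1]
  st <- segment_starts(length(x), params$window_length, params$overlap)
  freqs <- seq(0, params$nfft %/% 2) * params$sampling_rate / params$nfft
  win_list <- purrr::map(seq_along(st$starts), function(i) {
    p <- psd_core(x, params, starts = st$starts[i])
    tibble(window = i, start_sample = st$starts[i],
           start_s = (st$starts[i] - 1) / params$sampling_rate,
           frequency = freqs, power = p,
           power_db = 10 * log10(pmax(p, .Machine$double.xmin)))
  })
  new_tibble(dplyr::bind_rows(win_list), params = params,
             n_windows = length(st$starts), class = "lfp_spectrogram")
}

#' Spectrogram as a frequency-by-window matrix
#'
#' @param sg An `lfp_spectrogram`.
#' @param value Column to extract: `"power_db"` (default) or `"power"`.
#' @return Numeric matrix, rows = frequency bins, columns = windows;
#'   frequencies as rownames attribute `frequencies`.
#' @export
spectrogram_matrix <- function(sg, value = c("power_db", "power")) {
  value <- match.arg(value)
  nw <- attr(sg, "n_windows")
  freqs <- sg$frequency[sg$window == 1]
  m <- matrix(sg[[value]], nrow = length(freqs), ncol = nw)
  attr(m, "frequencies") <- freqs
  m
}

#' Integrated band power of a PSD
#'
#' Trapezoid-free rectangular integration `sum(power) * df` over
#' `band[1] <= f <= band[2]`.
#'
#' @param psd An `lfp_psd` (or any tibble with `frequency` and `power`).
#' @param band Length-2 numeric, Hz.
#' @return Band power in uV^2.
#' @export
band_power <- function(psd, band) {
  df <- diff(psd$frequency[1:2])
  sel <- psd$frequency >= band[1] & psd$frequency <= band[2]
  sum(psd$power[sel]) * df
}

#' @export
print.lfp_psd <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<lfp_psd> %s, %d bins, df = %.4g Hz, window %g s\n",
              p$method, nrow(x), p$resolution, p$window_sec))
  NextMethod()
}

#' @export
print.lfp_spectrogram <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<lfp_spectrogram> %d windows of %g s (overlap %.0f%%), %s\n",
              attr(x, "n_windows"), p$window_sec, 100 * p$overlap, p$method))
  NextMethod()
}
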