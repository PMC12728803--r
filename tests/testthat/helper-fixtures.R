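# shared fixture builders; everything is generated in code at test time

# spectrogram object from a dB matrix (bins x windows), for constructed cases
sg_from_db <- function(db, fs = 250, window_sec = 2, overlap = 0.5) {
  params <- spectral_params(fs, window_sec = window_sec, overlap = overlap,
                            method = "multitaper", half_bandwidth = 1)
  nb <- nrow(db); nw <- ncol(db)
  freqs <- seq(0, params$nfft %/% 2) * fs / params$nfft
  stopifnot(nb == length(freqs))
  step <- round(params$window_length * (1 - overlap))
  long <- do.call(rbind, lapply(seq_len(nw), function(i) {
    data.frame(window = i, start_sample = (i - 1L) * step + 1L,
               start_s = (i - 1L) * step / fs,
               frequency = freqs, power = 10^(db[, i] / 10),
               power_db = db[, i])
  }))
  structure(tibble::as_tibble(long), params = params, n_windows = nw,
            class = c("lfp_spectrogram", class(tibble::tibble())))
}

# background-only simulation spec (no oscillations, no heartbeats)
background_spec <- function(duration, seed, knee = 2, exponent = 1.5,
                            offset = 1, transients = NULL) {
  sim_spec(duration = duration, seed = seed,
           background = list(knee = knee, exponent = exponent, offset = offset),
           oscillations = NULL, qrs = list(heart_rate = 0),
           channels = "ch1", transients = transients)
}

# recall / precision of detected R peaks against ground truth apexes
detection_metrics <- function(detected, truth, tol = 2) {
  if (!length(truth)) return(c(recall = NA, precision = NA))
  hits <- vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1))
  tp <- vapply(detected, function(e) any(abs(truth - e) <= tol), logical(1))
  c(recall = mean(hits),
    precision = if (length(detected)) mean(tp) else NA)
}

# windows of a 2 s / 50% spectrogram overlapping a sample interval
windows_touching <- function(n_windows, start_sample, end_sample,
                             step = 250, len = 500) {
  starts <- (seq_len(n_windows) - 1L) * step + 1L
  which(starts <= end_sample & starts + len - 1L >= start_sample)
}

# -3 dB full width of the tallest PSD peak, linearly interpolated
width_3db <- function(psd) {
  pk <- which.max(psd$power_db)
  thr <- psd$power_db[pk] - 3
  df <- diff(psd$frequency[1:2])
  lo <- max(which(psd$power_db[1:pk] < thr))
  hi <- pk - 1 + min(which(psd$power_db[pk:nrow(psd)] < thr))
  f1 <- psd$frequency[lo] + (thr - psd$power_db[lo]) /
    (psd$power_db[lo + 1] - psd$power_db[lo]) * df
  f2 <- psd$frequency[hi - 1] + (thr - psd$power_db[hi - 1]) /
    (psd$power_db[hi] - psd$power_db[hi - 1]) * df
  f2 - f1
}

# independent Grubbs critical value: t quantile via the incomplete-beta
# representation of the t CDF (no qt), then the closed form
grubbs_oracle <- function(N, alpha) {
  p <- alpha / (2 * N)                      # upper-tail probability
  df <- N - 2
  xb <- qbeta(2 * p, df / 2, 0.5)           # I_x(df/2, 1/2) = 2p
  t2 <- df * (1 - xb) / xb                  # t^2 from x = df/(df + t^2)
  ((N - 1) / sqrt(N)) * sqrt(t2 / (df + t2))
}
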