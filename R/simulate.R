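#' Specification for a synthetic LFP recording
#'
#' Describes a ground-truth-annotated simulated recording: a 1/f-with-knee
#' aperiodic background, band-limited stochastic oscillations, a
#' quasi-periodic cardiac QRS artifact train shared (time-locked) across
#' channels with per-channel scaling, short high-amplitude transients, and
#' optional digitization.
#'
#' Defaults emulate a bipolar deep-brain LFP sensed at 250 Hz: background
#' parameters (`knee = 2`, `exponent = 1.5`, `offset = 1` in log10 uV^2/Hz)
#' give a trace of roughly 5 uV RMS, and the default 40 uV QRS apex makes the
#' artifact clearly visible against the 5-30 Hz bandpassed background, as is
#' typical where cardiac contamination is reported at all.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Duration in seconds; `duration * sampling_rate` must be a
#'   positive whole number of samples.
#' @param seed Integer seed; every stochastic component derives its stream
#'   from it, so a spec simulates reproducibly.
#' @param background List with `knee` (k >= 0), `exponent` (x >= 0) and
#'   `offset` (b), the parameters of the aperiodic model
#'   `log10 P(f) = b - log10(k + f^x)`.
#' @param oscillations Tibble/data frame with columns `center_freq` (Hz),
#'   `bandwidth` (Hz), `amplitude` (uV RMS); one row per band-limited
#'   oscillation, or `NULL`.
#' @param qrs List with `heart_rate` (bpm; 0 disables), `rate_jitter`
#'   (fractional SD of the inter-beat interval), `amplitude` (uV at the R
#'   apex), `polarity` (+1/-1), `channel_scales` (named per-channel factors),
#'   and optionally `stim_on_scale` (extra factor applied during
#'   stimulation-on segments).
#' @param transients Tibble/data frame with columns `onset` (s), `duration`
#'   (s), `amplitude` (uV), `kind` (`"ied"` or `"stim_edge"`), or `NULL`.
#' @param quantization_step Digitization step in uV; 0 (default) disables
#'   rounding.
#' @param channels Channel labels; the background is independent noise per
#'   channel, the QRS train is time-locked across channels.
#' @param stim_segments Optional stimulation-on intervals (tibble with
#'   `start_s`, `end_s`, `amplitude_mA`), carried onto the recording.
#' @return A list of class `lfp_sim_spec`.
#' @export
sim_spec <- function(sampling_rate = 250, duration = 60, seed = 1,
                     background = list(knee = 2, exponent = 1.5, offset = 1),
                     oscillations = tibble(center_freq = c(10, 20),
                                           bandwidth = c(2, 4),
                                           amplitude = c(1.5, 1)),
                     qrs = list(heart_rate = 70, rate_jitter = 0.03,
                                amplitude = 40, polarity = 1,
                                channel_scales = c(left = 0.2, right = 1)),
                     transients = NULL,
                     quantization_step = 0,
                     channels = c("left", "right"),
                     stim_segments = NULL) {
  assert_positive_scalar(sampling_rate, "sampling_rate")
  assert_positive_scalar(duration, "duration")
  n <- sampling_rate * duration
  if (abs(n - round(n)) > 1e-9 || round(n) < 1) {
    abort("`duration * sampling_rate` must be a positive integer sample count.",
          class = "lfpclean_invalid_argument")
  }
  stopifnot(background$knee >= 0, background$exponent >= 0)
  qrs$channel_scales <- qrs$channel_scales %||%
    stats::setNames(rep(1, length(channels)), channels)
  if (is.null(names(qrs$channel_scales)) ||
      !all(channels %in% names(qrs$channel_scales))) {
    qrs$channel_scales <- stats::setNames(
      rep_len(unname(qrs$channel_scales), length(channels)), channels)
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 seed = as.integer(seed), background = background,
                 oscillations = if (!is.null(oscillations)) as_tibble(oscillations),
                 qrs = qrs,
                 transients = if (!is.null(transients)) as_tibble(transients),
                 quantization_step = quantization_step,
                 channels = channels, stim_segments = stim_segments),
            class = "lfp_sim_spec")
}

# aperiodic model in linear power density units (uV^2/Hz)
background_density <- function(f, knee, exponent, offset) {
  10^offset / (knee + f^exponent)
}

#' Simulate the aperiodic 1/f background
#'
#' Synthesizes a real-valued trace whose expected one-sided power spectral
#' density follows `10^(b - log10(k + f^x))` by frequency-domain amplitude
#' shaping: Fourier amplitudes are set to the model's square root, phases are
#' uniform random, the spectrum is conjugate-symmetric, and the DC bin is
#' forced to zero. Deterministic given `spec$seed`.
#'
#' @param spec An [sim_spec()].
#' @return An [lfp_recording()] with one column per channel of independent
#'   background noise.
#' @export
simulate_background <- function(spec) {
  stopifnot(inherits(spec, "lfp_sim_spec"))
  if (spec$duration < 4) {
    abort("background simulation needs `duration >= 4` seconds.",
          class = "lfpclean_invalid_argument")
  }
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  b <- spec$background
  mat <- withr::with_seed(spec$seed, {
    vapply(seq_along(spec$channels), function(ch) {
      shaped_noise(n, fs, function(f)
        background_density(f, b$knee, b$exponent, b$offset))
    }, numeric(n))
  })
  colnames(mat) <- spec$channels
  lfp_recording(mat, fs, stim_state = if (is.null(spec$stim_segments)) "off" else "mixed",
                stim_segments = spec$stim_segments,
                provenance = "lfpclean synthetic background")
}

# draw a trace with expected one-sided PSD `density(f)` (uV^2/Hz)
shaped_noise <- function(n, fs, density) {
  freqs <- seq(0, n - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)          # DC .. Nyquist (or near)
  p <- density(freqs[half])
  p[1] <- 0                                   # DC forced to zero
  p[!is.finite(p) | p < 0] <- 0
  # one-sided density P = 2 |X|^2 / (fs n)  =>  |X| = sqrt(P fs n / 2)
  amp <- sqrt(p * fs * n / 2)
  phases <- runif(length(half), 0, 2 * pi)
  x <- complex(modulus = amp, argument = phases)
  x[1] <- 0
  full <- complex(real = numeric(n))
  full[half] <- x
  if (n %% 2 == 0) full[half[length(half)]] <- complex(real = amp[length(half)] *
                                                         sign(cos(phases[length(half)])))
  if (n > 2) {
    mirror <- (n:2)[seq_len(n - floor(n / 2) - 1)]
    full[mirror] <- Conj(full[2:(n - floor(n / 2))])
  }
  Re(fft(full, inverse = TRUE)) / n
}

#' Add a band-limited stochastic oscillation to a recording
#'
#' Adds band-filtered Gaussian noise (4th-order Butterworth, zero-phase)
#' scaled to a requested RMS amplitude. Filtered noise rather than a pure
#' sinusoid is used so spectral peaks have realistic width.
#'
#' @param rec An [lfp_recording()].
#' @param center_freq Peak center in Hz; must be below Nyquist.
#' @param bandwidth Full bandwidth in Hz.
#' @param amplitude Target RMS in uV (0 returns `rec` unchanged).
#' @param seed Integer seed for the noise draw.
#' @param channels Channels to modify; default all.
#' @return The recording with the oscillation added.
#' @export
add_oscillation <- function(rec, center_freq, bandwidth, amplitude, seed,
                            channels = NULL) {
  fs <- sampling_rate(rec)
  if (center_freq <= 0 || center_freq >= fs / 2) {
    abort("`center_freq` must lie in (0, Nyquist).",
          class = "lfpclean_invalid_argument")
  }
  if (amplitude == 0) return(rec)
  channels <- channels %||% channel_labels(rec)
  lo <- max(center_freq - bandwidth / 2, 0.01)
  hi <- min(center_freq + bandwidth / 2, fs / 2 * 0.999)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  mat <- channel_matrix(rec)
  withr::with_seed(seed, {
    for (ch in channels) {
      x <- signal::filtfilt(bf, rnorm(nrow(mat)))
      mat[, ch] <- mat[, ch] + x / sqrt(mean(x^2)) * amplitude
    }
  })
  replace_channels(rec, mat)
}

# stereotyped biphasic QRS complex: Q and S negative Gaussians flanking the
# R apex; total support ~55 samples at 250 Hz (>= 18 pre / 36 post capture)
qrs_waveform <- function(fs, amplitude = 1, polarity = 1) {
  half <- round(27 * fs / 250)
  t <- (-half):half
  w <- exp(-0.5 * (t / (3 * fs / 250))^2) -
    0.25 * exp(-0.5 * ((t + 7 * fs / 250) / (2 * fs / 250))^2) -
    0.30 * exp(-0.5 * ((t - 7 * fs / 250) / (3 * fs / 250))^2)
  polarity * amplitude * w / max(abs(w))
}

#' Simulate a quasi-periodic QRS artifact train
#'
#' Places a stereotyped biphasic QRS complex at quasi-periodic beat times
#' (inter-beat interval `60 / heart_rate` s, jittered by a fractional SD) and
#' applies per-channel scale and polarity. Beat times are shared across
#' channels — the cardiac artifact is time-locked between hemispheres.
#'
#' @param spec An [sim_spec()].
#' @return List with `artifact` (matrix, one column per channel, uV) and
#'   `event_samples` (1-based integer indices of each R apex).
#' @export
simulate_qrs_train <- function(spec) {
  stopifnot(inherits(spec, "lfp_sim_spec"))
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  q <- spec$qrs
  mat <- matrix(0, n, length(spec$channels),
                dimnames = list(NULL, spec$channels))
  if (is.null(q) || q$heart_rate <= 0) {
    return(list(artifact = mat, event_samples = integer(0)))
  }
  ibi <- 60 / q$heart_rate * fs
  if (spec$duration < 2 * 60 / q$heart_rate) {
    abort("`heart_rate` must yield at least 2 beats within `duration`.",
          class = "lfpclean_invalid_argument")
  }
  events <- withr::with_seed(spec$seed + 1L, {
    n_beats <- ceiling(n / ibi) + 2L
    gaps <- ibi * (1 + (q$rate_jitter %||% 0) * rnorm(n_beats))
    ev <- round(ibi / 2 + cumsum(c(0, gaps)))
    ev[ev >= 1 & ev <= n]
  })
  events <- sort(unique(as.integer(events)))
  w <- qrs_waveform(fs, q$amplitude, q$polarity %||% 1)
  half <- (length(w) - 1L) / 2L
  states <- if (!is.null(spec$stim_segments)) {
    seg <- spec$stim_segments
    ev_t <- (events - 1) / fs
    on <- rep(FALSE, length(events))
    for (i in seq_len(nrow(seg))) {
      on <- on | (ev_t >= seg$start_s[i] & ev_t < seg$end_s[i])
    }
    on
  } else rep(FALSE, length(events))
  on_scale <- q$stim_on_scale %||% 1
  train <- numeric(n)
  for (j in seq_along(events)) {
    idx <- (events[j] - half):(events[j] + half)
    ok <- idx >= 1 & idx <= n
    train[idx[ok]] <- train[idx[ok]] +
      w[ok] * if (states[j]) on_scale else 1
  }
  for (ch in spec$channels) {
    sc <- if (ch %in% names(q$channel_scales)) q$channel_scales[[ch]] else 1
    mat[, ch] <- train * sc
  }
  list(artifact = mat, event_samples = events)
}

# short high-amplitude transients: interictal-like sharp waves and
# stimulation on/off edge steps with exponential settling
transient_waveform <- function(kind, n_samp, fs, amplitude) {
  t <- (seq_len(n_samp) - 1) / fs
  dur <- n_samp / fs
  switch(kind,
         ied = {
           # sharp spike (~30 ms) followed by a slower opposite wave
           amplitude * (exp(-0.5 * ((t - 0.25 * dur) / (0.04 * dur))^2) -
                          0.6 * exp(-0.5 * ((t - 0.55 * dur) / (0.15 * dur))^2))
         },
         stim_edge = {
           # step edge settling exponentially (amplitude change artifact)
           amplitude * exp(-t / (dur / 4))
         },
         abort(sprintf("unknown transient kind '%s'", kind),
               class = "lfpclean_invalid_argument"))
}

simulate_transients <- function(spec) {
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  mat <- matrix(0, n, length(spec$channels),
                dimnames = list(NULL, spec$channels))
  windows <- tibble(start_sample = integer(0), end_sample = integer(0),
                    kind = character(0))
  tr <- spec$transients
  if (is.null(tr) || nrow(tr) == 0) return(list(trace = mat, windows = windows))
  for (i in seq_len(nrow(tr))) {
    start <- round(tr$onset[i] * fs) + 1L
    len <- max(round(tr$duration[i] * fs), 2L)
    idx <- start:(start + len - 1L)
    ok <- idx >= 1 & idx <= n
    w <- transient_waveform(tr$kind[i], len, fs, tr$amplitude[i])
    mat[idx[ok], ] <- mat[idx[ok], ] + w[ok]   # overlaps sum
    windows <- bind_rows(windows,
                         tibble(start_sample = as.integer(max(start, 1L)),
                                end_sample = as.integer(min(start + len - 1L, n)),
                                kind = tr$kind[i]))
  }
  list(trace = mat, windows = windows)
}

#' Assemble a full synthetic recording with ground truth
#'
#' Sums background + oscillations + QRS train + transients per channel, then
#' quantizes. The returned ground truth carries every component separately,
#' so tests can check conservation exactly: before quantization the emitted
#' recording equals `clean + qrs + transients` sample for sample.
#'
#' @param spec An [sim_spec()].
#' @return List with `recording` (the contaminated [lfp_recording()]) and
#'   `truth`, a list holding `clean` (background + oscillations recording),
#'   `qrs_trace`, `qrs_event_samples`, `transient_trace`,
#'   `transient_windows`, and `background` (the model parameters).
#' @export
assemble_recording <- function(spec) {
  stopifnot(inherits(spec, "lfp_sim_spec"))
  rec <- simulate_background(spec)
  osc <- spec$oscillations
  if (!is.null(osc)) {
    for (i in seq_len(nrow(osc))) {
      rec <- add_oscillation(rec, osc$center_freq[i], osc$bandwidth[i],
                             osc$amplitude[i], seed = spec$seed + 100L + i)
    }
  }
  qrs <- simulate_qrs_train(spec)
  trans <- simulate_transients(spec)
  clean <- channel_matrix(rec)
  total <- clean + qrs$artifact + trans$trace
  if (spec$quantization_step > 0) {
    total <- round(total / spec$quantization_step) * spec$quantization_step
  }
  contaminated <- replace_channels(rec, total)
  attr(contaminated, "provenance") <- "lfpclean synthetic recording"
  list(recording = contaminated,
       truth = list(clean = rec,
                    qrs_trace = qrs$artifact,
                    qrs_event_samples = qrs$event_samples,
                    transient_trace = trans$trace,
                    transient_windows = trans$windows,
                    background = spec$background))
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of [assemble_recording()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(qrs_event_samples = truth$qrs_event_samples,
         transient_windows = truth$transient_windows,
         background = truth$background),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
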