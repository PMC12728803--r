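#' Bandpass a recording for QRS detection
#'
#' Zero-phase (forward-backward) 4th-order Butterworth bandpass, 5-30 Hz by
#' default, isolating the cardiac QRS energy from slow drifts and
#' high-frequency noise. Zero-phase filtering keeps the filtered apex
#' aligned with the raw signal, which template subtraction relies on.
#'
#' @param rec An [lfp_recording()] sampled above 60 Hz.
#' @param low,high Passband edges in Hz.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return The filtered recording (same length, same metadata).
#' @export
bandpass_qrs <- function(rec, low = 5, high = 30, order = 4) {
  fs <- sampling_rate(rec)
  if (fs <= 60) abort("`sampling_rate` must exceed 60 Hz.",
                      class = "lfpclean_invalid_argument")
  ir_span <- ceiling(3 * fs / low)   # ~3 cycles of the lowest passband edge
  if (nrow(rec) < 3 * ir_span) {
    abort(sprintf("recording too short to bandpass: %d samples < %d.",
                  nrow(rec), 3 * ir_span), class = "lfpclean_too_short")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  mat <- channel_matrix(rec)
  n <- nrow(mat)
  pad <- min(3L * ir_span, n - 1L)
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    # odd-reflection padding keeps filter startup transients off the data
    xp <- c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    yp <- signal::filtfilt(bf, xp)
    mat[, j] <- yp[(pad + 1L):(pad + n)]
  }
  replace_channels(rec, mat)
}

#' Detect R-wave events in a bandpassed LFP
#'
#' Finds local maxima whose prominence exceeds `prominence_mult` times the
#' standard deviation of the bandpassed signal, separated by at least
#' `60 / max_heart_rate` seconds (at 250 Hz and 120 bpm: 125 samples). If
#' `allow_inversion`, detection also runs on the negated signal — the R wave
#' can invert with electrode geometry — and the polarity yielding more
#' events wins (ties go to positive).
#'
#' @param filtered A bandpassed [lfp_recording()] (see [bandpass_qrs()]).
#' @param channel Channel label or index (default first).
#' @param max_heart_rate Assumed maximum heart rate in bpm (default 120).
#' @param prominence_mult Prominence threshold in units of the filtered
#'   signal's SD (default 2.5).
#' @param allow_inversion Also try the negated signal (default TRUE).
#' @return Tibble of class `r_peak_events` with columns `event_sample`,
#'   `prominence`, `height`; attributes `polarity`, `prominence_threshold`,
#'   `min_peak_distance`, `source_channel`.
#' @export
detect_r_peaks <- function(filtered, channel = NULL, max_heart_rate = 120,
                           prominence_mult = 2.5, allow_inversion = TRUE) {
  channel <- resolve_channel(filtered, channel)
  x <- channel_matrix(filtered, channel)[, 1]
  fs <- sampling_rate(filtered)
  min_dist <- (60 / max_heart_rate) * fs
  thr <- prominence_mult * sd(x)
  run <- function(sig) {
    peaks <- local_maxima(sig)
    if (!length(peaks)) return(integer(0))
    prom <- peak_prominence(sig, peaks)
    keep <- prom >= thr
    enforce_min_distance(peaks[keep], sig[peaks[keep]], min_dist)
  }
  pos <- run(x)
  events <- pos; polarity <- 1L
  if (allow_inversion) {
    neg <- run(-x)
    pick_neg <- length(neg) > length(pos)
    if (length(neg) == length(pos) && length(pos) > 0) {
      # equal counts are common with inverted complexes (filter ringing gives
      # one positive overshoot per beat); the true apex has the larger
      # prominence, so break the tie on mean prominence, then positive
      pick_neg <- mean(peak_prominence(-x, neg)) >
        mean(peak_prominence(x, pos)) * (1 + 1e-9)
    }
    if (pick_neg) { events <- neg; polarity <- -1L }
  }
  sig <- polarity * x
  prom <- if (length(events)) peak_prominence(sig, events) else numeric(0)
  new_tibble(tibble(event_sample = as.integer(events),
                    prominence = prom, height = sig[events]),
             polarity = polarity, prominence_threshold = thr,
             min_peak_distance = min_dist, source_channel = channel,
             class = "r_peak_events")
}

#' Build an average QRS template
#'
#' Averages raw-signal windows `[event - pre, event + post]` around each
#' detected R apex and multiplies by an equal-length symmetric Hanning
#' window, forcing the template edges to exactly zero so subtraction cannot
#' introduce clicks. The template comes from the raw (not bandpassed)
#' signal: the artifact's energy outside 5-30 Hz must be removed too.
#' Events whose window crosses a record boundary are excluded.
#'
#' @param raw The raw [lfp_recording()].
#' @param events An `r_peak_events` tibble (from [detect_r_peaks()]).
#' @param channel Channel label or index (default first).
#' @param pre,post Samples before/after the apex (defaults 36/36; capture of
#'   the Q and S waves needs at least 18 before and 36 after, and a
#'   symmetric Hanning window at least 36 on both sides).
#' @param min_events Minimum usable events (default 10).
#' @param stim_state_tag State tag stored on the template.
#' @return A list of class `qrs_template`: `waveform`, `tapered_waveform`,
#'   `pre`, `post`, `n_events_averaged`, `stim_state`.
#' @export
build_template <- function(raw, events, channel = NULL, pre = 36, post = 36,
                           min_events = 10, stim_state_tag = stim_state(raw)) {
  stopifnot(pre >= 18, post >= 36)
  if (pre != post) {
    warn("asymmetric pre/post: the Hanning taper will be asymmetric around the apex.")
  }
  channel <- resolve_channel(raw, channel)
  x <- channel_matrix(raw, channel)[, 1]
  ev <- events$event_sample
  usable <- ev[ev - pre >= 1 & ev + post <= length(x)]
  if (length(usable) < min_events) {
    abort(sprintf("only %d usable events; need at least %d to average a template.",
                  length(usable), min_events),
          class = "lfpclean_insufficient_events")
  }
  win <- vapply(usable, function(e) x[(e - pre):(e + post)],
                numeric(pre + post + 1))
  waveform <- rowMeans(win)
  taper <- hann_window(pre + post + 1)
  structure(list(waveform = waveform,
                 tapered_waveform = waveform * taper,
                 pre = as.integer(pre), post = as.integer(post),
                 n_events_averaged = length(usable),
                 stim_state = stim_state_tag,
                 channel = channel),
            class = "qrs_template")
}

#' Subtract a QRS template at event times
#'
#' Subtracts the Hanning-tapered template aligned to each R apex. Events
#' whose window would cross a record boundary are skipped (a truncated taper
#' would break the zero-endpoint guarantee) and reported. Samples outside
#' event windows are untouched.
#'
#' @param raw The raw [lfp_recording()].
#' @param template A `qrs_template`.
#' @param events An `r_peak_events` tibble or integer vector of apex samples.
#' @param channel Channel label or index (default first).
#' @return The cleaned recording, with attribute `skipped_events` listing
#'   any boundary-crossing events.
#' @export
subtract_template <- function(raw, template, events, channel = NULL) {
  channel <- resolve_channel(raw, channel)
  mat <- channel_matrix(raw)
  x <- mat[, channel]
  ev <- if (is.data.frame(events)) events$event_sample else as.integer(events)
  ok <- ev - template$pre >= 1 & ev + template$post <= length(x)
  for (e in ev[ok]) {
    idx <- (e - template$pre):(e + template$post)
    x[idx] <- x[idx] - template$tapered_waveform
  }
  mat[, channel] <- x
  out <- replace_channels(raw, mat)
  attr(out, "skipped_events") <- ev[!ok]
  out
}

# detect + per-state template + subtract for one channel, given events
subtract_per_state <- function(raw, events, channel, pre, post, min_events) {
  states <- sample_states(raw)
  ev_state <- states[pmin(pmax(events$event_sample, 1L), nrow(raw))]
  report <- list()
  out <- raw
  for (st in unique(ev_state)) {
    ev_st <- events[ev_state == st, , drop = FALSE]
    tpl <- tryCatch(
      build_template(out, ev_st, channel = channel, pre = pre, post = post,
                     min_events = min_events, stim_state_tag = st),
      lfpclean_insufficient_events = function(e) NULL)
    pooled <- FALSE
    if (is.null(tpl)) {
      # too few events in this state: fall back to a pooled template
      tpl <- build_template(out, events, channel = channel, pre = pre,
                            post = post, min_events = min_events,
                            stim_state_tag = "pooled")
      pooled <- TRUE
    }
    out <- subtract_template(out, tpl, ev_st, channel = channel)
    report[[length(report) + 1]] <- tibble(
      channel = channel, stim_state = st,
      n_events = nrow(ev_st),
      n_events_averaged = tpl$n_events_averaged,
      template_peak_to_peak = diff(range(tpl$tapered_waveform)),
      pooled_template = pooled)
  }
  list(rec = out, report = bind_rows(report))
}

#' Remove the cardiac QRS artifact from a single channel
#'
#' Bandpass (5-30 Hz) -> R-peak detection -> per-stimulation-state average
#' template -> tapered subtraction from the raw signal.
#'
#' @inheritParams detect_r_peaks
#' @param rec The raw [lfp_recording()].
#' @param channel Channel label or index (default first).
#' @param pre,post Template half-windows in samples (see [build_template()]).
#' @param min_events Minimum events required to average a template.
#' @return List with `rec` (cleaned recording), `events`, and `report`
#'   (tibble of per-state template stats).
#' @export
remove_ecg <- function(rec, channel = NULL, max_heart_rate = 120,
                       prominence_mult = 2.5, allow_inversion = TRUE,
                       pre = 36, post = 36, min_events = 10) {
  channel <- resolve_channel(rec, channel)
  filt <- bandpass_qrs(rec)
  events <- detect_r_peaks(filt, channel = channel,
                           max_heart_rate = max_heart_rate,
                           prominence_mult = prominence_mult,
                           allow_inversion = allow_inversion)
  if (nrow(events) == 0) {
    return(list(rec = rec, events = events,
                report = tibble(channel = character(0),
                                stim_state = character(0),
                                n_events = integer(0))))
  }
  res <- subtract_per_state(rec, events, channel, pre, post, min_events)
  list(rec = res$rec, events = events, report = res$report)
}

#' Bilateral cardiac artifact removal with event transfer
#'
#' Cardiac contamination is time-locked across hemispheres, so R-wave times
#' estimated on the hemisphere with the larger artifact are reused to clean
#' both. Events are detected independently on both bandpassed channels; the
#' reference channel is the one with the larger mean detected prominence;
#' its event times are applied to both channels, with separate average
#' templates per channel and per stimulation state.
#'
#' @param left,right Single-channel [lfp_recording()]s of equal length and
#'   sampling rate (or one two-channel recording passed as `left` with
#'   `right = NULL`).
#' @inheritParams remove_ecg
#' @return List with `left`, `right` (cleaned recordings), `reference`
#'   (label of the event-source channel), `events`, and `report`.
#' @export
remove_ecg_bilateral <- function(left, right = NULL, max_heart_rate = 120,
                                 prominence_mult = 2.5, allow_inversion = TRUE,
                                 pre = 36, post = 36, min_events = 10) {
  if (is.null(right)) {
    stopifnot(n_channels(left) == 2)
    labs <- channel_labels(left)
    both <- left
  } else {
    stopifnot(nrow(left) == nrow(right),
              sampling_rate(left) == sampling_rate(right))
    labs <- c("left", "right")
    both <- lfp_recording(cbind(left = channel_matrix(left)[, 1],
                                right = channel_matrix(right)[, 1]),
                          sampling_rate(left), stim_state = stim_state(left),
                          stim_segments = stim_segments(left))
  }
  filt <- bandpass_qrs(both)
  cand <- purrr::map(labs, function(ch)
    detect_r_peaks(filt, channel = ch, max_heart_rate = max_heart_rate,
                   prominence_mult = prominence_mult,
                   allow_inversion = allow_inversion))
  names(cand) <- labs
  mean_prom <- vapply(cand, function(e)
    if (nrow(e)) mean(e$prominence) else -Inf, numeric(1))
  ref <- labs[which.max(mean_prom)]
  events <- cand[[ref]]
  mk_from <- function(rec, ch) {
    m <- channel_matrix(rec, ch)
    colnames(m) <- ch
    lfp_recording(m, sampling_rate(rec), stim_state = stim_state(rec),
                  stim_segments = stim_segments(rec))
  }
  if (nrow(events) == 0) {
    return(list(left = mk_from(both, labs[1]), right = mk_from(both, labs[2]),
                reference = ref, events = events,
                report = tibble(channel = character(0)), cleaned = both))
  }
  out <- both
  reports <- list()
  for (ch in labs) {
    res <- subtract_per_state(out, events, ch, pre, post, min_events)
    out <- res$rec
    reports[[ch]] <- res$report
  }
  list(left = mk_from(out, labs[1]), right = mk_from(out, labs[2]),
       reference = ref, events = events, report = bind_rows(reports),
       cleaned = out)
}
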