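#' LFP recording container
#'
#' An `lfp_recording` is a tibble with a `time_s` column followed by one
#' numeric column per channel (microvolts), carrying the sampling rate and
#' stimulation-state annotation as attributes. All pipeline stages take and
#' return this class, so calls chain with the pipe.
#'
#' @param data A data frame / tibble with a `time_s` column and one numeric
#'   column per channel, or a numeric matrix (columns = channels), or a bare
#'   numeric vector (one channel).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Optional channel names; defaults to existing column
#'   names or `"ch1"`, `"ch2"`, ...
#' @param stim_state Stimulation state annotation: `"on"`, `"off"` or
#'   `"mixed"`.
#' @param stim_segments Optional tibble of stimulation-on intervals with
#'   columns `start_s`, `end_s` and optionally `amplitude_mA`.
#' @param provenance Free-text provenance note.
#' @return A tibble of class `lfp_recording`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 10 * (0:999) / 250), sampling_rate = 250)
#' sampling_rate(rec)
#' channel_labels(rec)
#' @export
lfp_recording <- function(data, sampling_rate, channel_labels = NULL,
                          stim_state = c("off", "on", "mixed"),
                          stim_segments = NULL, provenance = NULL) {
  assert_positive_scalar(sampling_rate, "sampling_rate")
  stim_state <- match.arg(stim_state)
  if (is.numeric(data) && is.null(dim(data))) data <- matrix(data, ncol = 1)
  if (is.matrix(data)) {
    labels <- channel_labels %||% colnames(data) %||%
      paste0("ch", seq_len(ncol(data)))
    n <- nrow(data)
    df <- as_tibble(as.data.frame(data), .name_repair = "minimal")
    names(df) <- labels
    df <- dplyr::bind_cols(tibble(time_s = (seq_len(n) - 1) / sampling_rate), df)
  } else {
    df <- as_tibble(data)
    if (!"time_s" %in% names(df)) {
      df <- dplyr::bind_cols(
        tibble(time_s = (seq_len(nrow(df)) - 1) / sampling_rate), df)
    }
    labels <- channel_labels %||% setdiff(names(df), "time_s")
    df <- df[, c("time_s", labels)]
  }
  new_tibble(df,
             sampling_rate = sampling_rate,
             channel_labels = labels,
             stim_state = stim_state,
             stim_segments = stim_segments,
             provenance = provenance,
             class = "lfp_recording")
}

#' @rdname lfp_recording
#' @param rec An `lfp_recording`.
#' @export
sampling_rate <- function(rec) attr(rec, "sampling_rate")

#' @rdname lfp_recording
#' @export
channel_labels <- function(rec) attr(rec, "channel_labels")

#' @rdname lfp_recording
#' @export
stim_state <- function(rec) attr(rec, "stim_state")

#' @rdname lfp_recording
#' @export
stim_segments <- function(rec) attr(rec, "stim_segments")

#' @rdname lfp_recording
#' @export
n_channels <- function(rec) length(channel_labels(rec))

#' Extract the sample matrix of a recording
#'
#' @param rec An `lfp_recording`.
#' @param channels Channels to keep (labels or indices); default all.
#' @return Numeric matrix, one column per channel.
#' @export
channel_matrix <- function(rec, channels = NULL) {
  labels <- channel_labels(rec)
  if (!is.null(channels)) {
    if (is.numeric(channels)) channels <- labels[channels]
    stopifnot(all(channels %in% labels))
    labels <- channels
  }
  as.matrix(rec[, labels, drop = FALSE])
}

# rebuild a recording with new sample values, keeping all metadata
replace_channels <- function(rec, mat) {
  stopifnot(nrow(mat) == nrow(rec))
  out <- rec
  out[channel_labels(rec)] <- as.data.frame(mat)
  out
}

# per-sample stimulation state from the stim_segments annotation
sample_states <- function(rec) {
  seg <- stim_segments(rec)
  if (is.null(seg) || nrow(seg) == 0) {
    return(rep(stim_state(rec), nrow(rec)))
  }
  st <- rep("off", nrow(rec))
  for (i in seq_len(nrow(seg))) {
    st[rec$time_s >= seg$start_s[i] & rec$time_s < seg$end_s[i]] <- "on"
  }
  st
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d samples x %d channel(s) @ %g Hz (%.6g s), stim %s\n",
              nrow(x), n_channels(x), sampling_rate(x),
              nrow(x) / sampling_rate(x), stim_state(x)))
  NextMethod()
}
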