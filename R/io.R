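#' Write a recording as CSV + JSON sidecar
#'
#' The on-disk format is a CSV with a `time_s` column plus one column per
#' channel (uV), and a JSON sidecar carrying `sampling_rate_hz`,
#' `duration_s`, `channel_labels`, `stim_state`, optional `stim_segments`
#' and free-text `provenance`. Plain text, diff-able, desk-scale.
#'
#' @param rec An [lfp_recording()].
#' @param path Base path; `.csv` and `.json` are appended (a `.csv`
#'   extension is stripped first).
#' @return The base path, invisibly.
#' @export
write_recording <- function(rec, path) {
  base <- sub("\\.csv$", "", path)
  readr::write_csv(as_tibble(as.data.frame(rec)), paste0(base, ".csv"))
  seg <- stim_segments(rec)
  jsonlite::write_json(
    list(sampling_rate_hz = sampling_rate(rec),
         duration_s = nrow(rec) / sampling_rate(rec),
         channel_labels = as.list(channel_labels(rec)),
         stim_state = stim_state(rec),
         stim_segments = seg,
         provenance = attr(rec, "provenance") %||% "lfpclean"),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(base)
}

#' Read a recording from CSV + JSON sidecar
#'
#' Validates the format invariants: the sidecar must exist; the row count
#' must match `sampling_rate_hz * duration_s` within one sample; `time_s`
#' must increase with constant step `1/sampling_rate_hz` within 1e-9 s.
#'
#' @param path Base path or the `.csv` path.
#' @return An [lfp_recording()].
#' @export
read_recording <- function(path) {
  base <- sub("\\.csv$", "", path)
  csv <- paste0(base, ".csv"); sidecar <- paste0(base, ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("missing sidecar '%s'.", sidecar), class = "lfpclean_io_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  meta$sampling_rate_hz <- as.numeric(meta$sampling_rate_hz)
  df <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    abort(sprintf("'%s' contains no samples.", csv), class = "lfpclean_empty_file")
  }
  fs <- meta$sampling_rate_hz
  if (!is.null(meta$duration_s) &&
      abs(nrow(df) - fs * meta$duration_s) > 1) {
    abort(sprintf("row count %d inconsistent with sampling_rate_hz %g x duration_s %g (= %g).",
                  nrow(df), fs, meta$duration_s, fs * meta$duration_s),
          class = "lfpclean_io_error")
  }
  steps <- diff(df$time_s)
  if (any(steps <= 0) || any(abs(steps - 1 / fs) > 1e-9)) {
    abort("`time_s` must increase with constant step 1/sampling_rate_hz (tol 1e-9 s).",
          class = "lfpclean_io_error")
  }
  seg <- meta$stim_segments
  lfp_recording(df, fs,
                channel_labels = unlist(meta$channel_labels),
                stim_state = meta$stim_state %||% "mixed",
                stim_segments = if (!is.null(seg) && length(seg)) as_tibble(seg),
                provenance = meta$provenance)
}

# pull one time-domain entry (list with TimeDomainData etc.) into a tibble row
percept_entry <- function(e) {
  data <- e$TimeDomainData %||% e$time_domain_data
  rate <- e$SampleRateInHz %||% e$sample_rate_in_hz %||% e$SampleRate
  if (is.null(data) || is.null(rate) || !length(data)) return(NULL)
  list(channel = as.character(e$Channel %||% e$channel %||% "unknown"),
       rate = as.numeric(rate)[1],
       start = as.character(e$FirstPacketDateTime %||% e$first_packet_date_time %||% ""),
       data = as.numeric(unlist(data)))
}

#' Best-effort ingestion of Percept-style session JSON
#'
#' Scans a device session export for time-domain sections
#' (`BrainSenseTimeDomain`, `IndefiniteStreaming`) and extracts any arrays
#' found with their per-array sampling rate and channel label. Entries
#' sharing a start timestamp and length are grouped into one multi-channel
#' recording. Entries that cannot be parsed are skipped with a logged
#' reason. Stimulation state is never fabricated: recordings are marked
#' `"mixed"`. The vendor dialect is not publicly specified; coverage is
#' limited to community-documented key names.
#'
#' @param path Path to the session JSON.
#' @return List of [lfp_recording()]s (possibly empty, with a warning).
#' @export
read_percept_json <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) {
                    ok <- jsonlite::validate(txt)
                    abort(paste0("malformed JSON in '", path, "': ",
                                 attr(ok, "err") %||% conditionMessage(e)),
                          class = "lfpclean_parse_error")
                  })
  sections <- c(doc$BrainSenseTimeDomain, doc$IndefiniteStreaming)
  entries <- list()
  for (e in sections) {
    parsed <- tryCatch(percept_entry(e), error = function(err) NULL)
    if (is.null(parsed)) {
      inform("skipped one session entry: no usable time-domain array.")
    } else {
      entries[[length(entries) + 1]] <- parsed
    }
  }
  if (!length(entries)) {
    warn("no time-domain content found in session export.")
    return(list())
  }
  keys <- vapply(entries, function(e)
    sprintf("%s|%g|%d", e$start, e$rate, length(e$data)), character(1))
  purrr::map(split(entries, keys), function(grp) {
    mat <- vapply(grp, `[[`, numeric(length(grp[[1]]$data)), "data")
    labels <- make.unique(vapply(grp, `[[`, character(1), "channel"))
    colnames(mat) <- labels
    lfp_recording(mat, grp[[1]]$rate, stim_state = "mixed",
                  provenance = sprintf("percept session '%s' @ %s",
                                       basename(path), grp[[1]]$start))
  }) |> unname()
}
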