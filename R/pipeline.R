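#' Pipeline configuration
#'
#' All stage parameters with their defaults, plus stage enable flags and a
#' global seed. Serializes round-trip stable through JSON
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param ecg Enable cardiac QRS removal (default TRUE).
#' @param rejection Enable spectrogram window rejection (default TRUE).
#' @param detrend Enable aperiodic detrending (default TRUE).
#' @param max_heart_rate,prominence_mult,allow_inversion,pre,post,min_events
#'   ECG-stage parameters (see [remove_ecg_bilateral()]).
#' @param window_sec,overlap,half_bandwidth,method Spectral parameters (see
#'   [spectral_params()]).
#' @param alpha,band_corr,band_lowfreq Rejection parameters (see
#'   [background_psd()]).
#' @param rejection_method `"threshold"`, `"pca"` or `"both"`.
#' @param fit_band,high_band,min_prominence Detrend parameters (see
#'   [fit_aperiodic()]).
#' @param seed Global seed recorded in the run log.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(ecg = TRUE, rejection = TRUE, detrend = TRUE,
                            max_heart_rate = 120, prominence_mult = 2.5,
                            allow_inversion = TRUE, pre = 36, post = 36,
                            min_events = 10,
                            window_sec = 2, overlap = 0.5,
                            half_bandwidth = 1,
                            method = "multitaper",
                            alpha = 0.05, band_corr = c(4, 75),
                            band_lowfreq = c(0, 5.3),
                            rejection_method = "threshold",
                            fit_band = c(4, 75), high_band = c(55, 75),
                            min_prominence = 0.05, seed = 1) {
  cfg <- list(stages = list(ecg = ecg, rejection = rejection, detrend = detrend),
              ecg = list(max_heart_rate = max_heart_rate,
                         prominence_mult = prominence_mult,
                         allow_inversion = allow_inversion,
                         pre = pre, post = post, min_events = min_events),
              spectral = list(window_sec = window_sec, overlap = overlap,
                              half_bandwidth = half_bandwidth, method = method),
              rejection = list(alpha = alpha, band_corr = band_corr,
                               band_lowfreq = band_lowfreq,
                               method = rejection_method),
              detrend = list(fit_band = fit_band, high_band = high_band,
                             min_prominence = min_prominence),
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, list(
    ecg = raw$stages$ecg, rejection = raw$stages$rejection,
    detrend = raw$stages$detrend,
    max_heart_rate = raw$ecg$max_heart_rate,
    prominence_mult = raw$ecg$prominence_mult,
    allow_inversion = raw$ecg$allow_inversion,
    pre = raw$ecg$pre, post = raw$ecg$post, min_events = raw$ecg$min_events,
    window_sec = raw$spectral$window_sec, overlap = raw$spectral$overlap,
    half_bandwidth = raw$spectral$half_bandwidth, method = raw$spectral$method,
    alpha = raw$rejection$alpha, band_corr = raw$rejection$band_corr,
    band_lowfreq = raw$rejection$band_lowfreq,
    rejection_method = raw$rejection$method,
    fit_band = raw$detrend$fit_band, high_band = raw$detrend$high_band,
    min_prominence = raw$detrend$min_prominence, seed = raw$seed))
}

#' Run the full preprocessing pipeline
#'
#' Executes the stages in their fixed order — cardiac QRS removal in the
#' time domain first (predictable transient interference is best removed
#' before any transform), then the short-time frequency transform, rejection
#' of nonstationary windows, background PSD estimation, and finally the
#' aperiodic 1/f fit and detrend. Stages can be disabled via the config but
#' never reordered. Any stage error aborts with the stage name; outputs of
#' completed stages are preserved in the error condition.
#'
#' @param input An [lfp_recording()] or a path readable by
#'   [read_recording()].
#' @param config A [pipeline_config()].
#' @param channel Channel to carry through the spectral stages (default: the
#'   ECG reference channel if the ECG stage ran on two channels, else the
#'   first channel).
#' @param out_dir Optional directory; if given, stage outputs and a
#'   machine-readable JSON run log are written there.
#' @return List of class `lfp_pipeline_result`: `config`, `config_hash`,
#'   `recording` (post-ECG), `ecg`, `spectrogram`, `background`, `aperiodic`
#'   (two-pass fit results), `log`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), channel = NULL,
                         out_dir = NULL) {
  rec <- if (is.character(input)) read_recording(input) else input
  stopifnot(inherits(rec, "lfp_recording"))
  cfg_hash <- rlang::hash(unclass(config))
  log <- list(config_hash = cfg_hash, seed = config$seed,
              package_version = as.character(utils::packageVersion("lfpclean")),
              stages = list())
  results <- list(config = config, config_hash = cfg_hash)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "lfpclean_stage_failure", partial = results)
    })
  }

  ecg <- NULL
  if (isTRUE(config$stages$ecg)) {
    ecg <- run_stage("ecg", {
      p <- config$ecg
      if (n_channels(rec) >= 2) {
        res <- remove_ecg_bilateral(rec, max_heart_rate = p$max_heart_rate,
                                    prominence_mult = p$prominence_mult,
                                    allow_inversion = p$allow_inversion,
                                    pre = p$pre, post = p$post,
                                    min_events = p$min_events)
        rec <<- res$cleaned
        res
      } else {
        res <- remove_ecg(rec, max_heart_rate = p$max_heart_rate,
                          prominence_mult = p$prominence_mult,
                          allow_inversion = p$allow_inversion,
                          pre = p$pre, post = p$post,
                          min_events = p$min_events)
        rec <<- res$rec
        res
      }
    })
    log$stages$ecg <- list(n_events = nrow(ecg$events),
                           reference = ecg$reference %||% channel_labels(rec)[1])
  }
  results$recording <- rec
  results$ecg <- ecg
  channel <- channel %||% ecg$reference %||% channel_labels(rec)[1]

  sp <- config$spectral
  params <- spectral_params(sampling_rate(rec), window_sec = sp$window_sec,
                            overlap = sp$overlap,
                            method = sp$method,
                            half_bandwidth = if (sp$method == "multitaper")
                              sp$half_bandwidth else NULL)
  sg <- run_stage("spectrogram",
                  short_time_spectrogram(rec, params, channel = channel))
  results$spectrogram <- sg
  log$stages$spectrogram <- list(n_windows = attr(sg, "n_windows"),
                                 n_tapers = params$n_tapers)

  bg <- run_stage("rejection", {
    r <- config$rejection
    if (!isTRUE(config$stages$rejection)) {
      background_psd(sg, use_correlation = FALSE, use_lowfreq = FALSE)
    } else if (identical(r$method, "pca")) {
      pca_background(sg, band = r$band_corr)
    } else {
      background_psd(sg, alpha = r$alpha, band_corr = r$band_corr,
                     band_lowfreq = r$band_lowfreq)
    }
  })
  results$background <- bg
  log$stages$rejection <- list(
    method = attr(bg, "background_method"),
    n_rejected = length(attr(bg, "rejected_windows") %||% integer(0)),
    kept = length(attr(bg, "kept_windows")))

  if (isTRUE(config$stages$detrend)) {
    d <- config$detrend
    results$aperiodic <- run_stage("detrend",
      fit_aperiodic(bg, band = d$fit_band, high_band = d$high_band,
                    prominence = d$min_prominence))
    log$stages$detrend <- list(
      initial = results$aperiodic$initial[c("k", "x", "b")],
      refined = results$aperiodic$refined[c("k", "x", "b")],
      n_minima = length(results$aperiodic$minima))
  }
  results$log <- log

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_recording(results$recording, file.path(out_dir, "cleaned"))
    readr::write_csv(as_tibble(as.data.frame(bg)),
                     file.path(out_dir, "background_psd.csv"))
    if (!is.null(results$aperiodic)) {
      readr::write_csv(as_tibble(as.data.frame(results$aperiodic$detrended)),
                       file.path(out_dir, "detrended.csv"))
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
    write_pipeline_config(config, file.path(out_dir, "config.json"))
  }
  structure(results, class = "lfp_pipeline_result")
}
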