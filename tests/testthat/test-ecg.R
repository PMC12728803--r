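test_that("QRS bandpass has unit passband gain, kills DC, attenuates 60 Hz", {
  fs <- 250; n <- 5000; t <- (0:(n - 1)) / fs
  mid <- 500:4500   # avoid edge transients of the reflection padding
  sine15 <- lfp_recording(sin(2 * pi * 15 * t), fs)
  out15 <- channel_matrix(bandpass_qrs(sine15))[, 1]
  gain <- sd(out15[mid]) / sd(sin(2 * pi * 15 * t)[mid])
  expect_gt(gain, 0.95); expect_lt(gain, 1.05)

  dc <- lfp_recording(rep(3, n), fs)
  expect_lt(max(abs(channel_matrix(bandpass_qrs(dc)))), 1e-6 * 3)

  # oracle: the designed filter's squared magnitude response at 60 Hz,
  # applied twice by forward-backward filtering
  bf <- signal::butter(4, c(5, 30) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 60 / fs)
  H <- abs(sum(bf$b * z^(0:(length(bf$b) - 1))) /
             sum(bf$a * z^(0:(length(bf$a) - 1))))
  atten_db <- -40 * log10(H)          # |H|^2 for zero-phase application
  expect_gt(atten_db, 20)
  sine60 <- lfp_recording(sin(2 * pi * 60 * t), fs)
  out60 <- channel_matrix(bandpass_qrs(sine60))[, 1]
  expect_lt(sd(out60[mid]) / sd(sin(2 * pi * 60 * t)[mid]), 10^(-20 / 20))

  expect_error(bandpass_qrs(lfp_recording(rnorm(100), fs)),
               class = "lfpclean_too_short")
  expect_error(bandpass_qrs(lfp_recording(rnorm(1000), 50)),
               class = "lfpclean_invalid_argument")
})

test_that("R-peak detection matches ground truth and reports its settings", {
  zero <- lfp_recording(numeric(5000), 250)
  ev0 <- detect_r_peaks(zero)
  expect_equal(nrow(ev0), 0)
  expect_equal(attr(ev0, "polarity"), 1L)
  expect_equal(attr(ev0, "min_peak_distance"), 125)   # 0.5 s at 250 Hz / 120 bpm

  spec <- sim_spec(duration = 60, seed = 31,
                   qrs = list(heart_rate = 60, rate_jitter = 0, amplitude = 50,
                              polarity = 1, channel_scales = c(ch1 = 1)),
                   channels = "ch1")
  sim <- assemble_recording(spec)
  ev <- detect_r_peaks(bandpass_qrs(sim$recording))
  m <- detection_metrics(ev$event_sample, sim$truth$qrs_event_samples, tol = 2)
  expect_equal(unname(m["recall"]), 1)
  # jitter-free trains can superpose filter ringing exactly midway between
  # beats, which occasionally clears the 2.5-sigma prominence rule
  expect_gte(unname(m["precision"]), 0.95)

  # inverted QRS is found on the negated signal
  speci <- sim_spec(duration = 60, seed = 31,
                    qrs = list(heart_rate = 60, rate_jitter = 0, amplitude = 50,
                               polarity = -1, channel_scales = c(ch1 = 1)),
                    channels = "ch1")
  simi <- assemble_recording(speci)
  evi <- detect_r_peaks(bandpass_qrs(simi$recording))
  expect_equal(attr(evi, "polarity"), -1L)
  mi <- detection_metrics(evi$event_sample, simi$truth$qrs_event_samples, tol = 2)
  expect_equal(unname(mi["recall"]), 1)
})

test_that("template averaging converges to the event waveform", {
  fs <- 250; w <- qrs_waveform_fixture <- sin(seq(0, pi, length.out = 73))
  make_trace <- function(n_events, noise_sd, seed) {
    withr::with_seed(seed, {
      n <- 80 * (n_events + 1)
      x <- rnorm(n, sd = noise_sd)
      events <- 80 * seq_len(n_events)
      for (e in events) x[(e - 36):(e + 36)] <- x[(e - 36):(e + 36)] + w
      list(rec = lfp_recording(x, fs),
           ev = tibble::tibble(event_sample = events))
    })
  }
  # identical windows reproduce the waveform exactly
  t0 <- make_trace(12, noise_sd = 0, seed = 1)
  tpl0 <- build_template(t0$rec, t0$ev)
  expect_equal(tpl0$waveform, w, tolerance = 1e-12)
  expect_identical(tpl0$tapered_waveform[1], 0)
  expect_identical(tpl0$tapered_waveform[73], 0)

  # max error shrinks like 1/sqrt(n): n = 10 vs n = 1000
  errs <- vapply(c(10, 1000), function(n) {
    tt <- make_trace(n, noise_sd = 1, seed = n)
    max(abs(build_template(tt$rec, tt$ev)$waveform - w))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 10 / 3)   # ~sqrt(100) = 10, generous both ways
  expect_lt(errs[1] / errs[2], 30)

  expect_error(build_template(t0$rec, t0$ev[1:3, ]),
               class = "lfpclean_insufficient_events")
})

test_that("template subtraction cancels the artifact and nothing else", {
  fs <- 250
  spec <- sim_spec(duration = 30, seed = 17, channels = "ch1",
                   qrs = list(heart_rate = 70, rate_jitter = 0.02, amplitude = 40,
                              polarity = 1, channel_scales = c(ch1 = 1)))
  sim <- assemble_recording(spec)
  rec <- sim$recording
  ev <- detect_r_peaks(bandpass_qrs(rec))
  tpl <- build_template(rec, ev)

  # zero template: identity
  tpl0 <- tpl; tpl0$tapered_waveform <- numeric(73)
  expect_equal(channel_matrix(subtract_template(rec, tpl0, ev)),
               channel_matrix(rec), tolerance = 0)

  # exact self-cancellation of a tapered-template train
  n <- 7500
  x <- numeric(n); events <- seq(500, 7000, by = 300)
  for (e in events) x[(e - 36):(e + 36)] <- x[(e - 36):(e + 36)] + tpl$tapered_waveform
  out <- subtract_template(lfp_recording(x, fs), tpl, events)
  expect_lt(max(abs(channel_matrix(out))), 1e-9)

  # samples outside event windows are untouched, exactly
  cleaned <- subtract_template(rec, tpl, ev)
  touched <- unique(unlist(lapply(ev$event_sample,
                                  function(e) (e - 36):(e + 36))))
  untouched <- setdiff(seq_len(nrow(rec)), touched)
  expect_identical(channel_matrix(cleaned)[untouched, 1],
                   channel_matrix(rec)[untouched, 1])

  # boundary events are skipped and reported
  ev_edge <- tibble::tibble(event_sample = c(10L, ev$event_sample[1]))
  out_edge <- subtract_template(rec, tpl, ev_edge)
  expect_equal(attr(out_edge, "skipped_events"), 10L)
})

test_that("cleaning restores band power and never increases theta/alpha/beta", {
  spec <- sim_spec(duration = 60, seed = 23)
  sim <- assemble_recording(spec)
  res <- remove_ecg_bilateral(sim$recording)
  expect_equal(res$reference, "right")   # larger per-channel QRS scale

  for (band in list(c(4, 8), c(8, 12), c(12, 30))) {
    p_before <- band_power(welch_psd(sim$recording, channel = "right"), band)
    p_after <- band_power(welch_psd(res$right, channel = "right"), band)
    expect_lte(p_after, p_before)
  }
  p_clean <- band_power(welch_psd(sim$truth$clean, channel = "right"), c(4, 30))
  p_cleaned <- band_power(welch_psd(res$right, channel = "right"), c(4, 30))
  expect_lt(abs(p_cleaned - p_clean) / p_clean, 0.1)

  # weak channel: cleaning with transferred events reduces band-power error
  pl_clean <- band_power(welch_psd(sim$truth$clean, channel = "left"), c(4, 30))
  pl_raw <- band_power(welch_psd(sim$recording, channel = "left"), c(4, 30))
  pl_cleaned <- band_power(welch_psd(res$left, channel = "left"), c(4, 30))
  expect_lt(abs(pl_cleaned - pl_clean), abs(pl_raw - pl_clean))
})

test_that("bilateral removal builds per-state templates and handles no-QRS input", {
  seg <- tibble::tibble(start_s = 30, end_s = 60, amplitude_mA = 2)
  spec <- sim_spec(duration = 60, seed = 5, stim_segments = seg,
                   qrs = list(heart_rate = 70, rate_jitter = 0.03, amplitude = 40,
                              polarity = 1,
                              channel_scales = c(left = 0.2, right = 1),
                              stim_on_scale = 1.6))
  sim <- assemble_recording(spec)
  res <- remove_ecg_bilateral(sim$recording)
  rep_right <- res$report[res$report$channel == "right", ]
  expect_setequal(rep_right$stim_state, c("on", "off"))
  amp_on <- rep_right$template_peak_to_peak[rep_right$stim_state == "on"]
  amp_off <- rep_right$template_peak_to_peak[rep_right$stim_state == "off"]
  expect_gt(amp_on / amp_off, 1.3)   # generator scales stim-on QRS by 1.6
  expect_true(all(rep_right$n_events_averaged >= 10))

  # no QRS injected: quiescent output equals input
  spec0 <- sim_spec(duration = 20, seed = 9, qrs = list(heart_rate = 0))
  sim0 <- assemble_recording(spec0)
  res0 <- remove_ecg_bilateral(sim0$recording)
  if (nrow(res0$events) == 0) {
    expect_equal(channel_matrix(res0$cleaned), channel_matrix(sim0$recording),
                 tolerance = 0)
  } else {
    # spurious noise peaks may trip the 2.5-sigma rule; the subtraction must
    # then be small relative to the signal
    delta <- channel_matrix(res0$cleaned) - channel_matrix(sim0$recording)
    expect_lt(sd(delta), 0.5 * sd(channel_matrix(sim0$recording)))
  }
})
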