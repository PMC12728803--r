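test_that("Grubbs threshold matches an independently derived critical value", {
  expect_equal(grubbs_threshold(10, 0.05), 2.290, tolerance = 1e-3)
  for (N in c(3:10, 20, 50, 100, 200)) {
    for (alpha in c(0.01, 0.05)) {
      expect_equal(grubbs_threshold(N, alpha), grubbs_oracle(N, alpha),
                   tolerance = 1e-6)
    }
  }
  thr <- vapply(3:200, grubbs_threshold, numeric(1), alpha = 0.05)
  expect_true(all(diff(thr) > 0))                   # increasing in N
  expect_lt(grubbs_threshold(30, 0.99), grubbs_threshold(30, 0.01))
  expect_error(grubbs_threshold(2), class = "lfpclean_invalid_argument")
})

test_that("correlation filter rejects shape outliers but not dB offsets", {
  freqs <- seq(0, 125, by = 250 / 512)
  base_shape <- 10 - 15 * log10(pmax(freqs, 0.5))
  withr::with_seed(77, {
    db <- replicate(30, base_shape + rnorm(length(freqs), sd = 1.5))
  })
  # identical windows: SD of the statistic is 0, nothing rejected
  same <- sg_from_db(matrix(base_shape, length(freqs), 10))
  expect_false(any(correlation_outliers(same)$rejected))

  # one window with a distinct narrowband bump -> exactly that one rejected
  db_out <- db
  db_out[, 12] <- db_out[, 12] + 15 * exp(-0.5 * ((freqs - 40) / 2)^2)
  res <- correlation_outliers(sg_from_db(db_out))
  expect_identical(which(res$rejected), 12L)

  # a pure broadband offset preserves shape: invisible to correlation
  db_off <- db
  db_off[, 7] <- db_off[, 7] + 12
  res_off <- correlation_outliers(sg_from_db(db_off))
  expect_false(res_off$rejected[7])
  # ... which is exactly what the power filter is for
  res_pow <- lowfreq_power_outliers(sg_from_db(db_off), band = c(0, 125))
  expect_true(res_pow$rejected[7])

  # z-scores standardize across windows
  expect_equal(mean(res$z), 0, tolerance = 1e-10)
  expect_equal(sd(res$z), 1, tolerance = 1e-10)
})

test_that("low-frequency power filter flags transient-bearing windows", {
  tr <- tibble::tibble(onset = 14.3, duration = 0.15, amplitude = 200, kind = "ied")
  sim <- assemble_recording(background_spec(31, seed = 55, transients = tr))
  sg <- short_time_spectrogram(sim$recording)
  res <- lowfreq_power_outliers(sg)
  tw <- sim$truth$transient_windows
  touched <- windows_touching(attr(sg, "n_windows"), tw$start_sample, tw$end_sample)
  expect_true(all(touched %in% which(res$rejected)))

  flat <- sg_from_db(matrix(5, 257, 12))
  expect_false(any(lowfreq_power_outliers(flat)$rejected))
})

test_that("rejection is permutation-equivariant and duplicate-stable", {
  freqs <- seq(0, 125, by = 250 / 512)
  withr::with_seed(91, {
    db <- replicate(20, 8 - 12 * log10(pmax(freqs, 0.5)) + rnorm(257, sd = 1))
  })
  db[, 5] <- db[, 5] + 20 * exp(-0.5 * ((freqs - 30) / 3)^2)
  res <- correlation_outliers(sg_from_db(db))
  perm <- withr::with_seed(1, sample(20))
  res_p <- correlation_outliers(sg_from_db(db[, perm]))
  expect_identical(which(res_p$rejected), which(perm %in% which(res$rejected)))

  # duplicating an inlier never newly rejects previous inliers
  inliers <- setdiff(1:20, which(res$rejected))
  db_dup <- cbind(db, db[, inliers[1]])
  res_d <- correlation_outliers(sg_from_db(db_dup))
  expect_true(all(setdiff(which(res_d$rejected), 21) %in% which(res$rejected)))
})

test_that("background averaging keeps survivors in linear power", {
  # no outliers: background within 1 dB per bin of the plain average
  sim <- assemble_recording(background_spec(31, seed = 61))
  sg <- short_time_spectrogram(sim$recording)
  bg <- background_psd(sg)
  raw_db <- 10 * log10(rowMeans(spectrogram_matrix(sg, "power")))
  expect_lt(max(abs(bg$power_db - raw_db)), 1)

  # single window, filters off: background is that window
  one <- sg_from_db(matrix(3 - 10 * log10(pmax(seq(0, 125, by = 250 / 512), 0.5)),
                           ncol = 1))
  bg1 <- background_psd(one, use_correlation = FALSE, use_lowfreq = FALSE)
  expect_equal(bg1$power, one$power, tolerance = 1e-12)

  # transient contamination: rejection sharpens the beta peak
  tr <- tibble::tibble(onset = 14.3, duration = 0.15, amplitude = 200,
                       kind = "ied")
  spec <- sim_spec(duration = 31, seed = 63, channels = "ch1",
                   qrs = list(heart_rate = 0),
                   oscillations = tibble::tibble(center_freq = 20, bandwidth = 3,
                                                 amplitude = 2),
                   transients = tr)
  sim2 <- assemble_recording(spec)
  sg2 <- short_time_spectrogram(sim2$recording)
  bg2 <- background_psd(sg2)
  peak_height <- function(p) {
    sel <- p$frequency >= 15 & p$frequency <= 25
    shoulder <- p$frequency >= 32 & p$frequency <= 45
    max(p$power_db[sel]) - mean(p$power_db[shoulder])
  }
  raw <- lfpclean:::new_psd(bg2$frequency,
                            rowMeans(spectrogram_matrix(sg2, "power")),
                            attr(sg2, "params"))
  expect_gt(peak_height(bg2), peak_height(raw))

  # fewer than 3 windows: the Grubbs filters cannot run, all windows kept
  two <- sg_from_db(matrix(c(5, 6), 257, 2, byrow = FALSE))
  bg_two <- background_psd(two)
  expect_identical(attr(bg_two, "kept_windows"), 1:2)
})

test_that("PCA background recovers rank-1 structure and beats the raw mean", {
  freqs <- seq(0, 125, by = 250 / 512)
  shape <- exp(-0.5 * ((freqs - 20) / 10)^2)
  amps <- seq(2, 6, length.out = 12)
  db <- vapply(amps, function(a) a * shape + 4, numeric(length(freqs)))
  pb <- pca_background(sg_from_db(db))
  pc1 <- attr(pb, "pc1")
  sel <- freqs >= 4 & freqs <= 75
  shape_c <- shape[sel] - mean(shape[sel])
  cosine <- abs(sum(pc1 * shape_c)) / sqrt(sum(pc1^2) * sum(shape_c^2))
  expect_gt(cosine, 0.999)

  # orientation: PC1 background correlates positively with the mean PSD
  sim <- assemble_recording(background_spec(31, seed = 71))
  sg <- short_time_spectrogram(sim$recording)
  pb2 <- pca_background(sg)
  m <- spectrogram_matrix(sg, "power_db")
  sel2 <- attr(m, "frequencies") >= 4 & attr(m, "frequencies") <= 75
  expect_gt(cor(pb2$power_db[sel2], rowMeans(m)[sel2]), 0)

  # majority-clean + 3 contaminated windows: PC1 estimate closer to truth
  wins <- vapply(1:10, function(s) {
    tr <- tibble::tibble(onset = c(5.3, 14.3), duration = c(0.5, 0.15),
                         amplitude = c(100, 200), kind = c("stim_edge", "ied"))
    simc <- assemble_recording(background_spec(31, seed = 500 + s, transients = tr))
    sgc <- short_time_spectrogram(simc$recording)
    pbc <- pca_background(sgc)
    f <- pbc$frequency; selc <- f >= 4 & f <= 75
    truth_db <- 10 * log10(lfpclean:::background_density(f[selc], 2, 1.5, 1))
    raw_db <- 10 * log10(rowMeans(spectrogram_matrix(sgc, "power")))[selc]
    mean(abs(pbc$power_db[selc] - truth_db)) < mean(abs(raw_db - truth_db))
  }, logical(1))
  expect_gte(mean(wins), 0.8)

  expect_error(pca_background(sg_from_db(matrix(5, 257, 1))),
               class = "lfpclean_invalid_argument")
})
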