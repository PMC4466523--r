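test_that("velum curve construction: baseline, pulses, merging", {
  # empty schedule
  v0 <- make_velum_curve(NULL, fps = 14, duration = 2)
  expect_length(v0$curve$values, 28L)
  expect_true(all(v0$curve$values == 0))
  expect_equal(nrow(v0$intervals), 0L)

  # one nasal event: single maximum of 1 inside the support, 0 outside
  v1 <- single_pulse_curve(onset = 1, open = 0.5, fps = 14, duration = 3)
  t <- (seq_along(v1$curve$values) - 1) / 14
  inside <- t > 1 & t < 1.5
  expect_true(max(v1$curve$values[inside]) > 0.9)
  expect_true(all(v1$curve$values[!inside] == 0))
  expect_equal(v1$intervals, cbind(1, 1.5))

  # overlapping pulses merge by pointwise maximum; nonzero-sample count
  # matches direct enumeration over the merged support
  sched <- data.frame(onset = c(1.0, 1.4), kind = "nasal",
                      open_duration = c(0.5, 0.5))
  fps <- 100
  v2 <- make_velum_curve(sched, fps, 3)
  tt <- (seq_along(v2$curve$values) - 1) / fps
  # enumeration oracle: a sample is nonzero iff strictly inside a pulse
  in_any <- (tt > 1.0 & tt < 1.5) | (tt > 1.4 & tt < 1.9)
  expect_equal(sum(v2$curve$values > 0), sum(in_any))
  expect_equal(nrow(v2$intervals), 1L)
  expect_equal(as.numeric(v2$intervals), c(1.0, 1.9))

  # event outside duration errors
  bad <- data.frame(onset = 2.8, kind = "nasal", open_duration = 0.5)
  expect_error(make_velum_curve(bad, 14, 3), "outside duration")
})

test_that("EMG generator: SNR contract, burst placement, determinism", {
  cfg0 <- scenario_config(n_utterances = 2, n_channels = 1,
                          burst_snr = 0, crosstalk = matrix(1),
                          burst_gain = 1, seed = 5)
  sched <- cfg0$vowel_schedule
  iv <- cbind(sched$onset, sched$onset + sched$open_duration)
  dur <- max(iv) + 0.5
  vc <- velum_curve(numeric(round(dur * 14)), 14)

  lead_idx <- function(rate) {
    unlist(lapply(iv[, 1L], function(o) {
      (round((o - cfg0$burst_lead) * rate) + 1L):round(o * rate)
    }))
  }
  sil_idx <- function(rate, n) {
    t <- (seq_len(n) - 1) / rate
    # silence: away from any interval and any burst support
    keep <- rep(TRUE, n)
    for (k in seq_len(nrow(iv))) {
      keep[t >= iv[k, 1L] - 0.2 & t <= iv[k, 2L] + 0.2] <- FALSE
    }
    which(keep)
  }

  # snr = 0: pure noise; lead-window RMS within 5% of silence RMS
  ratios <- replicate(100, {
    s <- sample.int(1e6, 1)
    rec <- make_emg(vc, iv, cfg0, seed = s)
    x <- rec$channels[, 1L]
    li <- lead_idx(rec$rate)
    si <- sil_idx(rec$rate, length(x))
    sqrt(mean(x[li]^2)) / sqrt(mean(x[si]^2))
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)

  # snr = 4: lead-window RMS more than 2x silence RMS on 20 draws
  cfg4 <- scenario_config(n_utterances = 2, n_channels = 1,
                          burst_snr = 4, crosstalk = matrix(1),
                          burst_gain = 1, seed = 5)
  for (s in 1:20) {
    rec <- make_emg(vc, iv, cfg4, seed = s)
    x <- rec$channels[, 1L]
    li <- lead_idx(rec$rate)
    si <- sil_idx(rec$rate, length(x))
    expect_gt(sqrt(mean(x[li]^2)), 2 * sqrt(mean(x[si]^2)))
  }

  # determinism: same seed twice gives bit-identical recordings
  r1 <- make_emg(vc, iv, cfg4, seed = 42)
  r2 <- make_emg(vc, iv, cfg4, seed = 42)
  expect_identical(r1$channels, r2$channels)
  r3 <- make_emg(vc, iv, cfg4, seed = 43)
  expect_false(identical(r1$channels, r3$channels))

  expect_error(make_emg(vc, iv, modifyList(cfg4, list(burst_snr = -1))),
               "burst_snr")
})

test_that("warped audio: identity, affine scaling, knot images", {
  sched <- data.frame(onset = c(0.3, 1.0), kind = "nasal",
                      open_duration = c(0.4, 0.4))
  base <- make_base_audio(sched, 1.8, 8000, seed = 2)

  # identity warp: cross-correlation of the two tracks peaks at lag 0
  au <- make_warped_audio(base, NULL)
  a12 <- resample_audio(au$audio_mri, 8000)
  n <- min(length(a12$samples), length(au$audio_emg$samples))
  cc <- ccf(a12$samples[1:n], au$audio_emg$samples[1:n], lag.max = 40,
            plot = FALSE)
  # peak lag at 0 up to the sub-millisecond resampler transient
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 8)

  # affine warp t -> 1.1 t (MRI timeline 1.1x slower): duration scales
  knots <- cbind(c(0, 2.2), c(0, 2.0)) # t_mri, t_emg
  au2 <- make_warped_audio(base, knots)
  expect_equal(audio_duration(au2$audio_mri), 1.1 * audio_duration(base),
               tolerance = 1 / 16000)

  # piecewise-linear warp: knot images exact
  knots3 <- cbind(c(0, 0.8, 1.8), c(0, 1.0, 1.8))
  au3 <- make_warped_audio(base, knots3)
  expect_equal(au3$true_warp(knots3[, 1L]), knots3[, 2L])

  expect_error(make_warped_audio(base, cbind(c(0, 1), c(1, 0))),
               "monotone")
})

test_that("MRI stack: area follows the curve exactly", {
  # constant-zero curve: dark area constant at the configured minimum
  v0 <- velum_curve(numeric(10), 14)
  m0 <- make_mri_stack(v0, min_area = 12, max_area = 160, noise_sd = 0,
                       seed = 1)
  counts <- apply(m0$stack$frames < 0.5, 1L, sum)
  expect_true(all(counts == 12))

  # curve value 1 at frame k attains the configured maximum, by counting
  v1 <- velum_curve(c(0, 0.5, 1, 0.2), 14)
  m1 <- make_mri_stack(v1, min_area = 12, max_area = 160, noise_sd = 0,
                       seed = 1)
  expect_equal(sum(m1$stack$frames[3, , ] < 0.5), 160)
  expect_equal(m1$true_areas, round(12 + v1$values * 148))

  # 75 frames at 14 fps: stack length 75
  v75 <- velum_curve(rep(0.3, 75), 14)
  m75 <- make_mri_stack(v75, seed = 1)
  expect_equal(dim(m75$stack$frames)[1L], 75L)

  # rank correlation between dark-pixel count and the curve is 1
  vv <- velum_curve(c(0, 0.2, 0.9, 0.4, 1, 0.1), 14)
  mm <- make_mri_stack(vv, noise_sd = 0, seed = 1)
  expect_equal(cor(mm$true_areas, vv$values, method = "spearman"), 1)
})

test_that("scenario generation is deterministic in (config, seed)", {
  s1 <- make_scenario(small_config(n = 3, seed = 9), with_mri = TRUE)
  s2 <- make_scenario(small_config(n = 3, seed = 9), with_mri = TRUE)
  expect_identical(s1$emg$channels, s2$emg$channels)
  expect_identical(s1$audio_mri$samples, s2$audio_mri$samples)
  expect_identical(s1$mri$frames, s2$mri$frames)
  expect_identical(s1$true_velum$values, s2$true_velum$values)
  # nasal intervals non-overlapping and sorted
  iv <- s1$true_nasal_intervals
  expect_true(all(diff(iv[, 1L]) > 0))
  expect_true(all(iv[-1L, 1L] >= iv[-nrow(iv), 2L]))
  # audio/EMG durations agree within one sample
  expect_equal(audio_duration(s1$audio_emg),
               nrow(s1$emg$channels) / s1$emg$rate,
               tolerance = 1 / s1$audio_emg$rate)
})
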