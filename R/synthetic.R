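# Synthetic scenario generator: ground-truth velum curves, surface-EMG-like
# recordings with activation bursts preceding nasal intervals, paired audio
# tracks related by a known monotone time warp, and toy MRI stacks whose
# hypo-intense airway area follows the aperture curve. Everything is
# reproducible from (config, seed) and ground truth is returned alongside,
# so every downstream stage can be verified without real recordings.

#' Scenario configuration for the synthetic generator
#'
#' Collects the acquisition parameters the generator emulates: velum
#' aperture sampled at the MRI frame rate, 5-channel EMG at 600 Hz, audio
#' at 16000 Hz on the MRI side and 8000 Hz on the EMG side, and an EMG
#' activation lead relative to velum movement.
#'
#' @param n_utterances Number of nasal-vowel utterances to schedule.
#' @param vowel_schedule Optional data frame with columns `onset` (s),
#'   `kind` ("nasal"/"oral") and `open_duration` (s). When `NULL`, a
#'   regular schedule of `n_utterances` nasal events is built with
#'   `utterance_spacing` between onsets.
#' @param emg_rate EMG sampling rate, Hz.
#' @param mri_fps MRI frame rate, frames/s.
#' @param audio_rate_mri,audio_rate_emg Audio rates on the two sides, Hz.
#' @param n_channels Number of EMG channels.
#' @param burst_lead Activation onset lead before velum-opening onset, s.
#'   No quantitative lead is established for this muscle group; 0.10 s is
#'   a simulation choice, not a measured value.
#' @param burst_duration Duration of each activation burst, s. The
#'   default (0.60 s = `burst_lead` + the default open duration) lets a
#'   burst begin before the opening movement and persist through the open
#'   phase, matching the sustained activity visible when aligned EMG and
#'   aperture traces are overlaid.
#' @param burst_snr Ratio of burst RMS to baseline-noise RMS (>= 0).
#' @param closing_bursts Also place bursts before each nasal offset
#'   (closing movement)?
#' @param burst_gain Per-channel multiplier on burst amplitude, emulating
#'   electrode placements closer to or farther from the velum musculature.
#' @param crosstalk n_channels x n_channels mixing matrix (surface
#'   electrodes pick up neighboring muscles); `NULL` gives a mild default
#'   with 0.05 off-diagonal weight.
#' @param noise_sd Baseline Gaussian noise SD (pre-normalization units).
#' @param utterance_spacing Onset-to-onset spacing of scheduled events, s.
#' @param open_duration Velopharyngeal-port open duration per nasal event, s.
#' @param warp_knots Optional matrix of (t_mri, t_emg) knots of the
#'   piecewise-linear monotone warp; `NULL` means identity.
#' @param seed Integer seed driving all randomness.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_utterances = 10,
                            vowel_schedule = NULL,
                            emg_rate = 600,
                            mri_fps = 14,
                            audio_rate_mri = 16000,
                            audio_rate_emg = 8000,
                            n_channels = 5,
                            burst_lead = 0.10,
                            burst_duration = 0.60,
                            burst_snr = 4,
                            closing_bursts = FALSE,
                            burst_gain = NULL,
                            crosstalk = NULL,
                            noise_sd = 1,
                            utterance_spacing = 1.1,
                            open_duration = 0.5,
                            warp_knots = NULL,
                            seed = 1L) {
  if (emg_rate <= 0 || mri_fps <= 0 || audio_rate_mri <= 0 ||
      audio_rate_emg <= 0) stop("all rates must be positive")
  if (burst_lead < 0) stop("burst_lead must be >= 0")
  if (burst_snr < 0) stop("burst_snr must be >= 0")
  if (open_duration <= 0) stop("open_duration must be positive")
  if (is.null(burst_gain)) {
    burst_gain <- if (n_channels == 5L) c(0.6, 1, 1, 1, 0.6) else
      rep(1, n_channels)
  }
  if (length(burst_gain) != n_channels) {
    stop("burst_gain must have one entry per channel")
  }
  if (is.null(crosstalk)) {
    crosstalk <- diag(n_channels) * 0.95 + 0.05 / n_channels
  }
  crosstalk <- as.matrix(crosstalk)
  if (!all(dim(crosstalk) == n_channels) || any(!is.finite(crosstalk))) {
    stop("crosstalk must be a finite n_channels x n_channels matrix")
  }
  if (is.null(vowel_schedule)) {
    onsets <- 0.5 + (seq_len(n_utterances) - 1) * utterance_spacing
    vowel_schedule <- data.frame(
      onset = onsets, kind = "nasal", open_duration = open_duration,
      stringsAsFactors = FALSE)
  }
  if (!is.null(warp_knots)) {
    warp_knots <- as.matrix(warp_knots)
    if (ncol(warp_knots) != 2L) stop("warp_knots must have two columns")
    if (any(diff(warp_knots[, 1L]) <= 0) || any(diff(warp_knots[, 2L]) <= 0)) {
      stop("warp must be strictly monotone increasing")
    }
  }
  structure(list(
    n_utterances = n_utterances, vowel_schedule = vowel_schedule,
    emg_rate = emg_rate, mri_fps = mri_fps,
    audio_rate_mri = audio_rate_mri, audio_rate_emg = audio_rate_emg,
    n_channels = n_channels, burst_lead = burst_lead,
    burst_duration = burst_duration, burst_snr = burst_snr,
    closing_bursts = closing_bursts, burst_gain = burst_gain,
    crosstalk = crosstalk, noise_sd = noise_sd,
    utterance_spacing = utterance_spacing, open_duration = open_duration,
    warp_knots = warp_knots, seed = as.integer(seed)),
    class = "scenario_config")
}

#' Build a ground-truth velum-aperture curve from an event schedule
#'
#' Baseline 0 (closed velopharyngeal port) with one raised-cosine pulse of
#' peak 1 per nasal event spanning its open duration; oral events
#' contribute nothing. Overlapping pulses are merged by pointwise maximum.
#'
#' @param schedule Data frame with columns `onset`, `kind`,
#'   `open_duration`.
#' @param fps Sampling rate of the curve (MRI frame rate), Hz.
#' @param duration Total duration, s; must cover all events.
#' @return A list with `curve` (a [velum_curve] before normalization
#'   semantics — values already in [0, 1]) and `intervals` (matrix of
#'   half-open [onset, onset + open_duration) nasal supports, merged).
#' @export
make_velum_curve <- function(schedule, fps, duration) {
  if (fps <= 0) stop("fps must be positive")
  n <- round(duration * fps)
  t <- (seq_len(n) - 1) / fps
  x <- numeric(n)
  iv <- matrix(numeric(0), ncol = 2L)
  if (!is.null(schedule) && nrow(schedule)) {
    nas <- schedule[schedule$kind == "nasal", , drop = FALSE]
    if (nrow(nas)) {
      ends <- nas$onset + nas$open_duration
      if (any(nas$onset < 0) || any(ends > duration + 1e-9)) {
        stop("event outside duration")
      }
      for (k in seq_len(nrow(nas))) {
        o <- nas$onset[k]; d <- nas$open_duration[k]
        u <- (t - o) / d
        pulse <- ifelse(u >= 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
        x <- pmax(x, pulse)
      }
      iv <- merge_intervals(cbind(nas$onset, ends))
    }
  }
  list(curve = velum_curve(x, fps), intervals = iv)
}

# Band-limited (60-200 Hz shaped) unit-RMS noise carrier of `n` samples.
band_noise <- function(n, rate) {
  w <- stats::rnorm(n + 240L)
  ny <- rate / 2
  lo <- min(60 / ny, 0.95)
  hi <- min(200 / ny, 0.99)
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  y <- signal::filter(bf, w)
  y <- as.numeric(y)[(length(y) - n + 1L):length(y)]
  s <- rms(y)
  if (s > 0) y / s else y
}

#' Generate a multi-channel EMG recording for a scenario
#'
#' Each channel is Gaussian baseline noise plus Hann-enveloped,
#' band-limited stochastic bursts whose envelopes start `burst_lead`
#' seconds before each nasal-interval onset (and, optionally, before each
#' offset for the closing movement), scaled so burst RMS over its support
#' is `burst_snr` times the baseline-noise RMS. Channels are then mixed by
#' the crosstalk matrix.
#'
#' @param true_velum A [velum_curve] on the MRI clock (defines duration).
#' @param true_nasal_intervals Matrix of [start, end) nasal intervals, s.
#' @param config A [scenario_config].
#' @param seed Seed; defaults to `config$seed`.
#' @return An [emg_recording].
#' @export
make_emg <- function(true_velum, true_nasal_intervals, config,
                     seed = config$seed) {
  if (config$burst_snr < 0) stop("burst_snr must be >= 0")
  duration <- length(true_velum$values) / true_velum$rate
  if (nrow(true_nasal_intervals) &&
      any(true_nasal_intervals[, 2L] > duration + 1e-9)) {
    stop("nasal intervals must lie within the curve duration")
  }
  rate <- config$emg_rate
  n <- round(duration * rate)
  nb <- round(config$burst_duration * rate)
  # cosine-tapered (Tukey) envelope: half-cosine ramps of burst_lead
  # duration, flat in between — activation rises within the lead window
  # and is sustained over the rest of the burst
  nr <- max(1L, min(round(config$burst_lead * rate), nb %/% 2L))
  env <- rep(1, nb)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  env[seq_len(nr)] <- ramp
  env[(nb - nr + 1L):nb] <- rev(ramp)
  env_rms <- rms(env)
  with_seed(seed, {
    raw <- matrix(stats::rnorm(n * config$n_channels, sd = config$noise_sd),
                  nrow = n)
    if (config$burst_snr > 0 && nrow(true_nasal_intervals)) {
      starts <- true_nasal_intervals[, 1L] - config$burst_lead
      if (config$closing_bursts) {
        starts <- c(starts, true_nasal_intervals[, 2L] - config$burst_lead)
      }
      # peak amplitude so that RMS over the burst support = snr * noise RMS
      amp <- config$burst_snr * config$noise_sd / env_rms
      for (ch in seq_len(config$n_channels)) {
        for (s0 in starts) {
          i0 <- round(s0 * rate) + 1L
          idx <- i0:(i0 + nb - 1L)
          keep <- idx >= 1L & idx <= n
          if (!any(keep)) next
          carrier <- band_noise(nb, rate)
          raw[idx[keep], ch] <- raw[idx[keep], ch] +
            config$burst_gain[ch] * amp * (env * carrier)[keep]
        }
      }
    }
    mixed <- raw %*% t(config$crosstalk)
    emg_recording(mixed, rate)
  })
}

# Evaluate the piecewise-linear monotone warp t_mri -> t_emg (and inverse).
warp_fun <- function(knots) {
  if (is.null(knots)) {
    list(fwd = identity, inv = identity)
  } else {
    list(
      fwd = function(t) stats::approx(knots[, 1L], knots[, 2L], t,
                                      rule = 2)$y,
      inv = function(t) stats::approx(knots[, 2L], knots[, 1L], t,
                                      rule = 2)$y)
  }
}

#' Synthesize the base audio track for a schedule
#'
#' One tone-complex "syllable" per schedule event (distinct fundamentals
#' cycling over events) on a quiet background — enough spectral landmarks
#' for time alignment without speech synthesis.
#'
#' @param schedule Event data frame (`onset`, `kind`, `open_duration`).
#' @param duration Total duration, s.
#' @param rate Sampling rate, Hz.
#' @param seed Seed for the low-level background noise.
#' @return An [audio_signal].
#' @export
make_base_audio <- function(schedule, duration, rate, seed = 1L) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  f0s <- c(220, 330, 440, 550, 660)
  with_seed(seed, {
    x <- stats::rnorm(n, sd = 0.005)
    if (!is.null(schedule) && nrow(schedule)) {
      for (k in seq_len(nrow(schedule))) {
        o <- schedule$onset[k]; d <- schedule$open_duration[k]
        f0 <- f0s[(k - 1L) %% length(f0s) + 1L]
        u <- (t - o) / d
        envk <- ifelse(u >= 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
        x <- x + envk * (0.6 * sin(2 * pi * f0 * t) +
                         0.3 * sin(2 * pi * 2 * f0 * t) +
                         0.15 * sin(2 * pi * 3 * f0 * t))
      }
    }
    audio_signal(x / max(1, max(abs(x))), rate)
  })
}

#' Render a base audio track on the two acquisition clocks
#'
#' The EMG-side track is the base waveform resampled to the EMG audio rate.
#' The MRI-side track is the base time-warped by a smooth (piecewise
#' linear) strictly monotone warp and rendered at the MRI audio rate. The
#' true warp (MRI time -> EMG time) is returned for recovery tests.
#'
#' @param base An [audio_signal] (the EMG-side timeline).
#' @param warp_knots Matrix of (t_mri, t_emg) knots, both columns strictly
#'   increasing; `NULL` for the identity warp.
#' @param audio_rate_mri,audio_rate_emg Target rates, Hz.
#' @return List with `audio_mri`, `audio_emg` ([audio_signal]s) and
#'   `true_warp` (function MRI time -> EMG time).
#' @export
make_warped_audio <- function(base, warp_knots = NULL,
                              audio_rate_mri = 16000,
                              audio_rate_emg = 8000) {
  if (!length(base$samples)) stop("base audio must be non-empty")
  if (!is.null(warp_knots)) {
    warp_knots <- as.matrix(warp_knots)
    if (any(diff(warp_knots[, 1L]) <= 0) ||
        any(diff(warp_knots[, 2L]) <= 0)) {
      stop("warp must be strictly monotone increasing")
    }
  }
  w <- warp_fun(warp_knots)
  dur_emg <- audio_duration(base)
  audio_emg <- resample_audio(base, audio_rate_emg)
  dur_mri <- if (is.null(warp_knots)) dur_emg else w$inv(dur_emg)
  n_mri <- round(dur_mri * audio_rate_mri)
  t_mri <- (seq_len(n_mri) - 1) / audio_rate_mri
  t_base <- w$fwd(t_mri)
  base_t <- (seq_along(base$samples) - 1) / base$rate
  x_mri <- stats::approx(base_t, base$samples, t_base, rule = 2)$y
  list(audio_mri = audio_signal(x_mri, audio_rate_mri),
       audio_emg = audio_emg,
       true_warp = w$fwd)
}

#' Generate a toy MRI stack whose airway area follows the velum curve
#'
#' Bright background (about 0.8) with additive Gaussian noise and a dark
#' (about 0.1) region inside the ROI whose pixel count per frame is an
#' affine (hence monotone) function of the aperture value at that frame.
#'
#' @param true_velum A [velum_curve] on the MRI clock.
#' @param height,width Image size in pixels.
#' @param roi List with `rows` and `cols` (integer ranges) defining the
#'   rectangular ROI; `NULL` centers a ROI of half the image.
#' @param min_area,max_area Dark-region pixel counts at aperture 0 and 1.
#' @param noise_sd Additive intensity noise SD.
#' @param seed Seed for the noise.
#' @return List with `stack` (an [image_sequence]), `true_areas`
#'   (per-frame dark-pixel counts) and `roi` (logical H x W mask).
#' @export
make_mri_stack <- function(true_velum, height = 64, width = 64, roi = NULL,
                           min_area = 12, max_area = 160, noise_sd = 0.02,
                           seed = 1L) {
  if (is.null(roi)) {
    roi <- list(rows = (height %/% 4):(3 * height %/% 4),
                cols = (width %/% 4):(3 * width %/% 4))
  }
  mask <- matrix(FALSE, height, width)
  mask[roi$rows, roi$cols] <- TRUE
  if (sum(mask) < max_area) stop("ROI too small to contain max_area")
  # rank ROI pixels by distance to the ROI center: the dark region grows
  # outward from the center, so any prefix is connected (disk-like)
  ctr <- c(mean(roi$rows), mean(roi$cols))
  idx <- which(mask, arr.ind = TRUE)
  d2 <- (idx[, 1L] - ctr[1L])^2 + (idx[, 2L] - ctr[2L])^2
  ord <- idx[order(d2, idx[, 1L], idx[, 2L]), , drop = FALSE]
  v <- true_velum$values
  areas <- round(min_area + v * (max_area - min_area))
  Tn <- length(v)
  frames <- array(0, dim = c(Tn, height, width))
  with_seed(seed, {
    for (f in seq_len(Tn)) {
      img <- matrix(0.8, height, width)
      if (areas[f] > 0) {
        dark <- ord[seq_len(areas[f]), , drop = FALSE]
        img[dark] <- 0.1
      }
      img <- img + matrix(stats::rnorm(height * width, sd = noise_sd),
                          height, width)
      frames[f, , ] <- pmin(pmax(img, 0), 1)
    }
  })
  list(stack = image_sequence(frames, true_velum$rate),
       true_areas = areas, roi = mask)
}

#' Generate a complete synthetic scenario
#'
#' Drives all the generators from one configuration and seed: ground-truth
#' velum curve and nasal intervals on the MRI clock, multi-channel EMG with
#' anticipatory bursts, paired audio tracks related by the configured warp,
#' and (optionally) a toy MRI stack.
#'
#' @param config A [scenario_config].
#' @param with_mri Also generate the toy image stack? (Skipping it saves
#'   time when only the signal path is exercised.)
#' @return An object of class `scenario`: the config plus `true_velum`,
#'   `true_nasal_intervals`, `true_warp`, `emg`, `audio_mri`, `audio_emg`,
#'   and (if requested) `mri`, `true_areas`, `roi`.
#' @export
make_scenario <- function(config = scenario_config(), with_mri = FALSE) {
  sched <- config$vowel_schedule
  dur_emg <- max(sched$onset + sched$open_duration) + 0.5
  w <- warp_fun(config$warp_knots)
  # schedule lives on the EMG timeline; map events to the MRI timeline
  sched_mri <- sched
  sched_mri$onset <- w$inv(sched$onset)
  ends_mri <- w$inv(sched$onset + sched$open_duration)
  sched_mri$open_duration <- ends_mri - sched_mri$onset
  dur_mri <- if (is.null(config$warp_knots)) dur_emg else w$inv(dur_emg)

  vel <- make_velum_curve(sched_mri, config$mri_fps, dur_mri)
  # nasal intervals on the EMG clock (ground truth for zoning/labeling)
  iv_emg <- merge_intervals(cbind(sched$onset,
                                  sched$onset + sched$open_duration))

  base <- make_base_audio(sched, dur_emg, config$audio_rate_emg,
                          seed = config$seed + 1L)
  au <- make_warped_audio(base, config$warp_knots,
                          config$audio_rate_mri, config$audio_rate_emg)
  emg <- make_emg_on_emg_clock(iv_emg, dur_emg, config)
  out <- list(config = config,
              true_velum = vel$curve,
              true_nasal_intervals_mri = vel$intervals,
              true_nasal_intervals = iv_emg,
              true_warp = au$true_warp,
              emg = emg,
              audio_mri = au$audio_mri,
              audio_emg = au$audio_emg)
  if (with_mri) {
    mri <- make_mri_stack(vel$curve, seed = config$seed + 2L)
    out$mri <- mri$stack
    out$true_areas <- mri$true_areas
    out$roi <- mri$roi
  }
  structure(out, class = "scenario")
}

# EMG generation directly on the EMG clock (intervals already there).
make_emg_on_emg_clock <- function(iv_emg, dur_emg, config) {
  fake_curve <- velum_curve(numeric(round(dur_emg * config$emg_rate)),
                            config$emg_rate, degenerate = TRUE)
  make_emg(fake_curve, iv_emg, config, seed = config$seed)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %d events, %.1f s EMG @ %g Hz, %d channels, burst SNR %g\n",
    nrow(x$config$vowel_schedule), nrow(x$emg$channels) / x$emg$rate,
    x$emg$rate, ncol(x$emg$channels), x$config$burst_snr))
  invisible(x)
}
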