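# Shared builders for small, fast test scenarios.

small_config <- function(n = 6, seed = 1L, snr = 4, ...) {
  scenario_config(n_utterances = n, burst_snr = snr, seed = seed, ...)
}

# A velum curve with a single raised-cosine pulse.
single_pulse_curve <- function(onset = 1, open = 0.5, fps = 14,
                               duration = 3) {
  sched <- data.frame(onset = onset, kind = "nasal", open_duration = open)
  make_velum_curve(sched, fps, duration)
}

# A toy stack with a rectangular dark blob of exactly `npix` pixels in
# every frame, inside a centered ROI.
blob_stack <- function(npix = 120, frames = 3, h = 32, w = 32, fps = 14) {
  arr <- array(0.9, dim = c(frames, h, w))
  rows <- 10:(10 + npix %/% 10 - 1)
  cols <- 10:19
  stopifnot(length(rows) * length(cols) == npix)
  for (f in seq_len(frames)) arr[f, rows, cols] <- 0.1
  roi <- matrix(FALSE, h, w)
  roi[5:28, 5:28] <- TRUE
  list(seq = image_sequence(arr, fps), roi = roi,
       seed_pixel = c(0L, rows[1L] - 1L, cols[1L] - 1L), npix = npix)
}

# Straight-loop oracle for the 9 temporal features, written directly from
# the definitions (independent of extract_features' vectorized path).
features_oracle <- function(x) {
  L <- length(x)
  mu <- 0; for (v in x) mu <- mu + v; mu <- mu / L
  am <- 0; for (v in x) am <- am + abs(v); am <- am / L
  ss <- 0; for (v in x) ss <- ss + (v - mu)^2
  sdv <- sqrt(ss / L)
  mx <- x[1L]; mn <- x[1L]
  for (v in x) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  if (sdv == 0) kurt <- 0 else {
    s4 <- 0; for (v in x) s4 <- s4 + (v - mu)^4
    kurt <- s4 / L / sdv^4 - 3
  }
  en <- 0; for (v in x) en <- en + v^2; en <- en / L
  sgn <- function(v) if (v > 0) 1 else if (v < 0) -1 else 0
  prev <- sgn(x[1L]); if (prev == 0) prev <- 1
  zc <- 0
  for (i in 2:L) {
    cur <- sgn(x[i]); if (cur == 0) cur <- prev
    if (cur != prev) zc <- zc + 1
    prev <- cur
  }
  mas <- 0; for (i in 2:L) mas <- mas + abs(x[i] - x[i - 1L])
  c(mean = mu, abs_mean = am, sd = sdv, max = mx, min = mn,
    kurtosis = kurt, energy = en, zcr = zc / (L - 1L),
    mas = mas / (L - 1L))
}

# Ground-truth aperture curve rendered directly on the EMG sample clock
# (bypasses MRI extraction and DTW; for tests of downstream stages).
velum_on_emg_clock <- function(scn) {
  dur <- nrow(scn$emg$channels) / scn$emg$rate
  make_velum_curve(scn$config$vowel_schedule, scn$emg$rate, dur)$curve
}

FEATURE_NAMES_test <- function() {
  c("mean", "abs_mean", "sd", "max", "min", "kurtosis", "energy", "zcr",
    "mas")
}

# Intersection-over-union of two half-open intervals (test-side copy).
interval_iou_test <- function(a, b) {
  inter <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  union <- (a[2L] - a[1L]) + (b[2L] - b[1L]) - inter
  if (union <= 0) 0 else inter / union
}

# Closed-form mutual information (bits) of a 2x2 joint probability table.
mi_2x2_oracle <- function(p) {
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  s
}
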