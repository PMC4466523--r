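# Cross-modal alignment: both recordings carry an audio track; the two
# tracks are resampled to a common 12000 Hz rate, reduced to short-time
# log-energy envelopes, aligned by dynamic time warping, and the resulting
# warp path is collapsed to a monotone time map used to carry the velum
# curve onto the EMG clock.

#' Band-limited audio resampling
#'
#' Polyphase resampling to a target rate; output length is
#' `round(n * target / rate)`.
#'
#' @param a An [audio_signal].
#' @param target_rate Target sampling rate, Hz (> 0).
#' @return An [audio_signal] at `target_rate`.
#' @export
resample_audio <- function(a, target_rate) {
  if (target_rate <= 0) stop("target_rate must be positive")
  if (!length(a$samples)) return(audio_signal(numeric(0), target_rate))
  if (target_rate == a$rate) return(audio_signal(a$samples, target_rate))
  fr <- as.integer(c(target_rate, a$rate) /
                     pracma_gcd(as.integer(target_rate), as.integer(a$rate)))
  y <- as.numeric(signal::resample(a$samples, fr[1L], fr[2L]))
  n_out <- round(length(a$samples) * target_rate / a$rate)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  audio_signal(y, target_rate)
}

pracma_gcd <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Short-time log-energy envelope of an audio signal
#'
#' Frame energy in dB over a sliding window, floored at `floor_db`. This is
#' the feature representation the DTW alignment operates on.
#'
#' @param a An [audio_signal].
#' @param window Analysis window length, s.
#' @param hop Hop between consecutive frames, s.
#' @param floor_db Lower bound on the log-energy, dB.
#' @return List with `env` (dB values) and `hop` (s).
#' @export
log_energy <- function(a, window = 0.025, hop = 0.010, floor_db = -60) {
  L <- round(window * a$rate)
  S <- round(hop * a$rate)
  n <- length(a$samples)
  if (n < L) stop("signal shorter than one analysis window")
  starts <- seq(1L, n - L + 1L, by = S)
  x2 <- c(0, cumsum(a$samples^2))
  e <- (x2[starts + L] - x2[starts]) / L
  env <- pmax(10 * log10(pmax(e, .Machine$double.xmin)), floor_db)
  list(env = env, hop = hop)
}

#' Align two audio tracks by dynamic time warping
#'
#' Both signals are expected at a common rate (the pipeline resamples both
#' sides to 12000 Hz first). Each is reduced to a short-time log-energy
#' envelope (25 ms window, 10 ms hop, floor -60 dB); DTW with squared
#' difference local cost, step set \{(1,1),(1,0),(0,1)\} and a Sakoe-Chiba
#' band of 10% of the longer length returns the minimal-cost path.
#'
#' @param a,b [audio_signal]s at the same rate (`a` on the MRI side, `b`
#'   on the EMG side).
#' @param window,hop Envelope analysis parameters, s.
#' @param band Sakoe-Chiba half-width as a fraction of the longer envelope.
#' @return An object of class `warp_path`: `pairs` (L x 2 matrix of
#'   0-based (i, j) envelope indices), `cost`, `frame_hop` (s).
#' @export
dtw_align <- function(a, b, window = 0.025, hop = 0.010, band = 0.10) {
  if (a$rate != b$rate) {
    stop("signals must share a common rate (resample both first)")
  }
  fa <- log_energy(a, window, hop)
  fb <- log_energy(b, window, hop)
  res <- .dtw_core(fa$env, fb$env, band)
  structure(list(pairs = res$path, cost = res$cost, frame_hop = hop),
            class = "warp_path")
}

#' @export
print.warp_path <- function(x, ...) {
  n <- nrow(x$pairs)
  cat(sprintf("<warp_path> %d steps, cost %.3f, hop %g s\n",
              n, x$cost, x$frame_hop))
  invisible(x)
}

#' Collapse a warp path to a monotone time map
#'
#' For each MRI-side envelope index i, takes the median of the matched
#' EMG-side indices j; the resulting knots are linearly interpolated,
#' giving a non-decreasing map from MRI-side time to EMG-side time.
#'
#' @param path A `warp_path`.
#' @return Function mapping time (s) on the first signal's axis to time
#'   (s) on the second signal's axis (constant extrapolation outside).
#' @export
warp_time_map <- function(path) {
  if (!nrow(path$pairs)) stop("empty warp path")
  i <- path$pairs[, 1L]
  j <- path$pairs[, 2L]
  med <- tapply(j, i, stats::median)
  ti <- as.numeric(names(med)) * path$frame_hop
  tj <- as.numeric(med) * path$frame_hop
  tj <- cummax(tj) # guard monotonicity after the median collapse
  function(t) stats::approx(ti, tj, t, rule = 2, ties = "ordered")$y
}

#' Map a velum curve onto the EMG sample clock
#'
#' Composes the curve's MRI-side time base with the DTW-derived monotone
#' time map and resamples the result by linear interpolation onto the EMG
#' clock. The output duration equals the EMG-side audio duration implied
#' by the path.
#'
#' @param v A [velum_curve] on the MRI clock.
#' @param path A `warp_path` from [dtw_align()] (MRI side first).
#' @param emg_rate EMG sampling rate, Hz.
#' @return A [velum_curve] on the EMG clock.
#' @export
warp_curve <- function(v, path, emg_rate = 600) {
  if (!nrow(path$pairs)) stop("empty warp path")
  m <- warp_time_map(path)
  t_emg_end <- max(path$pairs[, 2L]) * path$frame_hop
  n_out <- max(1L, round(t_emg_end * emg_rate))
  u <- (seq_len(n_out) - 1) / emg_rate
  # invert the monotone map: for each EMG time, the matching MRI time
  ti <- seq(0, max(path$pairs[, 1L]) * path$frame_hop, by = path$frame_hop)
  tj <- m(ti)
  t_mri <- stats::approx(tj, ti, u, rule = 2, ties = "ordered")$y
  tv <- (seq_along(v$values) - 1) / v$rate
  vals <- stats::approx(tv, v$values, t_mri, rule = 2)$y
  velum_curve(vals, emg_rate, degenerate = v$degenerate)
}
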