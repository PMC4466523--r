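# EMG conditioning and framing: per-channel max-absolute normalization,
# rectification, and a 12-point moving average applied forward and
# backward so the net response is zero-phase; then segmentation into
# 100 ms frames advanced by 20 ms.

#' Pre-process an EMG recording
#'
#' Per channel: (1) max-absolute normalization to [-1, 1]; (2) absolute
#' value; (3) a 12-point moving-average filter run forward and then
#' backward over the rectified signal, so the net 23-tap response is
#' exactly zero-phase on the sample grid (an even-length single pass
#' cannot be). Edges use 12 samples of reflect padding, trimmed after
#' filtering. An all-zero channel is returned unchanged and flagged.
#'
#' @param rec An [emg_recording].
#' @param points Moving-average length in samples.
#' @return An [emg_recording] with non-negative channels; attribute
#'   `flat_channels` lists any all-zero channels that were skipped.
#' @export
preprocess <- function(rec, points = 12L) {
  ch <- rec$channels
  if (!nrow(ch)) stop("empty recording")
  flat <- integer(0)
  out <- ch
  for (k in seq_len(ncol(ch))) {
    x <- ch[, k]
    m <- max(abs(x))
    if (m == 0) {
      flat <- c(flat, k)
      next
    }
    x <- abs(x / m)
    out[, k] <- zero_phase_ma(x, points)
  }
  res <- emg_recording(out, rec$rate, rec$channel_meta, rec$marker_time)
  attr(res, "flat_channels") <- flat
  res
}

# Forward+backward boxcar of length `points` with reflect padding.
zero_phase_ma <- function(x, points = 12L) {
  n <- length(x)
  p <- min(points, n)
  pad <- c(rev(x[seq_len(p)]), x, rev(x[(n - p + 1L):n]))
  kern <- rep(1 / points, points)
  f <- stats::filter(pad, kern, method = "convolution", sides = 1L)
  f <- rev(as.numeric(stats::filter(rev(as.numeric(f)), kern,
                                    method = "convolution", sides = 1L)))
  # sides=1 convolution delays by (points-1); fwd+bwd delays cancel
  out <- f[(p + 1L):(p + n)]
  out[is.na(out)] <- 0
  out
}

#' Frame index over a sample sequence
#'
#' Half-open frames of `round(frame_length * rate)` samples advanced by
#' `round(frame_shift * rate)`; the trailing partial frame is discarded.
#'
#' @param n_samples Number of samples available.
#' @param rate Sampling rate, Hz.
#' @param frame_length Frame length, s (default 0.100).
#' @param frame_shift Frame shift, s (default 0.020).
#' @return An object of class `frame_index`: `frames` (two-column matrix
#'   of 0-based half-open `(start, end)` sample indices), `times`
#'   (two-column matrix of `(start, end)` seconds), `frame_length`,
#'   `frame_shift`, `rate`.
#' @export
frame_signal <- function(n_samples, rate, frame_length = 0.100,
                         frame_shift = 0.020) {
  if (frame_shift <= 0 || frame_length < frame_shift) {
    stop("require frame_length >= frame_shift > 0")
  }
  L <- round(frame_length * rate)
  S <- round(frame_shift * rate)
  n_frames <- if (n_samples < L) 0L else (n_samples - L) %/% S + 1L
  starts <- if (n_frames) (seq_len(n_frames) - 1L) * S else integer(0)
  frames <- cbind(start = starts, end = starts + L)
  structure(list(frames = frames, times = frames / rate,
                 frame_length = frame_length, frame_shift = frame_shift,
                 rate = rate),
            class = "frame_index")
}

#' @export
print.frame_index <- function(x, ...) {
  cat(sprintf("<frame_index> %d frames of %g s, shift %g s @ %g Hz\n",
              nrow(x$frames), x$frame_length, x$frame_shift, x$rate))
  invisible(x)
}
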