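#' Audio signal container
#'
#' A single-channel audio waveform with its sampling rate.
#'
#' @param samples Numeric vector of amplitudes (finite).
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class `audio_signal` with fields `samples` and
#'   `rate`.
#' @export
audio_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop("samples must be finite")
  }
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param a An `audio_signal`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(a) length(a$samples) / a$rate

#' Image sequence container
#'
#' A time-ordered stack of 2-D intensity frames at a fixed frame rate,
#' standing in for a real-time MRI recording of the vocal tract.
#'
#' @param frames Numeric array T x H x W with intensities in [0, 1].
#' @param fps Frame rate in frames per second (> 0).
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, fps) {
  if (length(dim(frames)) != 3L) stop("frames must be a T x H x W array")
  if (any(!is.finite(frames)) || any(frames < 0) || any(frames > 1)) {
    stop("intensities must be finite and in [0, 1]")
  }
  if (fps <= 0) stop("fps must be positive")
  structure(list(frames = frames, fps = fps), class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_sequence> %d frames of %d x %d @ %g fps\n",
              d[1L], d[2L], d[3L], x$fps))
  invisible(x)
}

#' Per-frame airway area curve
#'
#' Pixel counts of a segmented (hypo-intense airway) region, one per frame.
#'
#' @param areas Integer-valued non-negative vector, one entry per frame.
#' @param fps Frame rate in frames per second.
#' @return An object of class `area_curve`.
#' @export
area_curve <- function(areas, fps) {
  areas <- as.numeric(areas)
  if (any(areas < 0) || any(areas != round(areas))) {
    stop("areas must be non-negative integers")
  }
  if (fps <= 0) stop("fps must be positive")
  structure(list(areas = areas, fps = fps), class = "area_curve")
}

#' Normalized velum-aperture curve
#'
#' A uniformly sampled, min-max normalized aperture signal in [0, 1]:
#' minima correspond to a closed velopharyngeal port (oral sound), maxima to
#' an open port (nasal sound). The curve carries its mean and population
#' standard deviation, which drive the nasal-zone threshold.
#'
#' @param values Numeric vector in [0, 1].
#' @param rate Sampling rate in Hz.
#' @param degenerate Logical flag; `TRUE` marks a constant input that could
#'   not be normalized (no nasality detectable).
#' @return An object of class `velum_curve` with fields `values`, `rate`,
#'   `mean`, `sd` and `degenerate`.
#' @export
velum_curve <- function(values, rate, degenerate = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop("values must be finite and in [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  if (rate <= 0) stop("rate must be positive")
  structure(list(values = values, rate = rate,
                 mean = mean(values), sd = pop_sd(values),
                 degenerate = isTRUE(degenerate)),
            class = "velum_curve")
}

#' @export
print.velum_curve <- function(x, ...) {
  cat(sprintf(
    "<velum_curve> %d samples @ %g Hz; mean %.4f, sd %.4f%s\n",
    length(x$values), x$rate, x$mean, x$sd,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
plot.velum_curve <- function(x, ...) {
  t <- (seq_along(x$values) - 1) / x$rate
  plot(t, x$values, type = "l", xlab = "time (s)",
       ylab = "normalized aperture", ...)
  abline(h = x$mean, col = "blue", lty = 2)
  abline(h = x$mean + x$sd / 2, col = "darkgreen", lty = 2)
  invisible(x)
}

#' Multi-channel surface EMG recording
#'
#' @param channels Numeric matrix, one column per channel (equal lengths).
#' @param rate Sampling rate in Hz (600 in the acquisition emulated here).
#' @param channel_meta Optional data frame with columns `id` and
#'   `configuration` (monopolar/bipolar), one row per channel.
#' @param marker_time Optional synchronization marker, in seconds.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(channels, rate, channel_meta = NULL,
                          marker_time = 0) {
  channels <- as.matrix(channels)
  if (rate <= 0) stop("rate must be positive")
  if (is.null(channel_meta)) {
    channel_meta <- data.frame(
      id = seq_len(ncol(channels)),
      configuration = rep("bipolar", ncol(channels)),
      stringsAsFactors = FALSE)
  }
  if (nrow(channel_meta) != ncol(channels)) {
    stop("channel_meta must have one row per channel")
  }
  structure(list(channels = channels, rate = rate,
                 channel_meta = channel_meta, marker_time = marker_time),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$channels), nrow(x$channels), x$rate,
              nrow(x$channels) / x$rate))
  invisible(x)
}

#' Nasal / non-nasal zone labels
#'
#' An ordered, non-overlapping partition of a time span into nasal and
#' non-nasal zones, with the per-sample square wave (0 = non-nasal,
#' 1 = nasal) and, for nasal zones, the boundary geometry that produced
#' them.
#'
#' @param zones Data frame with columns `start`, `end` (seconds, half-open
#'   intervals) and `class` ("nasal"/"non-nasal"), sorted and contiguous.
#' @param square_wave Integer 0/1 vector at `rate`, consistent with zones.
#' @param rate Sampling rate of `square_wave` in Hz.
#' @param geometry Optional list of boundary-geometry records.
#' @return An object of class `zone_labels`.
#' @export
zone_labels <- function(zones, square_wave, rate, geometry = NULL) {
  stopifnot(all(c("start", "end", "class") %in% names(zones)))
  if (nrow(zones)) {
    if (any(zones$end <= zones$start)) stop("zones must have end > start")
    if (is.unsorted(zones$start)) stop("zones must be sorted")
    if (nrow(zones) > 1L &&
        any(abs(zones$start[-1L] - zones$end[-nrow(zones)]) > 1e-9)) {
      stop("zones must be contiguous (jointly covering the span)")
    }
    if (!all(zones$class %in% c("nasal", "non-nasal"))) {
      stop("zone class must be nasal or non-nasal")
    }
  }
  structure(list(zones = zones, square_wave = as.integer(square_wave),
                 rate = rate, geometry = geometry),
            class = "zone_labels")
}

#' @export
print.zone_labels <- function(x, ...) {
  n_nas <- sum(x$zones$class == "nasal")
  cat(sprintf("<zone_labels> %d zones (%d nasal, %d non-nasal) over %.2f s\n",
              nrow(x$zones), n_nas, nrow(x$zones) - n_nas,
              if (nrow(x$zones)) max(x$zones$end) else 0))
  invisible(x)
}

#' Nasal zones of a labeling, as a matrix of intervals
#' @param z A `zone_labels` object.
#' @return Two-column matrix of half-open [start, end) nasal intervals.
#' @export
nasal_intervals <- function(z) {
  nz <- z$zones[z$zones$class == "nasal", , drop = FALSE]
  cbind(nz$start, nz$end)
}
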