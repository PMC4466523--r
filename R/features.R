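# Nine first-order temporal features per EMG frame, in this fixed order:
# mean, absolute mean, standard deviation, maximum, minimum, kurtosis,
# energy, zero-crossing rate, mean absolute slope. Conventions (fixed for
# determinism, since "first order temporal features" admits variants):
# population SD; excess (Fisher) kurtosis with the population estimator,
# 0 by convention for a constant frame; energy as the mean of squares;
# ZCR as sign changes between consecutive samples over L-1, zeros
# inheriting the previous sign; mean absolute slope over L-1.

FEATURE_NAMES <- c("mean", "abs_mean", "sd", "max", "min", "kurtosis",
                   "energy", "zcr", "mas")

#' Temporal feature vector of one frame
#'
#' @param x Numeric frame of length >= 2.
#' @return Named numeric vector of the 9 features.
#' @export
extract_features <- function(x) {
  L <- length(x)
  if (L < 2L) stop("frame must have at least 2 samples")
  mu <- sum(x) / L
  sd_p <- sqrt(sum((x - mu)^2) / L)
  kurt <- if (sd_p == 0) 0 else sum((x - mu)^4) / L / sd_p^4 - 3
  s <- sign(x)
  # zeros inherit the previous sign (first sample's zero counts positive)
  if (s[1L] == 0) s[1L] <- 1
  for (i in seq_len(L)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  zcr <- sum(s[-1L] != s[-L]) / (L - 1L)
  c(mean = mu,
    abs_mean = sum(abs(x)) / L,
    sd = sd_p,
    max = max(x),
    min = min(x),
    kurtosis = kurt,
    energy = sum(x^2) / L,
    zcr = zcr,
    mas = sum(abs(diff(x))) / (L - 1L))
}

#' Feature table for one EMG channel
#'
#' Cuts a channel into frames and computes the 9 temporal features per
#' frame, optionally attaching zone-derived class labels.
#'
#' @param samples Numeric channel signal.
#' @param rate Sampling rate, Hz.
#' @param channel Channel id recorded in the table.
#' @param zones Optional [zone_labels] used to label each frame by the
#'   zone containing its midpoint.
#' @param frame_length,frame_shift Framing parameters, s.
#' @return A data frame with columns `channel`, `frame_start`, the 9
#'   feature columns, and `label` ("unlabeled" when no zones given);
#'   attribute `frame_index` carries the [frame_signal()] result.
#' @export
feature_table <- function(samples, rate, channel = 1L, zones = NULL,
                          frame_length = 0.100, frame_shift = 0.020) {
  fi <- frame_signal(length(samples), rate, frame_length, frame_shift)
  n <- nrow(fi$frames)
  feats <- matrix(NA_real_, n, length(FEATURE_NAMES),
                  dimnames = list(NULL, FEATURE_NAMES))
  for (k in seq_len(n)) {
    idx <- (fi$frames[k, 1L] + 1L):fi$frames[k, 2L]
    feats[k, ] <- extract_features(samples[idx])
  }
  label <- if (!is.null(zones) && n) label_frames(zones, fi$times) else
    rep("unlabeled", n)
  out <- data.frame(channel = rep(channel, n),
                    frame_start = fi$times[, 1L],
                    feats, label = label, stringsAsFactors = FALSE)
  attr(out, "frame_index") <- fi
  out
}
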