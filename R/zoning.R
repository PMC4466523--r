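# Nasal / non-nasal zoning of the warped velum curve. Samples with
# x(n) >= x_bar + sigma/2 are candidate-nasal; to include the whole
# transitional part of the signal (lowering and raising of the velum),
# each candidate run is widened using the angle between its nearest peak
# and the adjacent points where x(n) = x_bar: two congruent right
# triangles share the angle theta at the peak, the upper one spanning the
# drop from the peak level to x_bar, the lower one the drop from x_bar to
# 0, so the extra horizontal extension is
#   v2 = x_bar * |t_c - t_p| / (y_p - x_bar).
# The prose and figure this construction comes from admit more than one
# geometric reading; this formalization is fixed here and unit-tested.

#' Nasality threshold of a velum curve
#'
#' @param v A [velum_curve] (not degenerate).
#' @return List with `mean` (x-bar) and `tau` (x-bar + sigma/2).
#' @export
compute_threshold <- function(v) {
  if (v$degenerate || v$sd == 0) {
    stop("degenerate curve: no nasality detectable")
  }
  list(mean = v$mean, tau = v$mean + v$sd / 2)
}

#' Extend a nasal-zone boundary beyond the mean crossing
#'
#' Given the nearest peak `(t_p, y_p)` and the adjacent crossing of the
#' curve with its mean `(t_c, x_bar)`, computes
#' `v2 = x_bar * |t_c - t_p| / (y_p - x_bar)` and places the boundary at
#' `t_c + v2` (falling edge) or `t_c - v2` (rising edge), clipped to
#' `span = c(t_min, t_max)`.
#'
#' @param peak Numeric `(t_p, y_p)`.
#' @param crossing Numeric `(t_c, x_bar)`.
#' @param direction `"rising"` (zone onset) or `"falling"` (zone offset).
#' @param span Optional `c(t_min, t_max)` clip range, s.
#' @return Boundary time `t_b`, s.
#' @export
extend_boundary <- function(peak, crossing, direction = c("rising", "falling"),
                            span = NULL) {
  direction <- match.arg(direction)
  t_p <- peak[1L]; y_p <- peak[2L]
  t_c <- crossing[1L]; x_bar <- crossing[2L]
  if (y_p <= x_bar) stop("peak level must exceed the mean (no valid triangle)")
  v2 <- x_bar * abs(t_c - t_p) / (y_p - x_bar)
  t_b <- if (direction == "falling") t_c + v2 else t_c - v2
  if (!is.null(span)) t_b <- min(max(t_b, span[1L]), span[2L])
  t_b
}

# Local maxima of x: samples strictly greater than both neighbors;
# plateaus (runs of equal values higher than both flanks) contribute
# their midpoint. Returns sample indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (k in seq_along(r$values)) {
    left_ok <- k == 1L || r$values[k] > r$values[k - 1L]
    right_ok <- k == length(r$values) || r$values[k] > r$values[k + 1L]
    if (k > 1L && k < length(r$values) && left_ok && right_ok) {
      out <- c(out, floor((starts[k] + ends[k]) / 2))
    }
  }
  out
}

# Linear-interpolated time of the crossing x = level between samples
# i and i+1 (1-based), times on (idx-1)/rate.
crossing_time <- function(x, rate, i, level) {
  t0 <- (i - 1) / rate
  if (i >= length(x)) return(t0)
  dx <- x[i + 1L] - x[i]
  if (dx == 0) return(t0)
  t0 + (level - x[i]) / dx / rate
}

#' Segment a velum curve into nasal and non-nasal zones
#'
#' Thresholds the (min-max renormalized) curve at x-bar + sigma/2 to get
#' candidate nasal runs; for each run uses the first local maximum inside
#' it for the rising-edge geometry and the last for the falling-edge
#' geometry (a velum that stays open longer than one pulse gets different
#' peaks for the two boundaries), locates the adjacent crossings with
#' x-bar, extends both boundaries via [extend_boundary()], merges
#' overlapping extended runs, and emits the complementary non-nasal zones
#' plus the per-sample 0/1 square wave.
#'
#' @param v A [velum_curve] (not degenerate).
#' @param renormalize Min-max renormalize the values first (the default;
#'   warping preserves the range, but downstream callers may pass raw
#'   curves)?
#' @return A [zone_labels] object.
#' @export
detect_zones <- function(v, renormalize = TRUE) {
  if (v$degenerate) stop("degenerate curve: no nasality detectable")
  x <- v$values
  if (renormalize) {
    rng <- range(x)
    if (diff(rng) == 0) stop("degenerate curve: no nasality detectable")
    x <- (x - rng[1L]) / diff(rng)
  }
  rate <- v$rate
  n <- length(x)
  span <- c(0, n / rate)
  x_bar <- mean(x)
  sdv <- pop_sd(x)
  if (sdv == 0) stop("degenerate curve: no nasality detectable")
  tau <- x_bar + sdv / 2

  above <- x >= tau
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  geometry <- list()
  iv <- matrix(numeric(0), ncol = 2L)
  if (nrow(runs)) {
    for (k in seq_len(nrow(runs))) {
      i0 <- runs[k, 1L]; i1 <- runs[k, 2L]
      seg <- x[i0:i1]
      pk <- local_maxima(x)
      pk <- pk[pk >= i0 & pk <= i1]
      if (!length(pk)) pk <- i0 - 1L + which.max(seg)
      pk_first <- pk[1L]; pk_last <- pk[length(pk)]

      # adjacent x = x_bar crossings: nearest downward crossing left of
      # the run and upward crossing right of it (run edges if the curve
      # never returns to the mean)
      left_i <- i0 - 1L
      while (left_i >= 1L && x[left_i] >= x_bar) left_i <- left_i - 1L
      t_c_left <- if (left_i >= 1L) {
        crossing_time(x, rate, left_i, x_bar)
      } else (i0 - 1) / rate
      right_i <- i1 + 1L
      while (right_i <= n && x[right_i] >= x_bar) right_i <- right_i + 1L
      t_c_right <- if (right_i <= n) {
        crossing_time(x, rate, right_i - 1L, x_bar)
      } else (i1 - 1) / rate

      g_rise <- list(peak = c((pk_first - 1) / rate, x[pk_first]),
                     crossing = c(t_c_left, x_bar))
      g_fall <- list(peak = c((pk_last - 1) / rate, x[pk_last]),
                     crossing = c(t_c_right, x_bar))
      t_start <- extend_boundary(g_rise$peak, g_rise$crossing, "rising", span)
      t_end <- extend_boundary(g_fall$peak, g_fall$crossing, "falling", span)
      # extension never moves a boundary inward of the threshold run
      t_start <- min(t_start, (i0 - 1) / rate)
      t_end <- max(t_end, (i1 - 1) / rate + 1 / rate)
      iv <- rbind(iv, c(t_start, t_end))
      geometry[[length(geometry) + 1L]] <- list(rising = g_rise,
                                                falling = g_fall)
    }
    iv <- merge_intervals(iv)
  }

  zones <- build_partition(iv, span)
  t_mid <- ((seq_len(n) - 1) + 0) / rate
  sw <- integer(n)
  if (nrow(iv)) {
    for (k in seq_len(nrow(iv))) {
      sw[t_mid >= iv[k, 1L] & t_mid < iv[k, 2L]] <- 1L
    }
  }
  zone_labels(zones, sw, rate, geometry)
}

# Complement a set of merged nasal intervals into a full alternating
# partition of the span.
build_partition <- function(iv, span) {
  rows <- list()
  cur <- span[1L]
  if (nrow(iv)) {
    for (k in seq_len(nrow(iv))) {
      if (iv[k, 1L] > cur + 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = cur, end = iv[k, 1L], class = "non-nasal")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = max(iv[k, 1L], cur), end = iv[k, 2L], class = "nasal")
      cur <- iv[k, 2L]
    }
  }
  if (cur < span[2L] - 1e-12) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = cur, end = span[2L], class = "non-nasal")
  }
  if (!length(rows)) {
    rows[[1L]] <- data.frame(start = span[1L], end = span[2L],
                             class = "non-nasal")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label time frames by the zone containing their midpoint
#'
#' @param z A [zone_labels] object.
#' @param frame_times Two-column matrix of frame `(start, end)` times, s.
#' @return Character vector of `"nasal"`/`"non-nasal"`, one per frame.
#' @export
label_frames <- function(z, frame_times) {
  frame_times <- as.matrix(frame_times)
  mids <- (frame_times[, 1L] + frame_times[, 2L]) / 2
  span <- c(min(z$zones$start), max(z$zones$end))
  if (any(mids < span[1L] - 1e-9) || any(mids >= span[2L] + 1e-9)) {
    stop("frame outside the labeled span")
  }
  idx <- findInterval(pmin(mids, span[2L] - 1e-12), z$zones$start)
  z$zones$class[idx]
}
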