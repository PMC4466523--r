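# Internal helpers shared across modules.

# Run `expr` under a given RNG seed without disturbing the caller's RNG
# state. All stochastic operations in the package take an explicit seed and
# route through this, so there is no hidden global-state coupling.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Half-up rounding to `digits` decimals (round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Population standard deviation (divide by N).
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

rms <- function(x) sqrt(mean(x^2))

# Merge sorted-or-not half-open intervals given as a 2-column matrix.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  dimnames(iv) <- NULL
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (k in 2L:nrow(iv)) {
      last <- nrow(out)
      if (iv[k, 1L] <= out[last, 2L]) {
        out[last, 2L] <- max(out[last, 2L], iv[k, 2L])
      } else {
        out <- rbind(out, iv[k, , drop = FALSE])
      }
    }
  }
  out
}

# Intersection-over-union of two half-open intervals.
interval_iou <- function(a, b) {
  inter <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  union <- (a[2L] - a[1L]) + (b[2L] - b[1L]) - inter
  if (union <= 0) return(0)
  inter / union
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
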