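# Dependence between the warped velum curve and EMG: plug-in mutual
# information on an equal-width joint histogram,
#   I(X;Y) = sum_x sum_y p(x,y) log2( p(x,y) / (p(x) p(y)) ),
# a normalized variant, and Pearson correlation, overall and within
# nasal / non-nasal zones.

#' Plug-in mutual information between two signals
#'
#' Discretizes both signals on equal-width bins over their observed
#' ranges, forms the joint histogram, and evaluates the plug-in estimate
#' in bits; empty cells contribute 0. The normalized value divides by the
#' geometric mean of the marginal entropies (other variants selectable),
#' and is defined as 0 when either entropy is 0 (constant signal).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param bins Number of bins per axis (>= 2).
#' @param normalization `"sqrt"` (I / sqrt(Hx * Hy)), `"min"`
#'   (I / min(Hx, Hy)) or `"mean"` (I / ((Hx + Hy) / 2)).
#' @return An object of class `mi_estimate`: `I` (bits), `normalized`,
#'   `Hx`, `Hy`, `bins`, `n`, `joint` (the joint probability table),
#'   `degenerate` flag.
#' @export
mutual_information <- function(x, y, bins = 16L,
                               normalization = c("sqrt", "min", "mean")) {
  normalization <- match.arg(normalization)
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  if (bins < 2L) stop("bins must be >= 2")
  bx <- bin_assign(x, bins)
  by <- bin_assign(y, bins)
  joint <- table(factor(bx, levels = seq_len(bins)),
                 factor(by, levels = seq_len(bins))) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  outer_p <- outer(px, py)
  I <- sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
  I <- max(I, 0) # guard tiny negative rounding
  Hx <- entropy_bits(px)
  Hy <- entropy_bits(py)
  degenerate <- Hx == 0 || Hy == 0
  norm <- if (degenerate) 0 else switch(normalization,
    sqrt = I / sqrt(Hx * Hy),
    min = I / min(Hx, Hy),
    mean = I / ((Hx + Hy) / 2))
  structure(list(I = I, normalized = min(norm, 1), Hx = Hx, Hy = Hy,
                 bins = bins, n = n, joint = joint,
                 degenerate = degenerate),
            class = "mi_estimate")
}

bin_assign <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  b <- floor((x - rng[1L]) / diff(rng) * bins) + 1L
  pmin(b, bins)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> I = %.4f bits, normalized = %.4f (%d bins, n = %d)%s\n",
              x$I, x$normalized, x$bins, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Zone-wise dependence between the velum curve and an EMG channel
#'
#' Concatenates the samples of each zone class and computes mutual
#' information, normalized mutual information, and Pearson correlation
#' per class and overall. Signals must share a common clock.
#'
#' @param velum A [velum_curve] on the EMG clock.
#' @param emg_channel Numeric vector, same rate and length as the curve
#'   (tolerates a length mismatch of a few samples by truncation).
#' @param zones A [zone_labels] object on the same clock.
#' @param bins Histogram bins for the MI estimate.
#' @return Data frame with one row per class ("nasal", "non-nasal",
#'   "all"): `n`, `mi_bits`, `nmi`, `pearson_r`. Empty classes are
#'   skipped with a warning.
#' @export
zone_dependence <- function(velum, emg_channel, zones, bins = 16L) {
  n <- min(length(velum$values), length(emg_channel),
           length(zones$square_wave))
  v <- velum$values[seq_len(n)]
  e <- emg_channel[seq_len(n)]
  sw <- zones$square_wave[seq_len(n)]
  groups <- list(nasal = sw == 1L, `non-nasal` = sw == 0L,
                 all = rep(TRUE, n))
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (sum(sel) < 2L) {
      warning(sprintf("zone class '%s' empty: skipped", g))
      next
    }
    mi <- mutual_information(v[sel], e[sel], bins)
    r <- if (stats::sd(v[sel]) == 0 || stats::sd(e[sel]) == 0) NA_real_ else
      stats::cor(v[sel], e[sel])
    rows[[g]] <- data.frame(class = g, n = sum(sel), mi_bits = mi$I,
                            nmi = mi$normalized, pearson_r = r,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
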