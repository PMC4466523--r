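# Velum information from image sequences. Sagittal stacks: the airway
# between velum and pharyngeal wall appears hypo-intense; a seeded region
# growing restricted to a region of interest, with a neighborhood that
# includes the time axis, tracks the airway across all frames from a
# single seed. The per-frame pixel count of the grown region is the area
# curve: minima correspond to a closed velopharyngeal port, maxima to an
# open one. Coronal-oblique stacks are handled by the same growth with a
# configurable intensity polarity and several seeds.

# Connected component of `candidate` (T x H x W logical) containing the
# seed voxels, under 6-connectivity in (t, y, x) (face adjacency in space
# and time). Vectorized morphological growth: repeatedly dilate the
# current region by one voxel along the six faces and intersect with the
# candidate mask until a fixed point.
grow_region <- function(candidate, seeds_idx) {
  d <- dim(candidate)
  region <- array(FALSE, d)
  region[seeds_idx] <- TRUE
  if (!all(candidate[seeds_idx])) stop("seed outside candidate mask")
  repeat {
    grown <- region
    # shift +/- along each axis
    grown[-1, , ]    <- grown[-1, , ]    | region[-d[1L], , ]
    grown[-d[1L], , ] <- grown[-d[1L], , ] | region[-1, , ]
    grown[, -1, ]    <- grown[, -1, ]    | region[, -d[2L], ]
    grown[, -d[2L], ] <- grown[, -d[2L], ] | region[, -1, ]
    grown[, , -1]    <- grown[, , -1]    | region[, , -d[3L]]
    grown[, , -d[3L]] <- grown[, , -d[3L]] | region[, , -1]
    grown <- grown & candidate
    if (sum(grown) == sum(region)) break
    region <- grown
  }
  region
}

seed_matrix <- function(seeds) {
  s <- matrix(as.integer(unlist(seeds)), ncol = 3L, byrow = TRUE)
  colnames(s) <- c("frame", "row", "col")
  s
}

#' Segment the sagittal airway and return its per-frame area
#'
#' Grows a connected region of hypo-intense pixels (intensity below
#' `intensity_threshold`) from a single seed, restricted to the ROI, with
#' a 6-connected neighborhood in (t, y, x). Because the neighborhood
#' includes time, one seed in one frame is typically enough to track the
#' airway through the whole sequence.
#'
#' @param seq An [image_sequence].
#' @param roi Logical H x W mask (the region of interest between velum
#'   and pharyngeal wall).
#' @param seed_pixel Integer vector `(frame, row, col)`, 0-based.
#' @param intensity_threshold Hypo-intensity cutoff on the [0, 1] scale.
#' @return An [area_curve] of per-frame pixel counts of the grown region.
#' @export
segment_sagittal <- function(seq, roi, seed_pixel,
                             intensity_threshold = 0.5) {
  d <- dim(seq$frames)
  s <- seed_matrix(list(seed_pixel)) + 1L # to 1-based
  if (any(s < 1L) || s[1L] > d[1L] || s[2L] > d[2L] || s[3L] > d[3L]) {
    stop("seed outside image bounds")
  }
  if (!roi[s[2L], s[3L]]) stop("seed outside ROI")
  if (seq$frames[s[1L], s[2L], s[3L]] >= intensity_threshold) {
    stop("seed not hypo-intense at the given threshold")
  }
  candidate <- seq$frames < intensity_threshold
  roi3 <- aperm(array(roi, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  candidate <- candidate & roi3
  region <- grow_region(candidate, s)
  area_curve(apply(region, 1L, sum), seq$fps)
}

#' Segment a seeded cavity compartment in a coronal-oblique stack
#'
#' Grows the compartment containing the given seeds (typically a few seeds
#' inside the nasal cavity) by intensity similarity — pixels darker than
#' the threshold for `polarity = "dark"` (airway) or brighter for
#' `polarity = "bright"` — with the same spatiotemporal connectivity as
#' the sagittal case, and returns its per-frame area. Frames in which the
#' compartment is absent (closed velopharyngeal port) get area 0.
#'
#' @param seq An [image_sequence].
#' @param seeds List of integer `(frame, row, col)` triples, 0-based.
#' @param intensity_threshold Cutoff on the [0, 1] intensity scale.
#' @param polarity `"dark"` or `"bright"`: which side of the threshold
#'   the segmented compartment lies on.
#' @return An [area_curve].
#' @export
segment_coronal <- function(seq, seeds, intensity_threshold = 0.5,
                            polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (!length(seeds)) stop("at least one seed required")
  d <- dim(seq$frames)
  s <- seed_matrix(seeds) + 1L
  if (any(s < 1L) || any(s[, 1L] > d[1L]) || any(s[, 2L] > d[2L]) ||
      any(s[, 3L] > d[3L])) stop("seed outside image bounds")
  candidate <- if (polarity == "dark") {
    seq$frames < intensity_threshold
  } else {
    seq$frames > intensity_threshold
  }
  vals <- seq$frames[s]
  ok <- if (polarity == "dark") all(vals < intensity_threshold) else
    all(vals > intensity_threshold)
  if (!ok) stop("seed intensity inconsistent with the requested polarity")
  region <- grow_region(candidate, s)
  area_curve(apply(region, 1L, sum), seq$fps)
}

#' Normalize an area curve into a velum-aperture curve
#'
#' Min-max normalizes the per-frame areas to [0, 1] and attaches the mean
#' and population standard deviation of the normalized samples (the
#' quantities the nasal-zone threshold is built from). A constant input
#' cannot be normalized: an all-zero curve with the `degenerate` flag set
#' is returned (no nasality detectable).
#'
#' @param areas An [area_curve].
#' @return A [velum_curve].
#' @export
area_to_velum_curve <- function(areas) {
  a <- areas$areas
  rng <- range(a)
  if (diff(rng) == 0) {
    return(velum_curve(numeric(length(a)), areas$fps, degenerate = TRUE))
  }
  velum_curve((a - rng[1L]) / diff(rng), areas$fps)
}
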