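# Frame-level nasality classification: RBF-kernel SVM under stratified
# 10-fold cross-validation with seeded shuffling, per-fold error rate,
# sensitivity and specificity (nasal as the positive class) and t-based
# 95% confidence intervals over folds; zone-majority classification on
# top of the frame predictions; channel-set concatenation.

#' Stratified k-fold partition
#'
#' Folds are disjoint, jointly exhaustive, sized within one frame of each
#' other, with per-class proportions within one frame of the stratified
#' ideal.
#'
#' @param labels Factor or character vector of class labels.
#' @param k Number of folds.
#' @param seed Seed for the within-class shuffling.
#' @return Integer vector of fold assignments (1..k).
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("more folds than observations")
  fold <- integer(n)
  with_seed(seed, {
    # deal shuffled indices class by class, continuing the fold cycle
    # across classes so total fold sizes also stay within one frame
    pos <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  fold
}

fold_metrics <- function(truth, pred) {
  tp <- sum(truth == "nasal" & pred == "nasal")
  fn <- sum(truth == "nasal" & pred == "non-nasal")
  tn <- sum(truth == "non-nasal" & pred == "non-nasal")
  fp <- sum(truth == "non-nasal" & pred == "nasal")
  c(error = 100 * (fp + fn) / length(truth),
    sensitivity = if (tp + fn) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp) 100 * tn / (tn + fp) else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp)
}

t_ci_halfwidth <- function(x) {
  x <- x[!is.na(x)]
  k <- length(x)
  if (k < 2L) return(NA_real_)
  stats::qt(0.975, k - 1L) * stats::sd(x) / sqrt(k)
}

#' Cross-validated SVM classification of frame features
#'
#' Stratified k-fold cross-validation of a Gaussian-RBF SVM: per fold,
#' features are standardized on the training part (means/SDs reused on
#' the held-out part), the SVM is trained and evaluated, and error rate,
#' sensitivity and specificity are recorded (nasal = positive class).
#' Reported are per-fold values, their means, and t-based 95% confidence
#' half-widths (mean +/- t[0.025, k-1] * sd / sqrt(k)).
#'
#' @param features Numeric matrix or data frame of per-frame features.
#' @param labels Character vector, "nasal"/"non-nasal", one per frame.
#' @param k Number of folds.
#' @param seed Seed for fold assignment.
#' @param cost SVM regularization parameter C.
#' @param gamma RBF width; `NULL` gives 1/(d * mean feature variance) on
#'   the standardized training data.
#' @return An object of class `nasemg_cv`: `folds` (per-fold metric data
#'   frame), `mean`, `ci95` (half-widths), `confusion` (summed totals),
#'   `predictions` (out-of-fold prediction per frame), `k`, `seed`.
#' @export
crossvalidate <- function(features, labels, k = 10L, seed = 1L,
                          cost = 1, gamma = NULL) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (k > nrow(x)) stop("more folds than frames")
  fold <- stratified_folds(labels, k, seed)
  y <- factor(labels, levels = c("nasal", "non-nasal"))
  per_fold <- matrix(NA_real_, k, 7L)
  colnames(per_fold) <- c("error", "sensitivity", "specificity",
                          "tp", "fn", "tn", "fp")
  oof <- character(nrow(x))
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sd_ <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    xs <- sweep(sweep(x, 2L, mu), 2L, sd_, "/")
    g <- if (is.null(gamma)) {
      v <- mean(apply(xs[tr, , drop = FALSE], 2L, stats::var))
      1 / (ncol(xs) * max(v, .Machine$double.eps))
    } else gamma
    fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cost, gamma = g, scale = FALSE)
    pred <- as.character(predict(fit, xs[!tr, , drop = FALSE]))
    oof[!tr] <- pred
    per_fold[f, ] <- fold_metrics(labels[!tr], pred)
  }
  folds_df <- data.frame(fold = seq_len(k), per_fold)
  means <- colMeans(per_fold[, 1:3, drop = FALSE], na.rm = TRUE)
  ci <- apply(per_fold[, 1:3, drop = FALSE], 2L, t_ci_halfwidth)
  confusion <- colSums(per_fold[, 4:7, drop = FALSE])
  structure(list(folds = folds_df, mean = means, ci95 = ci,
                 confusion = confusion, predictions = oof,
                 k = k, seed = seed),
            class = "nasemg_cv")
}

#' @export
print.nasemg_cv <- function(x, ...) {
  cat(sprintf("<nasemg_cv> %d-fold cross-validation\n", x$k))
  cat(sprintf("  error        %5.1f%% +/- %.1f\n", x$mean["error"],
              x$ci95["error"]))
  cat(sprintf("  sensitivity  %5.1f%% +/- %.1f\n", x$mean["sensitivity"],
              x$ci95["sensitivity"]))
  cat(sprintf("  specificity  %5.1f%% +/- %.1f\n", x$mean["specificity"],
              x$ci95["specificity"]))
  invisible(x)
}

#' @export
summary.nasemg_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$folds, row.names = FALSE)
  invisible(object)
}

#' Concatenate per-channel feature tables for a channel set
#'
#' Column order is channel-id ascending, then feature order within each
#' channel; frame grid and labels must agree across channels.
#'
#' @param tables Named or unnamed list of [feature_table()] data frames,
#'   one per channel.
#' @return A data frame with `frame_start`, `9 * |set|` feature columns
#'   (`<feature>_ch<id>`), and `label`.
#' @export
combine_channels <- function(tables) {
  if (!length(tables)) stop("empty channel set")
  ids <- vapply(tables, function(tb) tb$channel[1L], numeric(1))
  tables <- tables[order(ids)]
  ids <- sort(ids)
  n <- nrow(tables[[1L]])
  for (tb in tables) {
    if (nrow(tb) != n) stop("mismatched frame counts across channels")
    if (max(abs(tb$frame_start - tables[[1L]]$frame_start)) > 1e-9) {
      stop("mismatched frame grids across channels")
    }
  }
  blocks <- lapply(seq_along(tables), function(k) {
    b <- tables[[k]][, FEATURE_NAMES, drop = FALSE]
    names(b) <- paste0(FEATURE_NAMES, "_ch", ids[k])
    b
  })
  out <- cbind(data.frame(frame_start = tables[[1L]]$frame_start),
               do.call(cbind, blocks),
               data.frame(label = tables[[1L]]$label,
                          stringsAsFactors = FALSE))
  out
}

#' Zone-majority classification from frame predictions
#'
#' Each zone, restricted to its `[a%, b%]` sub-interval by time, collects
#' the predicted classes of the frames whose midpoints fall inside; the
#' zone is predicted nasal iff the nasal count is equal to or higher than
#' the non-nasal count. Zones left with no frame midpoint after the
#' restriction are skipped with a warning.
#'
#' @param predictions Character vector of frame predictions.
#' @param frame_times Two-column matrix of frame `(start, end)` times, s.
#' @param zones A [zone_labels] object (ground truth).
#' @param part Numeric `c(a, b)` percentages of each zone to consider,
#'   default `c(0, 100)` (the whole zone).
#' @return List with `zones` (data frame: start, end, truth, predicted,
#'   n_frames), `error` (percent of decided zones misclassified),
#'   `n_skipped`.
#' @export
zone_majority <- function(predictions, frame_times, zones,
                          part = c(0, 100)) {
  if (part[1L] >= part[2L] || part[1L] < 0 || part[2L] > 100) {
    stop("part must satisfy 0 <= a < b <= 100")
  }
  frame_times <- as.matrix(frame_times)
  mids <- (frame_times[, 1L] + frame_times[, 2L]) / 2
  zdf <- zones$zones
  rows <- list()
  skipped <- 0L
  for (k in seq_len(nrow(zdf))) {
    s <- zdf$start[k]; e <- zdf$end[k]
    a <- s + (e - s) * part[1L] / 100
    b <- s + (e - s) * part[2L] / 100
    sel <- mids >= a & mids < b
    if (!any(sel)) {
      warning(sprintf("zone [%.3f, %.3f) has no frames in part [%g%%, %g%%]",
                      s, e, part[1L], part[2L]))
      skipped <- skipped + 1L
      next
    }
    n_nas <- sum(predictions[sel] == "nasal")
    n_non <- sum(sel) - n_nas
    pred <- if (n_nas >= n_non) "nasal" else "non-nasal"
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, end = e, truth = zdf$class[k], predicted = pred,
      n_frames = sum(sel), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = numeric(0), end = numeric(0),
               truth = character(0), predicted = character(0),
               n_frames = integer(0))
  err <- if (nrow(out)) 100 * mean(out$truth != out$predicted) else NA_real_
  list(zones = out, error = err, n_skipped = skipped)
}

#' Class-distribution summary
#'
#' Counts and percentages (half-up rounding to one decimal) of nasal and
#' non-nasal units (frames or zones), per group and overall.
#'
#' @param n_nasal,n_non_nasal Integer counts, possibly vectors (one entry
#'   per group) with names.
#' @return Data frame with counts and `pct_nasal` / `pct_non_nasal`.
#' @export
class_distribution <- function(n_nasal, n_non_nasal) {
  total <- n_nasal + n_non_nasal
  pct_nas <- ifelse(total > 0, round_half_up(100 * n_nasal / total, 1), 0)
  pct_non <- ifelse(total > 0, round_half_up(100 * n_non_nasal / total, 1), 0)
  if (any(total == 0)) warning("group with zero frames: percentages set to 0.0")
  data.frame(group = if (is.null(names(n_nasal))) seq_along(n_nasal) else
    names(n_nasal),
    n_nasal = n_nasal, n_non_nasal = n_non_nasal, total = total,
    pct_nasal = pct_nas, pct_non_nasal = pct_non,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Summary tables over a collection of cross-validation results
#'
#' @param results Named list of `nasemg_cv` objects (e.g. one per channel
#'   or per speaker).
#' @return List with `metrics` (one row per result: mean and 95% CI
#'   half-width of error/sensitivity/specificity) and `vs_mean` (each
#'   result's mean error minus the cross-result mean error, negative =
#'   better than average).
#' @export
cv_report <- function(results) {
  stopifnot(length(results) > 0)
  nm <- names(results)
  if (is.null(nm)) nm <- as.character(seq_along(results))
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    data.frame(group = nm[k],
               error = r$mean["error"], error_ci = r$ci95["error"],
               sensitivity = r$mean["sensitivity"],
               sensitivity_ci = r$ci95["sensitivity"],
               specificity = r$mean["specificity"],
               specificity_ci = r$ci95["specificity"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  metrics <- do.call(rbind, rows)
  grand <- mean(metrics$error)
  vs_mean <- data.frame(group = metrics$group,
                        error_minus_mean = metrics$error - grand,
                        stringsAsFactors = FALSE)
  list(metrics = metrics, vs_mean = vs_mean)
}
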