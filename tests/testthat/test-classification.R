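test_that("stratified folds are balanced and exhaustive", {
  set.seed(12)
  labels <- sample(rep(c("nasal", "non-nasal"), c(123, 77)))
  fold <- stratified_folds(labels, k = 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # per-class proportions within one frame of the stratified ideal
  for (cl in c("nasal", "non-nasal")) {
    per_fold <- table(fold[labels == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(stratified_folds(labels, k = 300), "folds")
})

test_that("cross-validation separates well-separated classes", {
  set.seed(31)
  n <- 250
  x <- rbind(matrix(rnorm(n * 2, mean = 0, sd = 0.5), ncol = 2),
             matrix(rnorm(n * 2, mean = 4, sd = 0.5), ncol = 2))
  y <- rep(c("nasal", "non-nasal"), each = n)
  cv <- crossvalidate(x, y, k = 10, seed = 1)
  expect_lte(cv$mean[["error"]], 2)
  # error consistent with the confusion totals
  err_from_conf <- 100 * (cv$confusion[["fp"]] + cv$confusion[["fn"]]) /
    sum(cv$confusion)
  expect_equal(mean(cv$folds$error), err_from_conf, tolerance = 0.5)
  expect_true(all(cv$folds$sensitivity >= 0 & cv$folds$sensitivity <= 100))
  expect_true(all(cv$folds$specificity >= 0 & cv$folds$specificity <= 100))
  expect_error(crossvalidate(x, rep("nasal", 2 * n)), "both classes")
})

test_that("cross-validation sits at chance on permuted labels", {
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(1000 * 3), ncol = 3)
    y <- sample(rep(c("nasal", "non-nasal"), 500))
    crossvalidate(x, y, k = 10, seed = s)$mean[["error"]]
  })
  expect_lt(abs(mean(errs) - 50), 5)
})

test_that("channel combination concatenates in channel-id order", {
  set.seed(9)
  sig <- rnorm(600)
  t3 <- feature_table(sig, 600, channel = 3)
  t4 <- feature_table(rnorm(600), 600, channel = 4)

  single <- combine_channels(list(t3))
  expect_equal(as.matrix(single[, paste0(FEATURE_NAMES_test(), "_ch3")]),
               as.matrix(t3[, FEATURE_NAMES_test()]),
               ignore_attr = TRUE)

  both <- combine_channels(list(t4, t3)) # given out of order
  expect_equal(ncol(both), 1 + 18 + 1)
  expect_equal(nrow(both), nrow(t3))
  # column order: channel-id ascending, then feature order (enumeration)
  expected <- c("frame_start",
                paste0(FEATURE_NAMES_test(), "_ch3"),
                paste0(FEATURE_NAMES_test(), "_ch4"),
                "label")
  expect_equal(names(both), expected)

  t_bad <- feature_table(rnorm(300), 600, channel = 5)
  expect_error(combine_channels(list(t3, t_bad)), "frame counts")
})

test_that("zone majority: tie rule, part restriction, perfect input", {
  zdf <- data.frame(start = c(0, 1, 2), end = c(1, 2, 3),
                    class = c("nasal", "non-nasal", "nasal"))
  z <- zone_labels(zdf, integer(0), 100)

  # 6 frames in zone 1, 3 nasal + 3 non-nasal: tie goes to nasal
  ft <- rbind(cbind(seq(0.0, 0.5, 0.1), seq(0.1, 0.6, 0.1)),
              cbind(seq(1.1, 1.5, 0.2), seq(1.2, 1.6, 0.2)),
              cbind(seq(2.1, 2.5, 0.2), seq(2.2, 2.6, 0.2)))
  preds <- c(rep(c("nasal", "non-nasal"), 3),
             rep("non-nasal", 3), rep("non-nasal", 3))
  zm <- zone_majority(preds, ft, z)
  expect_equal(zm$zones$predicted, c("nasal", "non-nasal", "non-nasal"))
  expect_equal(zm$error, 100 / 3, tolerance = 1e-9)

  # part [50, 100]: only frames with midpoints in the last half count
  ft10 <- cbind(seq(0.05, 0.95, 0.1) - 0.04, seq(0.05, 0.95, 0.1) + 0.04)
  preds10 <- rep(c("non-nasal", "nasal"), each = 5)
  zm2 <- zone_majority(preds10, ft10,
                       zone_labels(zdf[1L, ], integer(0), 100),
                       part = c(50, 100))
  mids <- rowMeans(ft10)
  expect_equal(zm2$zones$n_frames, sum(mids >= 0.5 & mids < 1))
  expect_equal(zm2$zones$predicted, "nasal")

  # perfect frame predictions give 0% zone error
  truth <- label_frames(zone_labels(zdf, integer(0), 100), ft)
  expect_equal(zone_majority(truth, ft, z)$error, 0)

  expect_error(zone_majority(preds, ft, z, part = c(60, 40)), "part")
  expect_warning(zone_majority(preds10[1:2], ft10[1:2, , drop = FALSE],
                               zone_labels(zdf[1L, ], integer(0), 100),
                               part = c(90, 100)),
                 "no frames")
})

test_that("class distribution percentages use half-up rounding", {
  d <- class_distribution(c(a = 357), c(a = 479))
  expect_equal(d$pct_nasal, 42.7)
  expect_equal(d$pct_non_nasal, 57.3)
  d2 <- class_distribution(801, 771)
  expect_equal(d2$pct_nasal, 51.0)
  expect_equal(d2$pct_non_nasal, 49.0)
  expect_warning(d0 <- class_distribution(0, 0), "zero")
  expect_equal(d0$pct_nasal, 0)
})

test_that("cv_report aggregates metrics and differences from the mean", {
  set.seed(2)
  mk <- function(s) {
    x <- matrix(rnorm(200 * 2, mean = rep(c(0, 2), each = 200)), ncol = 2)
    crossvalidate(x, rep(c("nasal", "non-nasal"), each = 100),
                  k = 5, seed = s)
  }
  rep_ <- cv_report(list(ch1 = mk(1), ch2 = mk(2)))
  expect_equal(nrow(rep_$metrics), 2L)
  expect_equal(sum(rep_$vs_mean$error_minus_mean), 0, tolerance = 1e-9)
})
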