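test_that("sagittal region growing counts the seeded blob exactly", {
  bs <- blob_stack(npix = 120)
  ac <- segment_sagittal(bs$seq, bs$roi, bs$seed_pixel, 0.5)
  expect_equal(ac$areas, rep(120, 3))

  # seed not hypo-intense on a uniformly bright sequence
  bright <- image_sequence(array(0.9, dim = c(2, 16, 16)), 14)
  roi <- matrix(TRUE, 16, 16)
  expect_error(segment_sagittal(bright, roi, c(0, 8, 8), 0.5),
               "not hypo-intense")
  # seed outside the ROI
  roi2 <- bs$roi; roi2[, ] <- FALSE; roi2[1:2, 1:2] <- TRUE
  expect_error(segment_sagittal(bs$seq, roi2, bs$seed_pixel, 0.5),
               "outside ROI")
})

test_that("region growing is restricted to the ROI and monotone in threshold", {
  scn <- make_scenario(small_config(n = 2, seed = 4), with_mri = TRUE)
  seed_px <- c(which.max(scn$true_velum$values) - 1L, 31L, 31L)
  lo <- segment_sagittal(scn$mri, scn$roi, seed_px, 0.4)
  hi <- segment_sagittal(scn$mri, scn$roi, seed_px, 0.6)
  expect_true(all(hi$areas >= lo$areas))
  roi_size <- sum(scn$roi)
  expect_true(all(hi$areas <= roi_size))
})

test_that("argmin of the sagittal area curve falls in a closed-velum frame", {
  # closing-then-opening aperture
  v <- velum_curve(c(1, 0.6, 0.2, 0, 0.2, 0.7, 1), 14)
  m <- make_mri_stack(v, noise_sd = 0.02, seed = 3)
  roi_idx <- which(m$roi, arr.ind = TRUE)
  seed_px <- c(0L, round(mean(roi_idx[, 1L])) - 1L,
               round(mean(roi_idx[, 2L])) - 1L)
  ac <- segment_sagittal(m$stack, m$roi, seed_px, 0.5)
  expect_equal(which.min(ac$areas), which.min(v$values))
})

test_that("sagittal recovery correlates with ground truth under noise", {
  scn <- make_scenario(small_config(n = 4, seed = 11))
  m <- make_mri_stack(scn$true_velum, noise_sd = 0.05, seed = 12)
  roi_idx <- which(m$roi, arr.ind = TRUE)
  seed_px <- c(which.max(scn$true_velum$values) - 1L,
               round(mean(roi_idx[, 1L])) - 1L,
               round(mean(roi_idx[, 2L])) - 1L)
  ac <- segment_sagittal(m$stack, m$roi, seed_px, 0.5)
  expect_gte(cor(ac$areas, m$true_areas), 0.95)
})

test_that("coronal segmentation: exact areas, absent cavity, idempotent seeds", {
  # single compartment with known per-frame areas (0 in frame 2)
  arr <- array(0.9, dim = c(3, 20, 20))
  arr[1, 5:8, 5:10] <- 0.1   # 24 px
  arr[3, 5:10, 5:10] <- 0.1  # 36 px
  sq <- image_sequence(arr, 14)
  # a closed port splits the compartment in time; one seed per epoch
  ac <- segment_coronal(sq, list(c(0, 5, 5), c(2, 6, 6)), 0.5,
                        polarity = "dark")
  expect_equal(ac$areas, c(24, 0, 36))

  # an extra seed in an already-seeded compartment changes nothing
  one <- segment_coronal(sq, list(c(0, 5, 5)), 0.5, "dark")
  two <- segment_coronal(sq, list(c(0, 5, 5), c(0, 6, 6)), 0.5, "dark")
  expect_equal(two$areas, one$areas)

  expect_error(segment_coronal(sq, list(), 0.5), "at least one seed")

  # bright-polarity growth segments a bright cavity
  arr2 <- array(0.1, dim = c(2, 10, 10))
  arr2[, 3:6, 3:6] <- 0.9
  acb <- segment_coronal(image_sequence(arr2, 14), list(c(0, 3, 3)),
                         0.5, "bright")
  expect_equal(acb$areas, c(16, 16))
})

test_that("area normalization: min-max, degenerate flag, moment fields", {
  v <- area_to_velum_curve(area_curve(c(0, 50, 100), 14))
  expect_equal(v$values, c(0, 0.5, 1))
  expect_false(v$degenerate)

  vd <- area_to_velum_curve(area_curve(rep(7, 5), 14))
  expect_true(vd$degenerate)
  expect_true(all(vd$values == 0))

  # mean and population SD recomputed with a direct two-pass formula
  set.seed(8)
  a <- area_curve(sample.int(200, 40, replace = TRUE), 14)
  v2 <- area_to_velum_curve(a)
  mu <- sum(v2$values) / length(v2$values)
  sd2 <- sqrt(sum((v2$values - mu)^2) / length(v2$values))
  expect_equal(v2$mean, mu, tolerance = 1e-12)
  expect_equal(v2$sd, sd2, tolerance = 1e-12)
})
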