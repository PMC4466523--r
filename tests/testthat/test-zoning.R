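test_that("nasality threshold is mean + half the population SD", {
  v <- velum_curve(c(0, 0, 1, 1), 14)
  th <- compute_threshold(v)
  expect_equal(th$mean, 0.5)
  expect_equal(th$tau, 0.75)

  expect_error(compute_threshold(velum_curve(rep(0.3, 10), 14)),
               "degenerate")

  # tau > mean whenever the curve varies
  set.seed(3)
  for (k in 1:10) {
    vv <- velum_curve(runif(50), 14)
    expect_gt(compute_threshold(vv)$tau, vv$mean)
  }
})

test_that("boundary extension reproduces the triangle geometry", {
  # zero-height second cathetus: boundary at the crossing
  expect_equal(extend_boundary(c(1, 1), c(1.5, 0), "falling"), 1.5)

  # hand-computed falling case: v2 = 0.5 * 0.5 / 0.5 = 0.5 s
  expect_equal(extend_boundary(c(1.0, 1.0), c(1.5, 0.5), "falling"), 2.0)

  # mirrored rising case by symmetry
  expect_equal(extend_boundary(c(1.0, 1.0), c(0.5, 0.5), "rising"), 0.0)

  expect_error(extend_boundary(c(1, 0.4), c(1.5, 0.5), "falling"),
               "triangle")

  # v2 monotone: non-decreasing in x_bar and |t_c - t_p|, non-increasing
  # in y_p (checked through the boundary position of a falling edge)
  v2_of <- function(y_p, t_c, x_bar)
    extend_boundary(c(1, y_p), c(t_c, x_bar), "falling") - t_c
  expect_true(all(diff(sapply(seq(0.1, 0.5, 0.1), function(xb)
    v2_of(1, 1.5, xb))) >= 0))
  expect_true(all(diff(sapply(seq(1.2, 2.0, 0.2), function(tc)
    v2_of(1, tc, 0.3))) >= 0))
  expect_true(all(diff(sapply(seq(0.6, 1.4, 0.2), function(yp)
    v2_of(yp, 1.5, 0.3))) <= 0))
})

test_that("zone detection: containment, partition, square wave", {
  v <- single_pulse_curve(onset = 1, open = 0.6, fps = 100,
                          duration = 3)$curve
  z <- detect_zones(v)
  nz <- nasal_intervals(z)
  expect_equal(nrow(nz), 1L)

  # the nasal zone strictly contains the tau-threshold run
  th <- compute_threshold(v)
  t <- (seq_along(v$values) - 1) / v$rate
  run <- range(t[v$values >= th$tau])
  expect_lt(nz[1, 1], run[1])
  expect_gt(nz[1, 2], run[2])

  # zones partition the span; square wave is 1 exactly on nasal zones
  expect_equal(z$zones$start[1L], 0)
  expect_equal(z$zones$end[nrow(z$zones)], length(v$values) / v$rate)
  sw_oracle <- as.integer(t >= nz[1, 1] & t < nz[1, 2])
  expect_equal(z$square_wave, sw_oracle)

  expect_error(detect_zones(velum_curve(rep(0, 10), 14,
                                        degenerate = TRUE)),
               "degenerate")
})

test_that("detected zones overlap ground truth on noisy synthetic curves", {
  # noise SD <= 0.02 on a multi-pulse curve; per-interval IoU >= 0.8
  set.seed(17)
  sched <- data.frame(onset = c(0.5, 1.6, 2.7, 3.8), kind = "nasal",
                      open_duration = 0.5)
  mk <- make_velum_curve(sched, 100, 4.8)
  noisy <- pmin(pmax(mk$curve$values + rnorm(length(mk$curve$values),
                                             sd = 0.02), 0), 1)
  z <- detect_zones(velum_curve(noisy, 100))
  nz <- nasal_intervals(z)
  expect_equal(nrow(nz), nrow(mk$intervals))
  for (k in seq_len(nrow(mk$intervals))) {
    ious <- apply(nz, 1L, interval_iou_test, b = mk$intervals[k, ])
    expect_gte(max(ious), 0.8)
  }
})

test_that("frame labels follow the zone containing the midpoint", {
  zdf <- data.frame(start = c(0, 1, 2), end = c(1, 2, 3),
                    class = c("non-nasal", "nasal", "non-nasal"))
  sw <- as.integer(seq(0, 2.99, by = 0.01) >= 1 &
                     seq(0, 2.99, by = 0.01) < 2)
  z <- zone_labels(zdf, sw, 100)

  expect_equal(label_frames(z, rbind(c(1.2, 1.4))), "nasal")
  # midpoint in a non-nasal zone, tail overlapping a nasal zone
  expect_equal(label_frames(z, rbind(c(0.85, 1.05))), "non-nasal")
  expect_error(label_frames(z, rbind(c(3.1, 3.3))), "outside")

  # label counts equal direct enumeration over midpoints
  fr <- cbind(seq(0, 2.8, by = 0.02), seq(0.1, 2.9, by = 0.02))
  labs <- label_frames(z, fr)
  mids <- rowMeans(fr)
  expect_equal(sum(labs == "nasal"), sum(mids >= 1 & mids < 2))
})
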