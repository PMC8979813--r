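test_that("a synthetic disk is segmented with sub-pixel accuracy", {
  frame <- render_disk(64, 64, 32, 32, 10)
  dm <- segment_frame(frame, pixel_size = 1)
  expect_equal(nrow(dm$props), 1L)
  expect_lt(abs(dm$props$row - 32), 0.5)
  expect_lt(abs(dm$props$col - 32), 0.5)
  expect_lt(abs(dm$props$radius_um - 10) / 10, 0.05)
})

test_that("blank and all-constant frames yield zero droplets", {
  expect_equal(nrow(segment_frame(matrix(0, 32, 32))$props), 0L)
  expect_equal(nrow(segment_frame(matrix(5, 32, 32))$props), 0L)
})

test_that("moment-derived axes reproduce an ideal ellipse", {
  frame <- render_ellipse(96, 96, 48, 48, 20, 10)
  dm <- segment_frame(frame, pixel_size = 1)
  ar <- dm$props$major_um / dm$props$minor_um
  expect_lt(abs(ar - 2) / 2, 0.05)
})

test_that("segmentation is invariant to affine intensity transforms", {
  set.seed(21)
  for (i in 1:5) {
    frame <- render_disk(48, 48, runif(1, 18, 30), runif(1, 18, 30),
                         runif(1, 6, 12)) + rnorm(48 * 48, sd = 0.01)
    a <- runif(1, 0.5, 30)
    b <- runif(1, -5, 50)
    for (policy in c("otsu", "quantile", "relative")) {
      d1 <- segment_frame(frame, threshold_policy = policy)
      d2 <- segment_frame(a * frame + b, threshold_policy = policy)
      expect_identical(d1$labels, d2$labels)
    }
  }
})

test_that("radius and axis estimates converge for large droplets", {
  for (r in c(20, 30)) {
    n <- 4 * r + 16
    dm <- segment_frame(render_disk(n, n, n / 2, n / 2, r), pixel_size = 1)
    expect_lt(abs(dm$props$radius_um - r) / r, 0.02)
    expect_lt(abs(dm$props$major_um / 2 - r) / r, 0.02)
  }
})

test_that("a static droplet yields a single full-length track", {
  masks <- lapply(1:10, function(i) {
    segment_frame(render_disk(48, 48, 24, 24, 8))
  })
  tracks <- track_droplets(masks, max_step = 2)
  expect_length(tracks, 1L)
  expect_equal(nrow(tracks[[1]]), 10L)
  expect_length(attr(tracks[[1]], "merged_from"), 0L)
})

test_that("a displacement beyond max_step splits the track", {
  masks <- c(
    lapply(1:3, function(i) segment_frame(render_disk(48, 48, 14, 14, 6))),
    lapply(1:3, function(i) segment_frame(render_disk(48, 48, 34, 34, 6)))
  )
  tracks <- track_droplets(masks, max_step = 2)
  expect_length(tracks, 2L)
  expect_equal(vapply(tracks, nrow, integer(1)), c(3L, 3L))
})

test_that("merging droplets terminate parent tracks and flag fusion", {
  pre <- lapply(1:3, function(i) {
    segment_frame(render_disk(64, 64, 32, 20, 7) +
                    render_disk(64, 64, 32, 44, 7) - 0.05)
  })
  post <- lapply(1:3, function(i) {
    segment_frame(render_ellipse(64, 64, 32, 32, 14, 8, pi / 2))
  })
  # parents sit 12 px from the fused centroid; max_step must cover that
  tracks <- track_droplets(c(pre, post), max_step = 13)
  merged <- Filter(function(tr) length(attr(tr, "merged_from")) == 2L, tracks)
  expect_length(merged, 1L)
  parents <- attr(merged[[1]], "merged_from")
  expect_equal(vapply(tracks[parents], function(tr) max(tr$frame),
                      numeric(1)), c(3, 3))
  expect_equal(min(merged[[1]]$frame), 4)
})

test_that("whole-droplet masking measures the second channel", {
  wd <- sim_wholedroplet_frap(seed = 31, noise_sd = 0.003)
  tr <- whole_droplet_mask_from_channel(wd$stacks, "FITC", "Cy5")
  # recovery embedded in the measured channel is visible in the trace
  norm <- tr$measured_mean / mean(tr$measured_mean[1:5])
  fit <- fit_recovery(norm, time_s = tr$time_s, t_bleach = wd$truth$t_bleach)
  expect_lt(abs(coef(fit)[["tau"]] - wd$truth$tau) / wd$truth$tau, 0.05)

  # identical channels: trace equals the within-mask mean of the mask channel
  same <- whole_droplet_mask_from_channel(
    list(a = wd$stacks$FITC, b = wd$stacks$FITC), "a", "b")
  dm <- segment_frame(wd$stacks$FITC$frames[, , 1],
                      pixel_size = wd$stacks$FITC$pixel_size)
  expect_equal(same$measured_mean[1],
               mean(wd$stacks$FITC$frames[, , 1][dm$labels > 0]))

  # blank mask channel: all-missing trace with a warning
  blank <- image_stack(array(0.5, c(16, 16, 3)))
  meas <- image_stack(array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_warning(
    out <- whole_droplet_mask_from_channel(list(m = blank, v = meas),
                                           "m", "v"),
    "empty")
  expect_true(all(is.na(out$measured_mean)))
})
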