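test_that("mirroring reflects the column range about the image midline", {
  # cols 101..150 in a 640-wide image map to cols 491..540
  r <- roi("knee", "left", top = 200, left = 101, bottom = 240, right = 150)
  h <- mirror_roi(r, 640)
  expect_equal(c(h$left, h$right), c(491L, 540L))
  expect_equal(c(h$top, h$bottom), c(200L, 240L))
  expect_identical(h$leg, "right")
  expect_identical(roi_dims(h), roi_dims(r))
})

test_that("mirroring is an involution and respects an explicit axis", {
  set.seed(51)
  for (i in 1:25) {
    left <- sample(1:300, 1); right <- left + sample(0:80, 1)
    top <- sample(1:400, 1); bottom <- top + sample(0:60, 1)
    r <- roi(sample(c("knee", "hip", "ankle"), 1),
             sample(c("left", "right"), 1), top, left, bottom, right)
    expect_identical(mirror_roi(mirror_roi(r, 640), 640), r)
  }
  r <- roi("knee", "left", 10, 30, 20, 40)
  h <- mirror_roi(r, 640, axis_col = 50)
  expect_equal(c(h$left, h$right), c(60L, 70L))
  expect_identical(mirror_roi(h, 640, axis_col = 50), r)
  # an off-centre axis can push the reflection out of bounds
  expect_error(mirror_roi(r, 640, axis_col = 15), "outside")
})

test_that("roi_frame_mean on forced-arithmetic cases", {
  f <- thermal_frame(matrix(31, 10, 10))
  expect_equal(roi_frame_mean(f, roi("knee", "left", 2, 2, 7, 9)), 31)
  g <- thermal_frame(matrix(c(30, 32, 31, 33), 2, 2))  # {30,31,32,33}
  expect_equal(roi_frame_mean(g, roi("knee", "left", 1, 1, 2, 2)), 31.5)
})

test_that("roi_frame_mean equals the brute-force pixel loop", {
  set.seed(52)
  f <- thermal_frame(matrix(runif(96 * 128, 22, 36), 96, 128))
  for (i in 1:30) {
    left <- sample(1:120, 1); right <- min(128L, left + sample(0:30, 1))
    top <- sample(1:90, 1); bottom <- min(96L, top + sample(0:30, 1))
    r <- roi("knee", "left", top, left, bottom, right)
    expect_equal(roi_frame_mean(f, r), bf_roi_mean(f, r), tolerance = 1e-12)
  }
  expect_error(roi_frame_mean(f, roi("knee", "left", 1, 1, 97, 5)),
               "outside")
})

test_that("roi_recording_mean averages per-frame means over given frames", {
  mk <- function(vals) {
    frames <- lapply(seq_along(vals), function(i)
      thermal_frame(matrix(vals[i], 4, 4), (i - 1) / 30, i))
    thermal_recording(frames, 30, "anterior_sitting")
  }
  r <- roi("knee", "left", 1, 1, 4, 4)
  rec <- mk(rep(31, 20))
  expect_equal(roi_recording_mean(rec, r, 1:20), 31)
  rec3 <- mk(c(30, 31, 32))
  expect_equal(roi_recording_mean(rec3, r, 1:3), 31)
  # only the listed frames enter
  expect_equal(roi_recording_mean(rec3, r, c(1, 3)), 31)
  expect_equal(roi_recording_mean(rec3, r, 2), 31)
  expect_error(roi_recording_mean(rec3, r, integer(0)), "non-empty")
  expect_error(roi_recording_mean(rec3, r, 4), "1..3")
})

test_that("roi_recording_mean matches a mean-of-means oracle on random data", {
  set.seed(53)
  frames <- lapply(1:8, function(i)
    thermal_frame(matrix(runif(48 * 64, 24, 36), 48, 64), (i - 1) / 30, i))
  rec <- thermal_recording(frames, 30, "anterior_sitting")
  r <- roi("lower_knee", "left", 10, 5, 30, 20)
  idx <- c(2, 3, 5, 8)
  oracle <- mean(vapply(idx, function(i) bf_roi_mean(frames[[i]], r),
                        numeric(1)))
  expect_equal(roi_recording_mean(rec, r, idx), oracle, tolerance = 1e-12)
})

test_that("percentage_difference reproduces the published group rows", {
  # printed median pairs and their printed percentage columns
  expect_equal(round(percentage_difference(32.01, 31.18), 2), 2.59)
  expect_equal(round(percentage_difference(30.58, 29.39), 2), 3.89)
  expect_equal(round(percentage_difference(32.45, 30.72), 2), 5.33)
  expect_equal(round(percentage_difference(31.91, 30.65), 2), 3.95)
})

test_that("percentage_difference algebra: zero at equality, guard, monotone", {
  for (t in c(28, 31.7, 36))
    expect_equal(percentage_difference(t, t), 0)
  expect_error(percentage_difference(0, 30), "positive")
  expect_error(percentage_difference(-2, 30), "positive")
  # strictly increasing in (affected - healthy) at fixed affected
  a <- 32
  d <- percentage_difference(a, a - seq(-1, 1, by = 0.1))
  expect_true(all(diff(d) > 0))  # larger affected-healthy gap -> larger pct
  pd <- percentage_difference(a, a - seq(0.1, 1, by = 0.1))
  expect_true(all(pd > 0))
})

test_that("paired_roi validates label, leg and dimensions", {
  a <- roi("knee", "left", 10, 10, 20, 20)
  expect_error(paired_roi(a, roi("hip", "right", 10, 40, 20, 50)), "label")
  expect_error(paired_roi(a, roi("knee", "left", 10, 40, 20, 50)),
               "opposite")
  expect_error(paired_roi(a, roi("knee", "right", 10, 40, 20, 51)),
               "identical")
  expect_s3_class(paired_roi(a, mirror_roi(a, 64)), "paired_roi")
})

test_that("measure_pair: symmetric phantom gives exactly zero asymmetry", {
  p <- small_params(noise_sd = 0)
  rec <- generate_recording(p, duration_s = 0.2, rate_hz = 30)
  rois <- phantom_rois(p, "left")
  for (lab in names(rois)) {
    pr <- paired_roi(rois[[lab]], mirror_roi(rois[[lab]], 128))
    m <- measure_pair(rec, pr, 1:6)
    expect_identical(m$pct_diff, 0)
    expect_equal(m$n_frames, 6L)
  }
})

test_that("measure_pair recovers a known hotspot elevation exactly", {
  center <- c(50, 41); sigma <- 8; amp <- 0.8
  p <- small_params(noise_sd = 0,
                    hotspot = list(leg = "left", center = center,
                                   sigma = sigma, amplitude = amp))
  rec <- generate_recording(p, duration_s = 0.2, rate_hz = 30)
  r <- roi("knee", "left", 44, 35, 56, 47)
  pr <- paired_roi(r, mirror_roi(r, 128))
  m <- measure_pair(rec, pr, 1:6)
  expect_equal(m$affected_mean - m$healthy_mean,
               bf_gaussian_elevation(r, center, sigma, amp),
               tolerance = 1e-12)
})

test_that("swapping affected and healthy flips sign and rescales", {
  p <- small_params(noise_sd = 0,
                    hotspot = list(leg = "left", center = c(50, 41),
                                   sigma = 8, amplitude = 0.8))
  rec <- generate_recording(p, duration_s = 0.2, rate_hz = 30)
  r <- roi("knee", "left", 44, 35, 56, 47)
  h <- mirror_roi(r, 128)
  m1 <- measure_pair(rec, paired_roi(r, h), 1:6)
  m2 <- measure_pair(rec, paired_roi(h, r), 1:6)
  expect_lt(m2$pct_diff, 0)
  # same absolute numerator, denominators differ per the definition
  expect_equal(m1$pct_diff * m1$affected_mean,
               -m2$pct_diff * m2$affected_mean, tolerance = 1e-9)
})
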