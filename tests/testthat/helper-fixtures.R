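# Shared fixtures and independent oracles.

# Small phantom used throughout: full geometry at reduced resolution.
small_params <- function(...) {
  phantom_params(image_shape = c(96, 128), ...)
}

# Brute-force ROI mean: explicit double loop, independent of the
# vectorised implementation.
bf_roi_mean <- function(frame, roi) {
  s <- 0; n <- 0L
  for (i in roi$top:roi$bottom) {
    for (j in roi$left:roi$right) {
      s <- s + frame$temps[i, j]
      n <- n + 1L
    }
  }
  s / n
}

# Sort-based median / IQR oracle (linear interpolation between order
# statistics, worked out directly from sorted values).
bf_median <- function(x) {
  x <- sort(x); n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}
bf_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
bf_iqr <- function(x) bf_quartile(x, 0.75) - bf_quartile(x, 0.25)

# Mean elevation of an isotropic Gaussian bump over an ROI, by direct
# pixel-grid summation of the analytic formula (numeric integration).
bf_gaussian_elevation <- function(roi, center, sigma, amplitude) {
  s <- 0; n <- 0L
  for (i in roi$top:roi$bottom) {
    for (j in roi$left:roi$right) {
      s <- s + amplitude *
        exp(-((i - center[1])^2 + (j - center[2])^2) / (2 * sigma^2))
      n <- n + 1L
    }
  }
  s / n
}

# A cohort table with the published pilot study's categorical composition:
# 30 subjects; 16 trauma, 17 weight-bearing, sides 11/18/1 (right/left/both),
# regions 13/6/8/3 (hip_thigh/knee/lower_leg/ankle), diagnoses 13/9/3/4/1.
reference_shaped_cohort <- function() {
  n <- 30L
  # the bilateral subject sits in the "other" diagnosis group; the
  # unknown-diagnosis subject is a different child (lost to follow-up)
  side <- rep("left", n)
  side[1:11] <- "right"
  side[26] <- "both"
  region <- c(rep("hip_thigh", 13), rep("knee", 6), rep("lower_leg", 8),
              rep("ankle", 3))
  dx <- c(rep("soft_tissue_injury", 13), rep("irritable_hip", 9),
          rep("fracture", 3), rep("other", 4), "unknown")
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = rep(5, n),
    affected_side = side,
    complaint_region = region,
    onset_hours = rep(24, n),
    diagnosis = dx,
    trauma = c(rep(TRUE, 16), rep(FALSE, 14)),
    weight_bearing = c(rep(TRUE, 17), rep(FALSE, 13)),
    stringsAsFactors = FALSE
  )
}
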