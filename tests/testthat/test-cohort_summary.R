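test_that("exclusion rules and reason codes", {
  base <- reference_shaped_cohort()

  # bilateral involvement excludes (no healthy-leg reference)
  res <- apply_exclusions(base)
  expect_true("bilateral" %in% unlist(strsplit(res$excluded$reason, ";")))

  # the published-cohort shape: 30 subjects, 1 bilateral + 1 unknown -> 28
  expect_equal(nrow(res$included), 28L)
  expect_equal(nrow(res$excluded), 2L)
  expect_setequal(res$excluded$reason, c("bilateral", "unknown_diagnosis"))

  # a subject at the inclusion margins stays in
  marginal <- subject_record("M1", age = 14.9, affected_side = "left",
                             complaint_region = "knee", onset_hours = 47,
                             diagnosis = "soft_tissue_injury")
  expect_equal(nrow(apply_exclusions(marginal)$included), 1L)

  # each rule fires with its own code
  late <- subject_record("L1", age = 3, affected_side = "left",
                         complaint_region = "knee", onset_hours = 49,
                         diagnosis = "fracture")
  old <- subject_record("O1", age = 15, affected_side = "left",
                        complaint_region = "knee", onset_hours = 2,
                        diagnosis = "fracture")
  expect_equal(apply_exclusions(late)$excluded$reason, "onset_over_48h")
  expect_equal(apply_exclusions(old)$excluded$reason, "age_limit")
})

test_that("complaint regions map to their relevant ROIs", {
  expect_setequal(relevant_rois("hip_thigh"), c("hip", "upper_knee"))
  expect_equal(relevant_rois("knee"), "knee")
  expect_equal(relevant_rois("lower_leg"), "lower_knee")
  expect_equal(relevant_rois("ankle"), "ankle")
  expect_error(relevant_rois("forearm"))
})

test_that("summarize_group: single subject keeps values, drops IQR", {
  g <- summarize_group(data.frame(affected_mean = 31.91,
                                  healthy_mean = 30.65))
  expect_equal(g$n, 1L)
  expect_equal(g$median_affected, 31.91)
  expect_equal(g$median_healthy, 30.65)
  expect_true(is.na(g$iqr_affected) && is.na(g$iqr_healthy))
  expect_equal(round(g$pct_diff, 2), 3.95)
})

test_that("summarize_group medians and IQRs match a sort-based oracle", {
  g <- summarize_group(data.frame(affected_mean = c(30, 31, 32),
                                  healthy_mean = c(29, 30, 31)))
  expect_equal(g$median_affected, 31)

  set.seed(61)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    a <- runif(n, 29, 35); h <- runif(n, 29, 35)
    g <- summarize_group(data.frame(affected_mean = a, healthy_mean = h))
    expect_equal(g$median_affected, bf_median(a))
    expect_equal(g$median_healthy, bf_median(h))
    expect_equal(g$iqr_affected, bf_iqr(a))
    expect_equal(g$iqr_healthy, bf_iqr(h))
    expect_equal(g$pct_diff,
                 (bf_median(a) - bf_median(h)) / bf_median(a) * 100)
  }
  expect_error(summarize_group(data.frame(affected_mean = numeric(0),
                                          healthy_mean = numeric(0))),
               "empty")
})

test_that("summarize_group and summarize_cohort are order-invariant", {
  set.seed(62)
  a <- runif(9, 29, 35); h <- runif(9, 29, 35)
  g1 <- summarize_group(data.frame(affected_mean = a, healthy_mean = h))
  perm <- sample(9)
  g2 <- summarize_group(data.frame(affected_mean = a[perm],
                                   healthy_mean = h[perm]))
  expect_equal(g1, g2)

  meas <- data.frame(
    subject_id = sprintf("S%02d", 1:6),
    diagnosis = rep(c("fracture", "soft_tissue_injury"), each = 3),
    complaint_region = "lower_leg", position = "anterior_sitting",
    roi = "lower_knee",
    affected_mean = runif(6, 30, 34), healthy_mean = runif(6, 29, 33))
  s1 <- summarize_cohort(meas)
  s2 <- summarize_cohort(meas[sample(6), ])
  expect_equal(s1, s2)
})

test_that("summarize_cohort keeps only relevant ROIs and named groups", {
  meas <- data.frame(
    subject_id = c("A", "A", "B", "C"),
    diagnosis = c("irritable_hip", "irritable_hip", "other",
                  "soft_tissue_injury"),
    complaint_region = c("hip_thigh", "hip_thigh", "knee", "knee"),
    position = "anterior_standing",
    roi = c("hip", "ankle", "knee", "knee"),
    affected_mean = c(32.2, 30.1, 31.9, 31.9),
    healthy_mean = c(31.8, 30.0, 31.5, 31.5))
  out <- summarize_cohort(meas)
  # ankle is not relevant to a hip/thigh complaint; "other" is not a group
  expect_equal(nrow(out), 2L)
  expect_setequal(out$roi, c("hip", "knee"))
  expect_false("other" %in% out$diagnosis)
})

test_that("descriptive summary reproduces the published percentages", {
  desc <- descriptive_summary(reference_shaped_cohort())
  pick <- function(cat, lev) desc$pct[desc$category == cat &
                                        desc$level == lev]
  expect_equal(pick("diagnosis", "soft_tissue_injury"), 43.3)
  expect_equal(pick("diagnosis", "irritable_hip"), 30.0)
  expect_equal(pick("diagnosis", "fracture"), 10.0)
  expect_equal(pick("affected_side", "left"), 60.0)
  expect_equal(pick("affected_side", "right"), 36.7)
  expect_equal(pick("trauma", "yes"), 53.3)
  expect_equal(pick("weight_bearing", "no"), 43.3)
  expect_equal(pick("complaint_region", "hip_thigh"), 43.3)

  # percentages within each category sum to 100 up to rounding
  sums <- tapply(desc$pct, desc$category, sum)
  expect_true(all(abs(sums - 100) <= 0.1 + 1e-9))

  # counts match the embedded reference distribution
  ref <- reference_complaint_counts()
  for (i in seq_len(nrow(ref))) {
    expect_equal(desc$n[desc$category == ref$category[i] &
                          desc$level == ref$level[i]], ref$n[i])
  }
})

test_that("descriptive summary of a single subject reports 100%", {
  s <- subject_record("Z1", age = 4, affected_side = "right",
                      complaint_region = "ankle", onset_hours = 5,
                      diagnosis = "fracture", trauma = TRUE,
                      weight_bearing = FALSE)
  desc <- descriptive_summary(s)
  expect_true(all(desc$pct == 100))
  expect_error(descriptive_summary(data.frame()), "empty")
})

test_that("every published group row regenerates from its printed medians", {
  ref <- reference_group_medians()
  expect_equal(nrow(ref), 12L)
  regen <- round(percentage_difference(ref$median_affected,
                                       ref$median_healthy), 2)
  expect_equal(regen, ref$pct_diff_reported)
  # single-subject rows carry no IQR
  expect_true(all(is.na(ref$iqr_affected[ref$n == 1])))
  expect_true(all(!is.na(ref$iqr_affected[ref$n > 1])))
})

test_that("formatted group table renders 2 dp and n/a IQRs", {
  meas <- data.frame(
    subject_id = "A", diagnosis = "soft_tissue_injury",
    complaint_region = "hip_thigh", position = "anterior_sitting",
    roi = "upper_knee", affected_mean = 31.91, healthy_mean = 30.65)
  fm <- format_group_summary(summarize_cohort(meas))
  expect_equal(fm$affected, "31.91 (n/a)")
  expect_equal(fm$healthy, "30.65 (n/a)")
  expect_equal(fm$pct_diff, "3.95")
})
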