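#' Published group medians from the originating clinical pilot cohort
#'
#' The group-level results reported by the clinical pilot study this
#' pipeline operationalises: for each (complaint region, ROI, imaging
#' position, diagnosis group) cell, the group size, the median affected-leg
#' and healthy-leg ROI temperatures (degrees C) and the printed percentage
#' temperature difference.  The underlying per-patient recordings were
#' never published, so these medians serve two roles here: a regression
#' fixture for the percentage-difference statistic (every printed
#' percentage regenerates from its median pair) and a realistic temperature
#' range for the synthetic phantom defaults.
#'
#' @return Data frame with columns `complaint_region`, `roi`, `position`,
#'   `diagnosis`, `n`, `median_affected`, `iqr_affected`, `median_healthy`,
#'   `iqr_healthy`, `pct_diff_reported` (IQRs `NA` where the source reports
#'   none, i.e. single-subject cells).
#' @export
reference_group_medians <- function() {
  df <- read.csv(text = '
complaint_region,roi,position,diagnosis,n,median_affected,iqr_affected,median_healthy,iqr_healthy,pct_diff_reported
hip_thigh,upper_knee,anterior_standing,soft_tissue_injury,3,32.01,1.92,31.18,2.64,2.59
hip_thigh,upper_knee,anterior_standing,irritable_hip,9,32.77,1.74,32.54,1.85,0.70
hip_thigh,hip,anterior_standing,soft_tissue_injury,4,31.93,1.64,31.50,1.12,1.35
hip_thigh,hip,anterior_standing,irritable_hip,8,32.16,2.19,31.82,1.60,1.06
hip_thigh,upper_knee,anterior_sitting,soft_tissue_injury,1,31.91,NA,30.65,NA,3.95
hip_thigh,upper_knee,anterior_sitting,irritable_hip,6,32.99,2.49,32.73,1.79,0.79
knee,knee,anterior_standing,soft_tissue_injury,4,31.87,1.05,31.47,1.80,1.26
knee,knee,anterior_sitting,soft_tissue_injury,6,32.76,1.70,32.43,0.99,1.01
lower_leg,lower_knee,anterior_standing,soft_tissue_injury,1,33.34,NA,32.85,NA,1.47
lower_leg,lower_knee,anterior_standing,fracture,3,30.58,2.55,29.39,2.08,3.89
lower_leg,lower_knee,anterior_sitting,soft_tissue_injury,2,33.97,0.38,33.45,0.65,1.53
lower_leg,lower_knee,anterior_sitting,fracture,4,32.45,3.16,30.72,1.92,5.33
', stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

#' Published distribution of presenting complaints
#'
#' The categorical composition of the originating 30-child pilot cohort:
#' counts per level of trauma, weight-bearing status, affected side,
#' presenting-complaint region and clinical diagnosis.  Used to build
#' fixture cohorts with the same categorical structure (hip and thigh
#' complaints are pooled into `hip_thigh`, the unit the ROI mapping
#' operates on).
#'
#' @return Data frame with columns `category`, `level`, `n`.
#' @export
reference_complaint_counts <- function() {
  read.csv(text = '
category,level,n
trauma,yes,16
trauma,no,14
weight_bearing,yes,17
weight_bearing,no,13
affected_side,right,11
affected_side,left,18
affected_side,both,1
complaint_region,hip_thigh,13
complaint_region,knee,6
complaint_region,lower_leg,8
complaint_region,ankle,3
diagnosis,soft_tissue_injury,13
diagnosis,irritable_hip,9
diagnosis,fracture,3
diagnosis,other,4
diagnosis,unknown,1
', stringsAsFactors = FALSE, strip.white = TRUE)
}
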