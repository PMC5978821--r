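#' Apply the study's exclusion rules to a cohort
#'
#' A subject is excluded when any of the following holds, each carrying a
#' machine-readable reason code:
#'
#' * `onset_over_48h` — more than 48 hours since symptom onset;
#' * `age_limit` — aged 15 years or older;
#' * `bilateral` — both legs involved, so no healthy-leg reference exists;
#' * `unknown_diagnosis` — lost to follow-up, no definitive diagnosis.
#'
#' Subjects diagnosed `"other"` are retained here (they belong in the
#' descriptive summary) even though they fall outside the three named
#' diagnosis groups of the group-summary table.
#'
#' @param cohort Data frame of subjects ([subject_table()] /
#'   [subject_record()] columns).
#' @return List with elements `included` (data frame) and `excluded` (data
#'   frame with an extra `reason` column; multiple codes are
#'   semicolon-joined).
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  reasons <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- character(0)
    if (cohort$onset_hours[i] > 48) r <- c(r, "onset_over_48h")
    if (cohort$age[i] >= 15) r <- c(r, "age_limit")
    if (cohort$affected_side[i] == "both") r <- c(r, "bilateral")
    if (cohort$diagnosis[i] == "unknown") r <- c(r, "unknown_diagnosis")
    r
  })
  drop <- lengths(reasons) > 0
  excluded <- cohort[drop, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- vapply(reasons[drop], paste, character(1),
                              collapse = ";")
  else
    excluded$reason <- character(0)
  included <- cohort[!drop, , drop = FALSE]
  rownames(included) <- rownames(excluded) <- NULL
  list(included = included, excluded = excluded)
}

#' Map a presenting-complaint region to its relevant ROIs
#'
#' Skin temperature declines naturally from hip to ankle, so different leg
#' segments cannot be compared with each other; each complaint region is
#' therefore analysed only through the ROIs that overlie it: hip/thigh pain
#' through the hip and upper-knee ROIs, knee pain through the knee ROI,
#' lower-leg pain through the lower-knee ROI and ankle pain through the
#' ankle ROI.
#'
#' @param complaint_region One of `"hip_thigh"`, `"knee"`, `"lower_leg"`,
#'   `"ankle"`.
#' @return Character vector of ROI labels.
#' @examples
#' relevant_rois("hip_thigh")
#' @export
relevant_rois <- function(complaint_region) {
  switch(match.arg(complaint_region, COMPLAINT_REGIONS),
         hip_thigh = c("hip", "upper_knee"),
         knee = "knee",
         lower_leg = "lower_knee",
         ankle = "ankle")
}

#' Summarise one diagnosis group
#'
#' Across the subjects of one (diagnosis group, region, ROI, position)
#' cell: medians and interquartile ranges of the affected-leg and
#' healthy-leg mean temperatures, and the percentage difference of the two
#' *medians* (not the median of per-subject percentage differences — the
#' convention that regenerates the published percentage column exactly).
#' With a single subject the IQR is reported absent (`NA`).  Quartiles use
#' linear interpolation between order statistics (`quantile` type 7).
#'
#' @param measurements Data frame with numeric columns `affected_mean` and
#'   `healthy_mean`, one row per subject.
#' @return One-row data frame: `n`, `median_affected`, `iqr_affected`,
#'   `median_healthy`, `iqr_healthy`, `pct_diff` (full precision).
#' @export
summarize_group <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("affected_mean", "healthy_mean") %in% names(measurements)))
  n <- nrow(measurements)
  if (n == 0L) stop_tl("cannot summarise an empty group")
  a <- measurements$affected_mean
  h <- measurements$healthy_mean
  med_a <- median(a)
  med_h <- median(h)
  data.frame(
    n = n,
    median_affected = med_a,
    iqr_affected = if (n > 1L) unname(diff(quantile(a, c(0.25, 0.75)))) else NA_real_,
    median_healthy = med_h,
    iqr_healthy = if (n > 1L) unname(diff(quantile(h, c(0.25, 0.75)))) else NA_real_,
    pct_diff = percentage_difference(med_a, med_h)
  )
}

#' Group-summary table across a cohort's measurements
#'
#' Builds the group-level table: one row per (complaint region, ROI,
#' imaging position, diagnosis group) combination present in the
#' measurements, restricted to the three named diagnosis groups
#' (soft tissue injury, irritable hip, fracture) and, per subject, to the
#' ROIs relevant to the presenting complaint ([relevant_rois()]).  A
#' subject lacking a recording in some position simply contributes nothing
#' to that row.
#'
#' @param measurements Data frame with columns `subject_id`, `diagnosis`,
#'   `complaint_region`, `position`, `roi`, `affected_mean`,
#'   `healthy_mean` (one row per subject x position x ROI).
#' @param groups Diagnosis groups to report.
#' @return Data frame of [summarize_group()] rows keyed by
#'   `complaint_region`, `roi`, `position`, `diagnosis`.
#' @export
summarize_cohort <- function(measurements,
                             groups = c("soft_tissue_injury",
                                        "irritable_hip", "fracture")) {
  stopifnot(is.data.frame(measurements))
  need <- c("subject_id", "diagnosis", "complaint_region", "position",
            "roi", "affected_mean", "healthy_mean")
  missing <- setdiff(need, names(measurements))
  if (length(missing))
    stop_tl("measurements lack column(s): ", paste(missing, collapse = ", "))
  m <- measurements[measurements$diagnosis %in% groups, , drop = FALSE]
  keep <- mapply(function(region, lab) lab %in% relevant_rois(region),
                 m$complaint_region, m$roi)
  m <- m[as.logical(keep), , drop = FALSE]
  if (nrow(m) == 0L)
    stop_tl("no measurements left after restricting to relevant ROIs/groups")
  key <- interaction(m$complaint_region, m$roi, m$position, m$diagnosis,
                     drop = TRUE)
  parts <- split(m, key)
  rows <- lapply(parts, function(p) {
    cbind(data.frame(complaint_region = p$complaint_region[1],
                     roi = p$roi[1], position = p$position[1],
                     diagnosis = p$diagnosis[1]),
          summarize_group(p))
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$complaint_region, COMPLAINT_REGIONS),
               match(out$roi, ROI_LABELS), out$position,
               match(out$diagnosis, DIAGNOSES))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Descriptive summary of presenting complaints
#'
#' Count and percentage (1 decimal place) per level of each categorical
#' feature of the cohort: trauma, weight-bearing status, affected side,
#' complaint region and diagnosis.  Percentages within a category sum to
#' 100 up to rounding.
#'
#' @param cohort Non-empty data frame of subjects.
#' @return Data frame with columns `category`, `level`, `n`, `pct`.
#' @export
descriptive_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop_tl("cohort is empty")
  n_total <- nrow(cohort)
  feat <- list(
    trauma = c("TRUE" = "yes", "FALSE" = "no"),
    weight_bearing = c("TRUE" = "yes", "FALSE" = "no"),
    affected_side = NULL,
    complaint_region = NULL,
    diagnosis = NULL
  )
  rows <- lapply(names(feat), function(col) {
    v <- as.character(cohort[[col]])
    relab <- feat[[col]]
    if (!is.null(relab)) v <- unname(relab[v])
    tab <- table(v)
    data.frame(category = col, level = names(tab),
               n = as.integer(tab),
               pct = round(as.integer(tab) / n_total * 100, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a group-summary table for reporting
#'
#' Renders temperatures and percentages at 2 decimal places and absent
#' IQRs (single-subject cells) as `"n/a"`, the reporting precision of the
#' group table.
#'
#' @param summary A [summarize_cohort()] data frame.
#' @return Data frame of formatted character columns.
#' @export
format_group_summary <- function(summary) {
  fmt_iqr <- function(x) ifelse(is.na(x), "n/a", sprintf("%.2f", x))
  data.frame(
    complaint_region = summary$complaint_region,
    roi = summary$roi,
    position = summary$position,
    diagnosis = summary$diagnosis,
    n = summary$n,
    affected = sprintf("%.2f (%s)", summary$median_affected,
                       fmt_iqr(summary$iqr_affected)),
    healthy = sprintf("%.2f (%s)", summary$median_healthy,
                      fmt_iqr(summary$iqr_healthy)),
    pct_diff = sprintf("%.2f", summary$pct_diff),
    stringsAsFactors = FALSE
  )
}
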