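#' Rectangular region of interest
#'
#' An axis-aligned rectangle on the image grid, identified by its anatomical
#' label and the leg it sits on.  Coordinates are 1-based and inclusive on
#' both axes (`top:bottom` rows by `left:right` columns), matching R matrix
#' indexing; a 1 x 1 rectangle has `top == bottom` and `left == right`.
#' Validity against a particular image is checked at measurement time.
#'
#' @param label One of `"upper_knee"`, `"knee"`, `"lower_knee"`, `"ankle"`,
#'   `"hip"`.
#' @param leg `"left"` or `"right"`.
#' @param top,left,bottom,right Integer pixel bounds, `top <= bottom`,
#'   `left <= right`, all >= 1.
#' @return An object of class `roi`.
#' @examples
#' r <- roi("knee", "left", top = 200, left = 101, bottom = 240, right = 150)
#' roi_dims(r)
#' @export
roi <- function(label, leg, top, left, bottom, right) {
  label <- match.arg(label, ROI_LABELS)
  leg <- match.arg(leg, c("left", "right"))
  b <- as.integer(c(top, left, bottom, right))
  if (anyNA(b) || any(b < 1L))
    stop_tl("ROI bounds must be positive integers")
  if (b[3] < b[1] || b[4] < b[2])
    stop_tl("ROI must satisfy top <= bottom and left <= right")
  structure(list(label = label, leg = leg,
                 top = b[1], left = b[2], bottom = b[3], right = b[4]),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s (%s leg): rows %d..%d, cols %d..%d (%d x %d px)\n",
              x$label, x$leg, x$top, x$bottom, x$left, x$right,
              x$bottom - x$top + 1L, x$right - x$left + 1L))
  invisible(x)
}

#' ROI height and width in pixels
#' @param x An [roi()].
#' @return `c(height, width)`.
#' @export
roi_dims <- function(x) {
  stopifnot(inherits(x, "roi"))
  c(x$bottom - x$top + 1L, x$right - x$left + 1L)
}

check_roi_in_frame <- function(roi, nrow, ncol) {
  if (roi$bottom > nrow || roi$right > ncol)
    stop_tl(sprintf(
      "ROI (rows %d..%d, cols %d..%d) lies outside the %d x %d image",
      roi$top, roi$bottom, roi$left, roi$right, nrow, ncol))
  invisible(TRUE)
}

#' Mirror an ROI onto the contralateral leg
#'
#' Reflects the column range about a vertical axis, leaving rows untouched
#' and flipping the leg; height and width are preserved and mirroring is an
#' involution.  The default axis is the image's vertical midline
#' (`(image_width + 1) / 2`), matching a subject centred in the frame; an
#' explicit `axis_col` (e.g. the midpoint between leg centroids) may
#' override it, in which case the reflected rectangle must still fall
#' inside the image.
#'
#' @param roi An [roi()] on the affected leg.
#' @param image_width Image width in columns.
#' @param axis_col Reflection axis (column units, halves allowed); default
#'   the image midline.
#' @return The mirrored [roi()] on the opposite leg.
#' @export
mirror_roi <- function(roi, image_width, axis_col = NULL) {
  stopifnot(inherits(roi, "roi"))
  image_width <- as.integer(image_width)
  if (roi$right > image_width)
    stop_tl("ROI does not fit in an image of width ", image_width)
  a <- axis_col %||% ((image_width + 1) / 2)
  new_left <- as.integer(round(2 * a - roi$right))
  new_right <- as.integer(round(2 * a - roi$left))
  if (new_left < 1L || new_right > image_width)
    stop_tl("mirrored ROI falls outside the image (axis_col = ", a, ")")
  roi(roi$label, if (roi$leg == "left") "right" else "left",
      top = roi$top, left = new_left, bottom = roi$bottom, right = new_right)
}

#' Paired affected/healthy ROI
#'
#' Couples an ROI on the affected leg with its size-identical,
#' same-labelled counterpart on the healthy leg (normally produced by
#' [mirror_roi()]).
#'
#' @param affected,healthy [roi()] objects with identical dimensions, the
#'   same anatomical label and opposite legs.
#' @return An object of class `paired_roi`.
#' @export
paired_roi <- function(affected, healthy) {
  stopifnot(inherits(affected, "roi"), inherits(healthy, "roi"))
  if (!identical(affected$label, healthy$label))
    stop_tl("paired ROIs must share one anatomical label")
  if (identical(affected$leg, healthy$leg))
    stop_tl("paired ROIs must lie on opposite legs")
  if (!identical(roi_dims(affected), roi_dims(healthy)))
    stop_tl("paired ROIs must have identical height and width")
  structure(list(affected = affected, healthy = healthy),
            class = "paired_roi")
}

#' Mean ROI temperature in one frame
#'
#' Arithmetic mean of all pixel temperatures inside the rectangle — the
#' per-frame reduction of the averaging procedure.
#'
#' @param frame A [thermal_frame].
#' @param roi An [roi()] fully inside the frame.
#' @return Mean temperature in degrees C.
#' @export
roi_frame_mean <- function(frame, roi) {
  stopifnot(inherits(frame, "thermal_frame"), inherits(roi, "roi"))
  check_roi_in_frame(roi, nrow(frame$temps), ncol(frame$temps))
  mean(frame$temps[roi$top:roi$bottom, roi$left:roi$right])
}

#' Mean ROI temperature across selected frames
#'
#' The per-frame ROI means over exactly the given frames, averaged without
#' weighting — the across-frame reduction of the averaging procedure
#' (classically over the 20 selected frames).
#'
#' @param recording A [thermal_recording].
#' @param roi An [roi()] inside the frames.
#' @param frame_indices Non-empty vector of 1-based frame indices.
#' @return Mean temperature in degrees C.
#' @export
roi_recording_mean <- function(recording, roi, frame_indices) {
  stopifnot(inherits(recording, "thermal_recording"))
  frame_indices <- as.integer(frame_indices)
  if (length(frame_indices) == 0L)
    stop_tl("`frame_indices` must be non-empty")
  n <- n_frames(recording)
  if (anyNA(frame_indices) || any(frame_indices < 1L | frame_indices > n))
    stop_tl("frame indices must lie in 1..", n)
  mean(vapply(frame_indices,
              function(i) roi_frame_mean(recording$frames[[i]], roi),
              numeric(1)))
}

#' Percentage temperature difference (affected vs healthy)
#'
#' The asymmetry statistic:
#' `(affected_mean - healthy_mean) / affected_mean * 100`.
#' The denominator is the affected-leg mean, so swapping the two arguments
#' changes both the sign and the magnitude.  Affected means must be
#' positive (skin temperatures in degrees C always are); the guard rejects
#' non-physiological input rather than returning an unstable ratio.
#' Full precision is returned; rounding to 2 decimal places happens only at
#' reporting boundaries.
#'
#' @param affected_mean,healthy_mean Mean ROI temperatures in degrees C;
#'   vectorised.
#' @return Percentage difference(s).
#' @examples
#' percentage_difference(32.01, 31.18)  # 2.59 at 2 dp
#' @export
percentage_difference <- function(affected_mean, healthy_mean) {
  if (any(!is.finite(affected_mean)) || any(!is.finite(healthy_mean)))
    stop_tl("means must be finite")
  if (any(affected_mean <= 0))
    stop_tl("`affected_mean` must be positive (degrees C skin temperature)")
  (affected_mean - healthy_mean) / affected_mean * 100
}

#' Measure a paired ROI over selected frames
#'
#' Applies the full averaging procedure to both members of a pair over the
#' *same* frame set — per-frame ROI means, then the across-frame mean for
#' each leg — and computes the percentage temperature difference.
#'
#' @param recording A [thermal_recording].
#' @param paired A [paired_roi()].
#' @param frame_indices Non-empty vector of 1-based frame indices shared by
#'   both ROIs.
#' @return An object of class `paired_measurement`: a list with
#'   `affected_mean`, `healthy_mean`, `n_frames`, `frame_indices` and
#'   `pct_diff`.
#' @export
measure_pair <- function(recording, paired, frame_indices) {
  stopifnot(inherits(paired, "paired_roi"))
  a <- roi_recording_mean(recording, paired$affected, frame_indices)
  h <- roi_recording_mean(recording, paired$healthy, frame_indices)
  structure(
    list(affected_mean = a, healthy_mean = h,
         n_frames = length(frame_indices),
         frame_indices = as.integer(frame_indices),
         pct_diff = percentage_difference(a, h)),
    class = "paired_measurement"
  )
}

#' @export
print.paired_measurement <- function(x, ...) {
  cat(sprintf(
    "<paired_measurement> affected %.2f degC, healthy %.2f degC over %d frames: %+.2f%%\n",
    x$affected_mean, x$healthy_mean, x$n_frames, x$pct_diff))
  invisible(x)
}
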