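#' Thermal frame
#'
#' A single radiometric frame: a rectangular matrix of skin/scene
#' temperatures in degrees Celsius, with its acquisition timestamp and
#' ordinal position within a recording.  All pixel statistics in the package
#' operate on this unit.
#'
#' Temperatures must be finite and inside the camera's radiometric range
#' (-40 to 650 degrees C); values outside it indicate a decoding or scaling
#' error and are rejected.
#'
#' @param temps Numeric matrix of temperatures in degrees C
#'   (rows x cols; row 1 = image top, column 1 = image left).
#' @param timestamp Seconds from the start of the recording.
#' @param index 1-based ordinal of the frame within its recording.
#' @return An object of class `thermal_frame`.
#' @examples
#' f <- thermal_frame(matrix(31, 4, 6))
#' dim(f$temps)
#' @export
thermal_frame <- function(temps, timestamp = 0, index = 1L) {
  if (!is.matrix(temps) || !is.numeric(temps) || length(temps) == 0L)
    stop_tl("`temps` must be a non-empty numeric matrix")
  if (!all(is.finite(temps)))
    stop_tl("`temps` contains non-finite values")
  rng <- range(temps)
  if (rng[1] < CAMERA_TEMP_RANGE[1] || rng[2] > CAMERA_TEMP_RANGE[2])
    stop_tl(sprintf(
      "temperatures outside the camera's radiometric range [%g, %g] degC (found %g..%g)",
      CAMERA_TEMP_RANGE[1], CAMERA_TEMP_RANGE[2], rng[1], rng[2]))
  if (!is.numeric(timestamp) || length(timestamp) != 1L || timestamp < 0)
    stop_tl("`timestamp` must be a single non-negative number")
  index <- as.integer(index)
  if (is.na(index) || index < 1L)
    stop_tl("`index` must be a positive integer")
  structure(
    list(temps = temps, timestamp = as.numeric(timestamp), index = index),
    class = "thermal_frame"
  )
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame> %d x %d px, t = %.3f s, index %d, %.2f..%.2f degC\n",
              nrow(x$temps), ncol(x$temps), x$timestamp, x$index,
              min(x$temps), max(x$temps)))
  invisible(x)
}

#' Thermal recording
#'
#' An ordered sequence of [thermal_frame] objects acquired at a fixed rate in
#' one of the four standardised imaging positions, together with the
#' recording-room environment and an opaque subject identifier.
#'
#' @param frames List of [thermal_frame] objects, already in acquisition
#'   order, all sharing one image shape, indices `1..n` and non-decreasing
#'   timestamps.
#' @param rate_hz Acquisition rate in frames per second.
#' @param position One of `"anterior_sitting"`, `"anterior_standing"`,
#'   `"left_lateral_standing"`, `"right_lateral_standing"`.
#' @param room_temp_c,humidity_pct Recording-room environment.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `thermal_recording`.
#' @export
thermal_recording <- function(frames, rate_hz, position,
                              room_temp_c = NA_real_, humidity_pct = NA_real_,
                              subject_id = "") {
  if (!is.list(frames) || length(frames) == 0L)
    stop_tl("`frames` must be a non-empty list of thermal_frame objects")
  ok <- vapply(frames, inherits, logical(1), "thermal_frame")
  if (!all(ok)) stop_tl("all elements of `frames` must be thermal_frame objects")
  idx <- vapply(frames, `[[`, integer(1), "index")
  if (!identical(idx, seq_along(frames)))
    stop_tl("frame indices must be consecutive 1..n in order")
  ts <- vapply(frames, `[[`, numeric(1), "timestamp")
  if (is.unsorted(ts)) stop_tl("frame timestamps must be non-decreasing")
  shp <- vapply(frames, function(f) dim(f$temps), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop_tl("all frames in a recording must share one image shape")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop_tl("`rate_hz` must be a single positive number")
  position <- match.arg(position, IMAGING_POSITIONS)
  structure(
    list(frames = frames, rate_hz = as.numeric(rate_hz), position = position,
         room_temp_c = as.numeric(room_temp_c),
         humidity_pct = as.numeric(humidity_pct),
         subject_id = as.character(subject_id)),
    class = "thermal_recording"
  )
}

#' @export
print.thermal_recording <- function(x, ...) {
  shp <- dim(x$frames[[1]]$temps)
  cat(sprintf("<thermal_recording> %d frames @ %g Hz, %d x %d px, position %s, subject '%s'\n",
              length(x$frames), x$rate_hz, shp[1], shp[2], x$position,
              x$subject_id))
  invisible(x)
}

#' Number of frames in a recording
#' @param recording A [thermal_recording].
#' @return Integer frame count.
#' @export
n_frames <- function(recording) {
  stopifnot(inherits(recording, "thermal_recording"))
  length(recording$frames)
}

frame_shape <- function(recording) dim(recording$frames[[1]]$temps)

#' Subject record
#'
#' Clinical metadata for one recruited child: demographics, the affected
#' side and presenting-complaint region, symptom onset, and the eventual
#' clinical diagnosis.  This is the unit that cohort-level exclusion rules
#' and descriptive summaries operate on; [subject_table()] binds several
#' into a data frame.
#'
#' @param subject_id Opaque identifier.
#' @param age Age in years (>= 0).
#' @param sex `"female"` or `"male"`.
#' @param height_cm,weight_kg,body_temp_c Anthropometrics and core
#'   temperature; may be `NA`.
#' @param affected_side `"left"`, `"right"` or `"both"`.
#' @param complaint_region One of `"hip_thigh"`, `"knee"`, `"lower_leg"`,
#'   `"ankle"`.
#' @param onset_hours Hours since symptom onset (>= 0).
#' @param diagnosis One of `"soft_tissue_injury"`, `"irritable_hip"`,
#'   `"fracture"`, `"other"`, `"unknown"`.
#' @param trauma,weight_bearing Logical flags.
#' @return A one-row data frame of class `subject_record`.
#' @export
subject_record <- function(subject_id, age, sex = NA_character_,
                           height_cm = NA_real_, weight_kg = NA_real_,
                           body_temp_c = NA_real_,
                           affected_side, complaint_region, onset_hours,
                           diagnosis, trauma = NA, weight_bearing = NA) {
  if (!is.numeric(age) || age < 0) stop_tl("`age` must be >= 0")
  if (!is.numeric(onset_hours) || onset_hours < 0)
    stop_tl("`onset_hours` must be >= 0")
  affected_side <- match.arg(affected_side, c("left", "right", "both"))
  complaint_region <- match.arg(complaint_region, COMPLAINT_REGIONS)
  diagnosis <- match.arg(diagnosis, DIAGNOSES)
  out <- data.frame(
    subject_id = as.character(subject_id), age = age, sex = sex,
    height_cm = height_cm, weight_kg = weight_kg, body_temp_c = body_temp_c,
    affected_side = affected_side, complaint_region = complaint_region,
    onset_hours = onset_hours, diagnosis = diagnosis,
    trauma = as.logical(trauma), weight_bearing = as.logical(weight_bearing),
    stringsAsFactors = FALSE
  )
  class(out) <- c("subject_record", class(out))
  out
}

#' Bind subject records into a cohort table
#' @param ... [subject_record()] rows or compatible one-row data frames.
#' @return A data frame with one row per subject.
#' @export
subject_table <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  out
}
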