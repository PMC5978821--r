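#' Write a thermal frame to disk
#'
#' Two on-disk raster formats are supported:
#'
#' * `"csv"` — the raw temperature matrix, comma-separated floats, one image
#'   row per line, no header.  Lossless to printed precision.
#' * `"tiff16"` — single-channel unsigned 16-bit TIFF holding counts
#'   `round((temp - offset) / scale)`.  The scale/offset pair lives in a JSON
#'   sidecar (`<path>.json`) rather than TIFF tags, so any 16-bit TIFF reader
#'   can decode the counts.  The default step of 0.01 K per count is
#'   deliberately finer than the camera's noise floor (NETD < 40 mK), so
#'   quantisation never dominates sensor noise.
#'
#' @param frame A [thermal_frame].
#' @param path Output file path (parent directory must exist).
#' @param format `"csv"` or `"tiff16"`.
#' @param scale,offset Quantisation for `tiff16`: degrees C per count and
#'   count-zero temperature.
#' @param sidecar For `tiff16`, write the JSON sidecar next to the file
#'   (disable when scale/offset are recorded in a recording manifest
#'   instead).
#' @return `path`, invisibly.
#' @seealso [read_frame()]
#' @export
write_frame <- function(frame, path, format = c("csv", "tiff16"),
                        scale = 0.01, offset = 0, sidecar = TRUE) {
  stopifnot(inherits(frame, "thermal_frame"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop_tl("parent directory does not exist: ", dirname(path))
  if (format == "csv") {
    data.table::fwrite(as.data.frame(frame$temps), path,
                       col.names = FALSE, row.names = FALSE)
  } else {
    if (scale <= 0) stop_tl("`scale` must be positive")
    counts <- round((frame$temps - offset) / scale)
    if (min(counts) < 0 || max(counts) > 65535)
      stop_tl(sprintf(
        "temperatures do not fit 16-bit counts with scale %g, offset %g (counts %g..%g)",
        scale, offset, min(counts), max(counts)))
    tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
    if (isTRUE(sidecar)) {
      jsonlite::write_json(
        list(schema = "thermal-frame-sidecar", version = 1L,
             scale = scale, offset = offset,
             timestamp = frame$timestamp, index = frame$index),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(path)
}

#' Read a thermal frame from disk
#'
#' Inverse of [write_frame()].  For `tiff16`, scale and offset are taken
#' from the JSON sidecar written by [write_frame()] unless supplied
#' explicitly (as [load_recording()] does from the manifest).  A written
#' then re-read frame reproduces temperatures exactly for `csv` and to
#' within half a quantisation step (`scale / 2`) for `tiff16`.
#'
#' @param path File path.
#' @param format `"csv"` or `"tiff16"`.
#' @param scale,offset Quantisation for `tiff16`; `NULL` means read the
#'   sidecar (`<path>.json`), which must then exist.
#' @param timestamp,index Frame metadata; for `tiff16` the sidecar values
#'   take precedence when present.
#' @return A [thermal_frame].
#' @export
read_frame <- function(path, format = c("csv", "tiff16"),
                       scale = NULL, offset = NULL,
                       timestamp = 0, index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_tl("frame file does not exist: ", path)
  if (format == "csv") {
    dt <- tryCatch(
      suppressWarnings(data.table::fread(path, header = FALSE, sep = ",",
                                         colClasses = "numeric",
                                         showProgress = FALSE)),
      error = function(e) stop_tl("unparseable CSV raster ", path, ": ",
                                  conditionMessage(e)))
    m <- as.matrix(dt)
    if (!is.numeric(m) || anyNA(m))
      stop_tl("unparseable (non-numeric or missing) cell in ", path)
    dimnames(m) <- NULL
    return(thermal_frame(m, timestamp = timestamp, index = index))
  }
  if (is.null(scale) || is.null(offset)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop_tl("tiff16 frame requires a scale/offset sidecar; missing: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    scale <- scale %||% meta$scale
    offset <- offset %||% meta$offset
    timestamp <- meta$timestamp %||% timestamp
    index <- meta$index %||% index
  }
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2L) stop_tl("expected a single-channel TIFF: ", path)
  thermal_frame(img * scale + offset,
                timestamp = timestamp, index = as.integer(index))
}

# Manifest schema (JSON, one file per recording directory):
#   schema: "thermal-recording-manifest", version: 1
#   subject_id, position, rate_hz, room_temp_c, humidity_pct
#   frame_format: "csv" | "tiff16"; scale, offset (tiff16 only)
#   frames: ordered array of frame file paths relative to the manifest
MANIFEST_SCHEMA <- "thermal-recording-manifest"

#' Write a recording (frames + JSON manifest) to a directory
#'
#' Frames are written as `frame_0001.<ext>` ... in order, and a
#' `manifest.json` records the acquisition rate, imaging position,
#' environment, subject id and (for `tiff16`) the shared scale/offset.
#'
#' @param recording A [thermal_recording].
#' @param dir Output directory (created if absent).
#' @param format,scale,offset Passed to [write_frame()]; one scale/offset
#'   pair is shared by all frames and stored in the manifest, not in
#'   per-frame sidecars.
#' @return The manifest path, invisibly.
#' @export
write_recording <- function(recording, dir, format = c("csv", "tiff16"),
                            scale = 0.01, offset = 0) {
  stopifnot(inherits(recording, "thermal_recording"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") "csv" else "tif"
  rel <- sprintf("frame_%04d.%s", seq_along(recording$frames), ext)
  for (i in seq_along(recording$frames)) {
    write_frame(recording$frames[[i]], file.path(dir, rel[i]), format,
                scale = scale, offset = offset, sidecar = FALSE)
  }
  manifest <- list(
    schema = MANIFEST_SCHEMA, version = 1L,
    subject_id = recording$subject_id,
    position = recording$position,
    rate_hz = recording$rate_hz,
    room_temp_c = recording$room_temp_c,
    humidity_pct = recording$humidity_pct,
    frame_format = format,
    frames = rel
  )
  if (format == "tiff16") {
    manifest$scale <- scale
    manifest$offset <- offset
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(mpath)
}

#' Load a recording from its manifest
#'
#' Reads the JSON manifest written by [write_recording()], loads every
#' listed frame in manifest order, validates that all frames share one
#' image shape, and reconstructs timestamps as `(index - 1) / rate_hz`.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @return A [thermal_recording].
#' @export
load_recording <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop_tl("manifest does not exist: ", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(m$schema, MANIFEST_SCHEMA))
    stop_tl("not a recording manifest (schema '", m$schema %||% "?", "')")
  if (length(m$frames) == 0L)
    stop_tl("manifest lists no frames: ", manifest_path)
  if (!m$position %in% IMAGING_POSITIONS)
    stop_tl("unknown imaging position label: '", m$position, "'")
  base <- dirname(manifest_path)
  paths <- file.path(base, m$frames)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_tl("missing frame file(s): ", paste(missing, collapse = ", "))
  fmt <- m$frame_format
  frames <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    frames[[i]] <- read_frame(paths[i], fmt,
                              scale = m$scale, offset = m$offset,
                              timestamp = (i - 1) / m$rate_hz, index = i)
  }
  shp <- vapply(frames, function(f) dim(f$temps), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop_tl("frames in ", base, " do not share one image shape")
  thermal_recording(frames, rate_hz = m$rate_hz, position = m$position,
                    room_temp_c = m$room_temp_c %||% NA_real_,
                    humidity_pct = m$humidity_pct %||% NA_real_,
                    subject_id = m$subject_id %||% "")
}
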