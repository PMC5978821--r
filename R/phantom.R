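#' Thermal leg-pair phantom parameters
#'
#' Describes the synthetic imaging subject: two vertical lower-limb
#' silhouettes placed symmetrically about the image's vertical midline, a
#' linear proximodistal skin-temperature gradient (warmest proximally,
#' cooling towards the ankle, as observed clinically), an optional focal
#' Gaussian hotspot on one leg, per-pixel Gaussian sensor noise at the
#' camera's NETD scale, and an optional fraction of motion-corrupted frames.
#'
#' Leg geometry is specified as fractions of the image so the same phantom
#' scales to any resolution.  Each leg is a vertical band around its axis
#' column whose half-width tapers linearly from `halfwidth_top_frac` to
#' `halfwidth_bottom_frac`; the right-leg axis is the mirror image of the
#' left-leg axis, so with zero noise and no hotspot the two legs are exact
#' mirror images.
#'
#' Motion corruption emulates a child moving during acquisition: the whole
#' silhouette is translated sideways by `corrupt_shift_frac` of the image
#' width and the frame acquires a global temperature bias of
#' `corrupt_bias_c`.  Corrupted frames are distinguishable only by content;
#' frame selection must find them.
#'
#' @param image_shape `c(rows, cols)`; default 480 x 640, the study camera's
#'   resolution.
#' @param proximal_temp,distal_temp Skin temperature (degrees C) at the top
#'   and bottom of the leg; `proximal_temp >= distal_temp`.
#' @param background_temp Background (room surfaces) temperature, degrees C.
#' @param leg_axis_frac Left-leg axis column as a fraction of image width.
#' @param leg_top_frac,leg_bottom_frac Vertical leg extent as row fractions.
#' @param halfwidth_top_frac,halfwidth_bottom_frac Leg half-width at top and
#'   bottom, as fractions of image width.
#' @param hotspot `NULL`, or `list(leg, center = c(row, col), sigma,
#'   amplitude)`: an additive isotropic Gaussian of peak `amplitude`
#'   (degrees C, >= 0) and standard deviation `sigma` (pixels), applied only
#'   to pixels of the named leg.
#' @param noise_sd Per-pixel Gaussian sensor noise SD in degrees C; default
#'   0.04, the study camera's NETD ceiling.
#' @param corrupt_frac Fraction of frames of a recording to corrupt
#'   (`0 <= corrupt_frac < 1`; the count is rounded down).
#' @param corrupt_shift_frac,corrupt_bias_c Magnitude of the corruption:
#'   sideways translation (fraction of width) and global bias (degrees C).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_shape = c(480L, 640L),
                           proximal_temp = 33.5, distal_temp = 30.5,
                           background_temp = 23,
                           leg_axis_frac = 0.32,
                           leg_top_frac = 0.06, leg_bottom_frac = 0.96,
                           halfwidth_top_frac = 0.085,
                           halfwidth_bottom_frac = 0.05,
                           hotspot = NULL,
                           noise_sd = 0.04,
                           corrupt_frac = 0,
                           corrupt_shift_frac = 0.15,
                           corrupt_bias_c = 1.5) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 8L))
    stop_tl("`image_shape` must be c(rows, cols), each >= 8")
  if (proximal_temp < distal_temp)
    stop_tl("`proximal_temp` must be >= `distal_temp` (proximodistal gradient)")
  if (noise_sd < 0) stop_tl("`noise_sd` must be >= 0")
  if (corrupt_frac < 0 || corrupt_frac >= 1)
    stop_tl("`corrupt_frac` must satisfy 0 <= corrupt_frac < 1")
  if (leg_top_frac >= leg_bottom_frac)
    stop_tl("`leg_top_frac` must be < `leg_bottom_frac`")
  if (!is.null(hotspot)) {
    stopifnot(is.list(hotspot))
    hotspot$leg <- match.arg(hotspot$leg, c("left", "right"))
    if (length(hotspot$center) != 2L)
      stop_tl("hotspot `center` must be c(row, col)")
    if (hotspot$center[1] < 1 || hotspot$center[1] > image_shape[1] ||
        hotspot$center[2] < 1 || hotspot$center[2] > image_shape[2])
      stop_tl("hotspot center lies outside the image")
    if (hotspot$amplitude < 0) stop_tl("hotspot `amplitude` must be >= 0")
    if (hotspot$sigma <= 0) stop_tl("hotspot `sigma` must be > 0")
  }
  structure(
    list(image_shape = image_shape,
         proximal_temp = proximal_temp, distal_temp = distal_temp,
         background_temp = background_temp,
         leg_axis_frac = leg_axis_frac,
         leg_top_frac = leg_top_frac, leg_bottom_frac = leg_bottom_frac,
         halfwidth_top_frac = halfwidth_top_frac,
         halfwidth_bottom_frac = halfwidth_bottom_frac,
         hotspot = hotspot, noise_sd = noise_sd,
         corrupt_frac = corrupt_frac,
         corrupt_shift_frac = corrupt_shift_frac,
         corrupt_bias_c = corrupt_bias_c),
    class = "phantom_params"
  )
}

# Geometry of one phantom: integer axis columns, leg row extent and
# per-row half-widths.  The right axis is the exact mirror of the left,
# so leg masks are mirror-symmetric about the vertical midline.
phantom_geometry <- function(params) {
  R <- params$image_shape[1]; C <- params$image_shape[2]
  axis_left <- as.integer(round(params$leg_axis_frac * C))
  axis_right <- C + 1L - axis_left
  top <- max(1L, as.integer(round(params$leg_top_frac * R)))
  bottom <- min(R, as.integer(round(params$leg_bottom_frac * R)))
  rows <- top:bottom
  frac <- (rows - top) / (bottom - top)
  hw <- params$halfwidth_top_frac * C +
    frac * (params$halfwidth_bottom_frac - params$halfwidth_top_frac) * C
  list(axis_left = axis_left, axis_right = axis_right,
       top = top, bottom = bottom, halfwidth = hw)
}

# Deterministic base image (no noise); shift translates the silhouette
# sideways (columns) by `shift` pixels — used for motion corruption.
phantom_base <- function(params, shift = 0L) {
  R <- params$image_shape[1]; C <- params$image_shape[2]
  g <- phantom_geometry(params)
  m <- matrix(params$background_temp, R, C)
  rows <- g$top:g$bottom
  grad <- params$proximal_temp +
    (rows - g$top) / (g$bottom - g$top) *
      (params$distal_temp - params$proximal_temp)
  cols <- matrix(seq_len(C), nrow = length(rows), ncol = C, byrow = TRUE)
  hw <- g$halfwidth
  mask_l <- abs(cols - (g$axis_left + shift)) <= hw
  mask_r <- abs(cols - (g$axis_right + shift)) <= hw
  sub <- m[rows, , drop = FALSE]
  gradm <- matrix(grad, nrow = length(rows), ncol = C)
  sub[mask_l] <- gradm[mask_l]
  sub[mask_r] <- gradm[mask_r]
  hs <- params$hotspot
  if (!is.null(hs) && hs$amplitude > 0) {
    mask_hs <- if (hs$leg == "left") mask_l else mask_r
    ri <- matrix(rows, nrow = length(rows), ncol = C)
    bump <- hs$amplitude *
      exp(-((ri - hs$center[1])^2 + (cols - (hs$center[2] + shift))^2) /
            (2 * hs$sigma^2))
    sub[mask_hs] <- sub[mask_hs] + bump[mask_hs]
  }
  m[rows, ] <- sub
  m
}

#' Generate one phantom frame
#'
#' Renders the deterministic phantom of [phantom_params()] and adds
#' independent per-pixel Gaussian sensor noise of SD `noise_sd`.  With
#' `noise_sd = 0` and no hotspot the left and right leg pixel sets are exact
#' mirror images about the vertical midline, and temperature along a leg
#' axis is non-increasing from top to bottom.
#'
#' @param params A [phantom_params()].
#' @param timestamp,index Frame metadata.
#' @param seed Optional integer seed (the caller's RNG state is preserved);
#'   `NULL` draws from the current RNG stream.
#' @return A [thermal_frame].
#' @export
generate_phantom_frame <- function(params, timestamp = 0, index = 1L,
                                   seed = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  base <- phantom_base(params)
  with_seed_or_current(seed, {
    if (params$noise_sd > 0)
      base <- base + matrix(rnorm(length(base), sd = params$noise_sd),
                            nrow(base), ncol(base))
    thermal_frame(base, timestamp = timestamp, index = index)
  })
}

#' Generate a phantom video recording
#'
#' Produces `floor(duration_s * rate_hz)` frames of the phantom (the study
#' protocol: 20 s at 30 Hz, i.e. 600 frames per recording).  A seeded draw
#' picks `floor(corrupt_frac * n)` frames to corrupt with the documented
#' motion perturbation (silhouette translation plus temperature bias).  The
#' ground-truth corrupted indices are attached as
#' `attr(recording, "corrupted")` purely so simulations can be validated;
#' nothing in the analysis pipeline reads the attribute — corrupted frames
#' are detectable only through their content.
#'
#' @param params A [phantom_params()].
#' @param duration_s,rate_hz Recording length (s) and frame rate (Hz), both
#'   positive; defaults follow the study protocol.
#' @param position Imaging position label for the recording.
#' @param seed Optional integer seed; a fixed seed yields a bit-identical
#'   recording.
#' @param subject_id,room_temp_c,humidity_pct Recording metadata.
#' @return A [thermal_recording] with the `"corrupted"` attribute described
#'   above.
#' @export
generate_recording <- function(params, duration_s = 20, rate_hz = 30,
                               position = "anterior_sitting", seed = NULL,
                               subject_id = "phantom",
                               room_temp_c = 23, humidity_pct = 45) {
  stopifnot(inherits(params, "phantom_params"))
  if (duration_s <= 0) stop_tl("`duration_s` must be > 0")
  if (rate_hz <= 0) stop_tl("`rate_hz` must be > 0")
  n <- as.integer(floor(duration_s * rate_hz))
  if (n < 1L) stop_tl("duration x rate yields no frames")
  clean <- phantom_base(params)
  R <- nrow(clean); C <- ncol(clean)
  with_seed_or_current(seed, {
    n_bad <- as.integer(floor(params$corrupt_frac * n))
    bad <- if (n_bad > 0) sort(sample.int(n, n_bad)) else integer(0)
    if (n_bad > 0) {
      shift <- as.integer(round(params$corrupt_shift_frac * C))
      corrupt <- phantom_base(params, shift = shift) + params$corrupt_bias_c
    }
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      base <- if (i %in% bad) corrupt else clean
      if (params$noise_sd > 0)
        base <- base + matrix(rnorm(R * C, sd = params$noise_sd), R, C)
      frames[[i]] <- thermal_frame(base, timestamp = (i - 1) / rate_hz,
                                   index = i)
    }
    rec <- thermal_recording(frames, rate_hz = rate_hz, position = position,
                             room_temp_c = room_temp_c,
                             humidity_pct = humidity_pct,
                             subject_id = subject_id)
    attr(rec, "corrupted") <- bad
    rec
  })
}

#' Default ROI placement on a phantom leg
#'
#' Places the five anatomical ROIs (hip, upper knee, knee, lower knee,
#' ankle) as rectangles along the named leg of the phantom, each fully
#' inside the silhouette, sized from the phantom geometry.  Row bands are
#' fixed fractions of the leg's vertical extent; each rectangle is centred
#' on the leg axis with a width safely inside the local half-width.
#'
#' @param params A [phantom_params()].
#' @param leg `"left"` or `"right"`.
#' @return Named list of [roi()] objects, one per label.
#' @export
phantom_rois <- function(params, leg = c("left", "right")) {
  stopifnot(inherits(params, "phantom_params"))
  leg <- match.arg(leg)
  g <- phantom_geometry(params)
  axis <- if (leg == "left") g$axis_left else g$axis_right
  span <- g$bottom - g$top
  bands <- list(
    hip        = c(0.02, 0.14),
    upper_knee = c(0.30, 0.42),
    knee       = c(0.46, 0.56),
    lower_knee = c(0.60, 0.74),
    ankle      = c(0.84, 0.94)
  )
  out <- lapply(names(bands), function(lab) {
    b <- bands[[lab]]
    top <- g$top + as.integer(round(b[1] * span))
    bottom <- g$top + as.integer(round(b[2] * span))
    # narrowest half-width over the band (legs taper distally)
    hw_min <- min(g$halfwidth[(top - g$top + 1L):(bottom - g$top + 1L)])
    half <- max(1L, as.integer(floor(0.7 * hw_min)))
    roi(lab, leg, top = top, left = axis - half,
        bottom = bottom, right = axis + half)
  })
  setNames(out, names(bands))
}
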