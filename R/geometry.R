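#' Build the vertical-arc detector array geometry
#'
#' Constructs the transducer array used for photoacoustic detection: a
#' curve-linear arc of square piezo elements stacked vertically, all element
#' faces pointing at the arc centre.  The coordinate system is right-handed
#' with `z` the rotation axis (up positive) and the origin at the intersection
#' of the rotation axis with the plane of the array's centre element; the arc
#' lies in the `x`-`z` plane at azimuth 0 and is centred on `z = 0`, so with an
#' even element count the two centremost elements straddle the scan plane by
#' half a pitch.
#'
#' @param arc_radius Arc radius in mm: distance of every element centre from
#'   the origin (default 65).
#' @param n_elements Number of elements (default 96).
#' @param element_width Element width (lateral, in-plane) in mm (default 1.3).
#' @param element_height Element height along the arc in mm (default 1.3).
#' @param inter_element_gap Gap between neighbouring elements along the arc in
#'   mm (default 0.1); the angular pitch is
#'   `(element_height + inter_element_gap) / arc_radius` radians.
#' @param center_frequency Transducer centre frequency in MHz (default 6).
#' @param fractional_bandwidth Fractional bandwidth at -6 dB (default 0.55).
#'
#' @return An object of class `detector_array` with derived fields
#'   `element_positions` (n x 3 matrix, mm) and `element_normals`
#'   (unit vectors pointing at the arc centre).
#' @export
#' @examples
#' arr <- detector_array()
#' mean(arr$element_positions[, 3])        # symmetric about the scan plane
#' range(sqrt(rowSums(arr$element_positions^2)))  # all exactly at 65 mm
detector_array <- function(arc_radius = 65, n_elements = 96,
                           element_width = 1.3, element_height = 1.3,
                           inter_element_gap = 0.1,
                           center_frequency = 6,
                           fractional_bandwidth = 0.55) {
  if (!is.numeric(arc_radius) || arc_radius <= 0)
    stop("invalid geometry: 'arc_radius' must be positive", call. = FALSE)
  if (!is.numeric(n_elements) || n_elements < 1 || n_elements != round(n_elements))
    stop("invalid geometry: 'n_elements' must be a positive integer", call. = FALSE)
  if (element_width <= 0 || element_height <= 0)
    stop("invalid geometry: element dimensions must be positive", call. = FALSE)
  if (inter_element_gap < 0)
    stop("invalid geometry: 'inter_element_gap' must be non-negative", call. = FALSE)

  pitch_rad <- (element_height + inter_element_gap) / arc_radius
  # elevation angles centred on the scan plane
  idx <- seq_len(n_elements) - (n_elements + 1) / 2
  alpha <- idx * pitch_rad
  pos <- cbind(arc_radius * cos(alpha), 0, arc_radius * sin(alpha))
  colnames(pos) <- c("x", "y", "z")
  nrm <- -pos / arc_radius

  structure(list(
    arc_radius = arc_radius,
    n_elements = as.integer(n_elements),
    element_width = element_width,
    element_height = element_height,
    inter_element_gap = inter_element_gap,
    center_frequency = center_frequency,
    fractional_bandwidth = fractional_bandwidth,
    angular_pitch_rad = pitch_rad,
    element_elevation_rad = alpha,
    element_positions = pos,
    element_normals = nrm
  ), class = "detector_array")
}

#' @export
print.detector_array <- function(x, ...) {
  cat(sprintf(
    "<detector_array> %d elements, arc radius %g mm, span %.1f deg\n",
    x$n_elements, x$arc_radius,
    (x$n_elements - 1) * x$angular_pitch_rad * 180 / pi))
  cat(sprintf("  element %g x %g mm, gap %g mm; %g MHz centre, %g fractional bandwidth (-6 dB)\n",
              x$element_width, x$element_height, x$inter_element_gap,
              x$center_frequency, x$fractional_bandwidth))
  invisible(x)
}

#' Perturb an array geometry to emulate manufacturing tolerances
#'
#' Returns a copy of `array` whose element positions are perturbed, while the
#' nominal fields are left untouched.  Reconstructing with the *nominal*
#' geometry from data simulated with a *perturbed* geometry reproduces the
#' artifacts of uncompensated hardware tolerances (e.g. the dual-peak
#' elongation of targets along the rotation axis).
#'
#' @param array A [detector_array()].
#' @param radius_error Uniform radial offset in mm added to every element's
#'   distance from the origin (arc centred as mounted).
#' @param curvature_error Error in the arc's radius of curvature in mm, with
#'   the centre element kept at its nominal stand-off: the arc's focal point
#'   slides off the rotation axis, so off-plane elements acquire elevation-odd
#'   range errors.
#' @param element_jitter Standard deviation in mm of independent Gaussian
#'   radial errors per element (requires a prior `set.seed()` call for
#'   reproducibility).
#' @return A `detector_array` with perturbed `element_positions`.
#' @export
perturb_array <- function(array, radius_error = 0, curvature_error = 0,
                          element_jitter = 0) {
  stopifnot(inherits(array, "detector_array"))
  R <- array$arc_radius
  alpha <- array$element_elevation_rad
  r_eff <- rep(R + radius_error, array$n_elements)
  pos <- cbind(r_eff * cos(alpha), 0, r_eff * sin(alpha))
  if (curvature_error != 0) {
    # arc of curvature radius R + d whose centre element stays at stand-off R:
    # curvature centre at x = -d on the array axis
    Rc <- R + curvature_error
    pos <- cbind(Rc * cos(alpha * R / Rc) - curvature_error, 0,
                 Rc * sin(alpha * R / Rc))
    pos[, 1] <- pos[, 1] + radius_error * cos(alpha)
    pos[, 3] <- pos[, 3] + radius_error * sin(alpha)
  }
  if (element_jitter > 0) {
    dj <- stats::rnorm(array$n_elements, 0, element_jitter)
    pos <- pos + dj * cbind(cos(alpha), 0, sin(alpha))
  }
  colnames(pos) <- c("x", "y", "z")
  array$element_positions <- pos
  array$element_normals <- -pos / sqrt(rowSums(pos^2))
  array
}

#' Data-acquisition configuration
#'
#' @param sampling_rate Sampling rate in MHz (default 40).
#' @param samples_per_channel Samples recorded per channel per pulse
#'   (default 4096, hardware maximum 4096).
#' @param gain_db Receive gain in dB, hardware range 46 to 91 (default 46).
#' @param prf Laser pulse repetition frequency in Hz (default 10).
#' @param hardware_lowpass Anti-aliasing low-pass corner in MHz (default 10).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate = 40, samples_per_channel = 4096,
                               gain_db = 46, prf = 10, hardware_lowpass = 10) {
  if (samples_per_channel > 4096 || samples_per_channel < 1)
    stop("'samples_per_channel' must be in 1..4096", call. = FALSE)
  if (gain_db < 46 || gain_db > 91)
    stop("'gain_db' outside the hardware range [46, 91] dB", call. = FALSE)
  if (sampling_rate <= 0 || prf <= 0)
    stop("'sampling_rate' and 'prf' must be positive", call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 samples_per_channel = as.integer(samples_per_channel),
                 gain_db = gain_db, prf = prf,
                 hardware_lowpass = hardware_lowpass),
            class = "acquisition_config")
}

#' Rotation schedule of a scan
#'
#' The sample rotates continuously while the laser fires at the pulse
#' repetition frequency; one photoacoustic frame is captured per pulse, so a
#' full-revolution scan at the maximum stage speed of 10 deg/s takes 36 s and
#' yields 360 frames at 10 Hz.
#'
#' @param speed Rotation speed in deg/s; the stage maximum is 10.
#' @param sweep Total swept angle in degrees (default 360).
#' @param prf Pulse repetition frequency in Hz (default 10).
#' @return An object of class `rotation_schedule` with fields `duration` (s),
#'   `n_frames`, `frame_timestamps` (s) and `nominal_angles` (deg).
#' @export
#' @examples
#' rotation_schedule(10, 360, 10)$duration   # 36 s
#' rotation_schedule(10, 360, 10)$n_frames   # 360 frames
rotation_schedule <- function(speed = 10, sweep = 360, prf = 10) {
  if (speed <= 0 || sweep <= 0 || prf <= 0)
    stop("'speed', 'sweep' and 'prf' must be positive", call. = FALSE)
  if (speed > 10)
    stop("rotation speed exceeds the 10 deg/s hardware maximum", call. = FALSE)
  duration <- sweep / speed
  n_frames <- floor(duration * prf)
  ts <- (seq_len(n_frames) - 1) / prf
  structure(list(speed = speed, sweep = sweep, prf = prf,
                 duration = duration, n_frames = as.integer(n_frames),
                 frame_timestamps = ts,
                 nominal_angles = speed * ts),
            class = "rotation_schedule")
}

#' Camera model for the fluorescence imaging channel
#'
#' @param fov Field of view in mm, length-2 (default `c(40, 40)`), focused at
#'   the rotation axis.
#' @param pixels Sensor size in pixels, length-2 (default `c(2048, 2040)`;
#'   2x2-binned acquisition `c(1024, 1020)` is also used in practice).
#' @param exposure Exposure time in ms (default 25).
#' @param read_noise Read noise in electrons RMS (default 2.5).
#' @param quantum_efficiency Peak quantum efficiency, dimensionless
#'   (default 0.45).
#' @return An object of class `camera_model`; `pixel_pitch` (mm) is derived
#'   per axis as `fov / pixels`.
#' @export
camera_model <- function(fov = c(40, 40), pixels = c(2048, 2040),
                         exposure = 25, read_noise = 2.5,
                         quantum_efficiency = 0.45) {
  stopifnot(length(fov) == 2, length(pixels) == 2)
  if (exposure <= 0) stop("'exposure' must be positive", call. = FALSE)
  if (any(pixels < 1) || any(fov <= 0)) stop("invalid camera geometry", call. = FALSE)
  structure(list(fov = as.numeric(fov), pixels = as.integer(pixels),
                 pixel_pitch = as.numeric(fov) / as.numeric(pixels),
                 exposure = exposure, read_noise = read_noise,
                 quantum_efficiency = quantum_efficiency),
            class = "camera_model")
}

#' Coupling-medium description
#'
#' @param temperature Water temperature in degrees Celsius (default 25).
#' @param sound_speed Optional explicit speed of sound in m/s; when `NULL` it
#'   is derived from `temperature` by [speed_of_sound()].
#' @param water_mu_a Optical absorption of the coupling water in 1/cm, either a
#'   scalar or a `data.frame` with columns `wavelength` (nm) and `mu_a`.
#' @return An object of class `medium`.
#' @export
medium <- function(temperature = 25, sound_speed = NULL, water_mu_a = 0) {
  if (is.data.frame(water_mu_a)) {
    stopifnot(all(c("wavelength", "mu_a") %in% names(water_mu_a)))
    if (any(water_mu_a$mu_a < 0)) stop("'water_mu_a' must be non-negative", call. = FALSE)
  } else if (any(water_mu_a < 0)) {
    stop("'water_mu_a' must be non-negative", call. = FALSE)
  }
  if (!is.null(sound_speed) && sound_speed <= 0)
    stop("'sound_speed' must be positive", call. = FALSE)
  structure(list(temperature = temperature, sound_speed = sound_speed,
                 water_mu_a = water_mu_a),
            class = "medium")
}

#' Speed of sound in the coupling water
#'
#' Returns the explicit `sound_speed` override when the medium carries one,
#' otherwise evaluates Marczak's (1997) fifth-order pure-water polynomial at
#' the medium temperature (validity restricted here to 0-60 degrees C).
#'
#' @param medium A [medium()].
#' @return Speed of sound in m/s.
#' @export
#' @examples
#' speed_of_sound(medium(25))                      # ~1497 m/s
#' speed_of_sound(medium(sound_speed = 1500))      # override passthrough
speed_of_sound <- function(medium) {
  stopifnot(inherits(medium, "medium"))
  if (!is.null(medium$sound_speed)) return(medium$sound_speed)
  t <- medium$temperature
  if (t < 0 || t > 60)
    stop("temperature outside the 0-60 degC validity range", call. = FALSE)
  1.402385e3 + 5.038813 * t - 5.799136e-2 * t^2 + 3.287156e-4 * t^3 -
    1.398845e-6 * t^4 + 2.787860e-9 * t^5
}

#' Water absorption at a wavelength
#'
#' Looks up (with linear interpolation) the medium's tabulated water
#' absorption, or returns the scalar value.
#'
#' @param medium A [medium()].
#' @param wavelength Wavelength in nm.
#' @return Absorption coefficient in 1/cm.
#' @export
water_absorption <- function(medium, wavelength) {
  wa <- medium$water_mu_a
  if (is.data.frame(wa)) {
    stats::approx(wa$wavelength, wa$mu_a, xout = wavelength, rule = 2)$y
  } else {
    rep(wa, length(wavelength))
  }
}
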