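#' Analytic pressure trace of a photoacoustic source at a detector point
#'
#' Closed-form forward model for a uniformly heated spherical absorber: the
#' received pressure is a bipolar N-shaped pulse centred at the acoustic
#' arrival time `t0 = d / c` with support `t0 +/- a / c` (where `a` is the
#' sphere radius and `d` the source-detector distance), amplitude proportional
#' to `mu_a * scale * a / d`, and zero time integral.  Filament and cuvette
#' absorbers are decomposed into sub-resolution spheres by
#' [discretize_absorber()] and their contributions superposed.
#'
#' @param absorber An [absorbers] object.
#' @param element_position Receive point, 3-vector in mm.
#' @param time_grid Times in microseconds at which to evaluate the trace; must
#'   cover the acoustic arrival window.
#' @param medium A [medium()] (provides the speed of sound).
#' @param wavelength Wavelength in nm for spectral absorbers.
#' @return Numeric vector of pressures (arbitrary units) on `time_grid`.
#' @export
#' @examples
#' ab <- sphere_absorber(c(0, 0, 0), radius = 0.4, mu_a = 1)
#' tg <- seq(42, 45, by = 1 / 40)  # 40 MHz sampling
#' p <- forward_pressure(ab, c(65, 0, 0), tg, medium(sound_speed = 1500))
#' tg[which.max(abs(p))]  # arrival near 65 mm / 1.5 mm/us = 43.33 us
forward_pressure <- function(absorber, element_position, time_grid,
                             medium = paftom::medium(), wavelength = NA) {
  stopifnot(inherits(absorber, "absorber"), length(element_position) == 3)
  c_mm_us <- speed_of_sound(medium) / 1000  # m/s -> mm/us
  sp <- discretize_absorber(absorber, wavelength)
  d <- sqrt((sp$centers[, 1] - element_position[1])^2 +
            (sp$centers[, 2] - element_position[2])^2 +
            (sp$centers[, 3] - element_position[3])^2)
  if (any(d <= sp$radius))
    stop("element position lies inside the absorber", call. = FALSE)
  tau <- sp$radius / c_mm_us
  t0 <- d / c_mm_us
  out <- numeric(length(time_grid))
  for (k in seq_along(d)) {
    u <- (t0[k] - time_grid) / tau
    inside <- abs(u) <= 1
    out[inside] <- out[inside] +
      (sp$mu_a * sp$scale * sp$radius / d[k]) * u[inside]
  }
  out
}

#' Transducer band-pass response
#'
#' Zero-phase Gaussian band-pass amplitude response centred on the array's
#' centre frequency; the -6 dB full width equals
#' `fractional_bandwidth * center_frequency`.
#'
#' @param f Frequencies in MHz (may be negative; the response is even).
#' @param center_frequency Centre frequency, MHz.
#' @param fractional_bandwidth Fractional -6 dB bandwidth.
#' @return Amplitude response in `[0, 1]`.
#' @export
bandpass_response <- function(f, center_frequency = 6,
                              fractional_bandwidth = 0.55) {
  half_bw <- center_frequency * fractional_bandwidth / 2
  # Gaussian whose amplitude falls to 10^(-6/20) at +/- half_bw
  sigma <- half_bw / sqrt(2 * log(10^(6 / 20)))
  exp(-(abs(f) - center_frequency)^2 / (2 * sigma^2))
}

#' Hardware anti-aliasing low-pass amplitude response
#'
#' Fourth-order Butterworth magnitude, applied zero-phase.
#'
#' @param f Frequencies in MHz.
#' @param cutoff -3 dB corner in MHz; `Inf` disables the stage.
#' @return Amplitude response.
#' @export
lowpass_response <- function(f, cutoff = 10) {
  if (!is.finite(cutoff)) return(rep(1, length(f)))
  1 / sqrt(1 + (abs(f) / cutoff)^8)
}

# zero-phase application of the combined instrument amplitude response to
# each column of a (n_samp x n_el [x n_frames]) trace block sampled at fs MHz
.apply_response <- function(traces, fs, array, hardware_lowpass = 10) {
  dims <- dim(traces)
  n <- dims[1]
  f <- (seq_len(n) - 1) / n * fs
  f <- ifelse(f > fs / 2, f - fs, f)
  H <- bandpass_response(f, array$center_frequency, array$fractional_bandwidth) *
    lowpass_response(f, hardware_lowpass)
  m <- matrix(traces, nrow = n)
  out <- Re(stats::mvfft(stats::mvfft(m) * H, inverse = TRUE)) / n
  array(out, dim = dims)
}

#' Apply the receive-chain instrument effects to ideal traces
#'
#' Applies, in order: (i) the zero-phase Gaussian transducer band-pass
#' ([bandpass_response()]), (ii) the hardware anti-aliasing low-pass
#' ([lowpass_response()]), (iii) the linear receive gain
#' `10^(gain_db / 20)`, and (iv) additive white Gaussian noise.  Element
#' directivity (finite-aperture sub-element averaging) is part of the forward
#' trace synthesis in [simulate_scan()], which needs the source-detector
#' geometry.
#'
#' @param traces Traces sampled at `acq$sampling_rate`: a matrix
#'   (samples x elements) or 3D array (samples x elements x frames).
#' @param array A [detector_array()].
#' @param acq An [acquisition_config()].
#' @param noise_sigma Standard deviation of the additive output-referred
#'   noise (same units as the gained signal).
#' @param seed Optional RNG seed for reproducible noise.
#' @return Traces of the same shape.
#' @export
apply_instrument <- function(traces, array, acq, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(array, "detector_array"), inherits(acq, "acquisition_config"))
  dims <- dim(traces)
  if (is.null(dims)) { traces <- matrix(traces, ncol = 1); dims <- dim(traces) }
  out <- .apply_response(traces, acq$sampling_rate, array, acq$hardware_lowpass)
  out <- out * 10^(acq$gain_db / 20)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    out <- out + stats::rnorm(length(out), 0, noise_sigma)
  }
  out
}

# sub-element receive points for every element at azimuth 0:
# a flat n x n grid over the element face (lateral = y, tangential = along arc)
.sub_points <- function(array, n_sub) {
  pos <- array$element_positions
  alpha <- atan2(pos[, 3], pos[, 1])
  if (n_sub == 1) {
    return(list(pos = pos, el = seq_len(array$n_elements) - 1L))
  }
  off <- (seq_len(n_sub) - (n_sub + 1) / 2) / n_sub
  u <- rep(off * array$element_width, each = n_sub)    # lateral (y)
  v <- rep(off * array$element_height, times = n_sub)  # tangential
  nel <- array$n_elements
  ns <- n_sub * n_sub
  # tangential unit vector of element e: (-sin a, 0, cos a)
  px <- rep(pos[, 1], each = ns) + rep(-sin(alpha), each = ns) * rep(v, nel)
  py <- rep(pos[, 2], each = ns) + rep(u, nel)
  pz <- rep(pos[, 3], each = ns) + rep(cos(alpha), each = ns) * rep(v, nel)
  list(pos = cbind(px, py, pz), el = rep(seq_len(nel) - 1L, each = ns))
}

.rotate_z <- function(xyz, theta_rad) {
  ca <- cos(theta_rad); sa <- sin(theta_rad)
  cbind(ca * xyz[, 1] - sa * xyz[, 2],
        sa * xyz[, 1] + ca * xyz[, 2],
        xyz[, 3])
}

# collect all discretized spheres of a phantom at one wavelength
.phantom_spheres <- function(phantom, wavelength) {
  centers <- NULL; radius <- NULL; strength <- NULL
  for (ab in phantom$absorbers) {
    sp <- discretize_absorber(ab, wavelength)
    if (sp$mu_a <= 0) next
    centers <- rbind(centers, sp$centers)
    radius <- c(radius, rep(sp$radius, nrow(sp$centers)))
    strength <- c(strength,
                  rep(sp$mu_a * sp$scale * sp$radius *
                        phantom$scattering_attenuation, nrow(sp$centers)))
  }
  list(centers = centers, radius = radius, strength = strength)
}

#' Simulate a rotate-scan photoacoustic acquisition
#'
#' Full forward simulation: the phantom's absorbers are decomposed into
#' spherical sources, analytic N-wave traces are synthesised on a temporally
#' supersampled grid for every frame of the rotation schedule (averaging over
#' sub-element receive points to model the finite 1.3 mm aperture), the
#' transducer band-pass, hardware low-pass, receive gain and additive noise
#' are applied, and the result is decimated to the acquisition sampling rate.
#' Per-pulse laser energies are drawn around the nominal output energy, and a
#' motor angle log is emitted on its own clock, asynchronous with the frame
#' timestamps, as produced by the physical rotation stage.
#'
#' @param phantom A [phantom()].
#' @param array A [detector_array()] — the geometry assumed downstream.
#' @param acq An [acquisition_config()].
#' @param schedule A [rotation_schedule()].
#' @param wavelength Excitation wavelength in nm (default 800).
#' @param noise_sigma Output-referred white-noise standard deviation.
#' @param energy_jitter Relative per-pulse energy jitter (default 0.01).
#' @param nominal_energy Nominal pulse energy in mJ (default 80).
#' @param seed Optional seed; a fixed seed makes the scan bit-reproducible.
#' @param oversample Temporal supersampling factor for N-wave synthesis
#'   (default 4).
#' @param n_sub Sub-element grid order for directivity (default 5, i.e. 5x5
#'   receive points per element; 1 disables aperture averaging).
#' @param array_true Optional perturbed geometry (see [perturb_array()]) used
#'   for the *physical* wave propagation while `array` remains the nominal
#'   geometry recorded in the scan; emulates uncompensated manufacturing
#'   tolerances.
#' @param angles_deg Optional explicit per-frame angles overriding the
#'   schedule's nominal angles (the motor log is synthesised accordingly).
#' @return A `scan_data` object: `pa_frames` (samples x elements x frames
#'   array), `frame_timestamps` (s), `motor_log` (data.frame `time`, `angle`),
#'   `pulse_energies` (mJ), `wavelength`, `gain_db` and a config snapshot.
#' @export
simulate_scan <- function(phantom, array = detector_array(),
                          acq = acquisition_config(),
                          schedule = rotation_schedule(),
                          wavelength = 800, noise_sigma = 0,
                          energy_jitter = 0.01, nominal_energy = 80,
                          seed = NULL, oversample = 4, n_sub = 5,
                          array_true = NULL, angles_deg = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (!is.null(seed)) set.seed(seed)
  c_mm_us <- speed_of_sound(phantom$medium) / 1000
  geom <- if (is.null(array_true)) array else array_true
  sub <- .sub_points(geom, n_sub)
  sph <- .phantom_spheres(phantom, wavelength)
  n_frames <- schedule$n_frames
  angles <- if (is.null(angles_deg)) schedule$nominal_angles else angles_deg
  stopifnot(length(angles) == n_frames)
  fs_fine <- acq$sampling_rate * oversample
  n_fine <- acq$samples_per_channel * oversample
  frames <- array(0, dim = c(acq$samples_per_channel, array$n_elements, n_frames))
  energies <- nominal_energy * pmax(1e-3, 1 + energy_jitter *
                                      stats::rnorm(n_frames))
  keep <- seq(1, n_fine, by = oversample)
  gain_lin <- 10^(acq$gain_db / 20)
  noise_all <- if (noise_sigma > 0)
    stats::rnorm(length(frames), 0, noise_sigma) else NULL
  if (!is.null(sph$centers)) {
    for (f in seq_len(n_frames)) {
      subpos <- .rotate_z(sub$pos, -angles[f] * pi / 180)
      tr <- cpp_forward_frame(subpos, sub$el, sph$centers, sph$radius,
                              sph$strength, array$n_elements,
                              max(1L, n_sub)^2, n_fine, fs_fine, c_mm_us)
      tr <- .apply_response(tr, fs_fine, array, acq$hardware_lowpass)
      frames[, , f] <- tr[keep, ] * gain_lin * (energies[f] / nominal_energy)
    }
  }
  if (!is.null(noise_all)) frames <- frames + noise_all
  # asynchronous motor log: its own clock rate and phase, covering the scan
  motor_t <- seq(-0.35 + 0.0137, schedule$duration + 0.4, by = 1 / 7.3)
  motor_a <- schedule$speed * pmin(pmax(motor_t, 0), schedule$duration)
  structure(list(
    pa_frames = frames,
    frame_timestamps = schedule$frame_timestamps,
    motor_log = data.frame(time = motor_t, angle = motor_a),
    pulse_energies = energies,
    wavelength = wavelength,
    gain_db = acq$gain_db,
    fl_frames = NULL,
    config = list(array = array, acq = acq, schedule = schedule,
                  medium = phantom$medium, nominal_energy = nominal_energy,
                  noise_sigma = noise_sigma, seed = seed,
                  oversample = oversample, n_sub = n_sub)
  ), class = "scan_data")
}

#' @export
print.scan_data <- function(x, ...) {
  d <- dim(x$pa_frames)
  cat(sprintf("<scan_data> %d frames x %d elements x %d samples, %g nm, gain %g dB\n",
              d[3], d[2], d[1], x$wavelength, x$gain_db))
  if (!is.null(x$fl_frames))
    cat(sprintf("  + FL stack %d x %d x %d\n", dim(x$fl_frames)[1],
                dim(x$fl_frames)[2], dim(x$fl_frames)[3]))
  invisible(x)
}

#' Simulate the multi-angle fluorescence frame stack
#'
#' Each frame is an orthographic parallel projection of the phantom's
#' emitters onto the camera plane at that frame's rotation angle (the focal
#' plane sits at the rotation axis and lens perspective is neglected), plus an
#' optional circular excitation-leakage background pattern, Poisson shot
#' noise and Gaussian read noise.
#'
#' @param phantom A [phantom()] with non-`NULL` `emitters`.
#' @param camera A [camera_model()].
#' @param schedule A [rotation_schedule()].
#' @param filterbleed_amplitude Peak electrons of the circular leakage ring
#'   (default 0 = none).
#' @param bleed_radius,bleed_width Ring radius and Gaussian width in mm.
#' @param photons_per_unit Electrons per unit concentration per ms exposure.
#' @param noise Add Poisson shot noise and read noise (default TRUE).
#' @param seed Optional RNG seed.
#' @param angles_deg Optional explicit frame angles.
#' @return Array (rows x cols x frames) of camera frames in electrons, with
#'   attribute `angles_deg`.  Rows run top to bottom (+z to -z), columns along
#'   the lab `y` axis.
#' @export
simulate_fl_scan <- function(phantom, camera = camera_model(pixels = c(256, 256)),
                             schedule = rotation_schedule(),
                             filterbleed_amplitude = 0, bleed_radius = 14,
                             bleed_width = 3, photons_per_unit = 200,
                             noise = TRUE, seed = NULL, angles_deg = NULL) {
  stopifnot(inherits(phantom, "phantom"), !is.null(phantom$emitters))
  if (!is.null(seed)) set.seed(seed)
  em <- phantom$emitters
  npx <- camera$pixels  # c(n_cols?, ...) convention: fov/pixels per axis
  n_cols <- npx[1]; n_rows <- npx[2]
  pitch_y <- camera$pixel_pitch[1]; pitch_z <- camera$pixel_pitch[2]
  ycoord <- (seq_len(n_cols) - (n_cols + 1) / 2) * pitch_y
  zcoord <- ((n_rows + 1) / 2 - seq_len(n_rows)) * pitch_z
  angles <- if (is.null(angles_deg)) schedule$nominal_angles else angles_deg
  n_frames <- length(angles)
  out <- array(0, dim = c(n_rows, n_cols, n_frames))
  bleed <- if (filterbleed_amplitude > 0) {
    r <- sqrt(outer(zcoord^2, ycoord^2, "+"))
    filterbleed_amplitude * exp(-(r - bleed_radius)^2 / (2 * bleed_width^2))
  } else 0
  scale <- photons_per_unit * camera$exposure * camera$quantum_efficiency
  for (f in seq_len(n_frames)) {
    th <- angles[f] * pi / 180
    img <- matrix(0, n_rows, n_cols)
    for (k in seq_len(nrow(em))) {
      qy <- sin(th) * em$x[k] + cos(th) * em$y[k]
      qz <- em$z[k]
      s <- em$sigma[k]
      gy <- exp(-(ycoord - qy)^2 / (2 * s^2))
      gz <- exp(-(zcoord - qz)^2 / (2 * s^2))
      amp <- scale * em$concentration[k] * em$yield[k] *
        pitch_y * pitch_z / (2 * pi * s^2)
      img <- img + amp * outer(gz, gy)
    }
    img <- img + bleed
    if (noise) {
      img <- stats::rpois(length(img), pmax(img, 0)) +
        stats::rnorm(length(img), 0, camera$read_noise)
      img <- matrix(img, n_rows, n_cols)
    }
    out[, , f] <- img
  }
  attr(out, "angles_deg") <- angles
  attr(out, "pixel_pitch") <- c(pitch_y, pitch_z)
  out
}
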