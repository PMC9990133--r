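#' Running average across frames
#'
#' Centred moving mean along the frame axis to suppress frame-to-frame
#' background noise; at the stack edges the window is truncated to the
#' available frames.  `window = 1` is the identity.
#'
#' @param frames 3D array (samples x elements x frames).
#' @param window Odd window length in frames (default 5).
#' @return Array of the same shape.
#' @export
running_average_frames <- function(frames, window = 5) {
  stopifnot(length(dim(frames)) == 3)
  if (window < 1 || window %% 2 == 0)
    stop("'window' must be an odd positive count", call. = FALSE)
  if (window == 1) return(frames)
  n <- dim(frames)[3]
  half <- (window - 1) / 2
  # rolling window sum: O(one frame) of extra memory
  out <- array(0, dim = dim(frames))
  acc <- frames[, , 1] * 0
  hi0 <- min(half, n)
  for (k in seq_len(hi0)) acc <- acc + frames[, , k]
  for (k in seq_len(n)) {
    hi <- k + half; lo <- k - half
    if (hi <= n) acc <- acc + frames[, , hi]
    if (lo - 1 >= 1) acc <- acc - frames[, , lo - 1]
    out[, , k] <- acc / (min(hi, n) - max(lo, 1) + 1)
  }
  out
}

#' Butterworth low-pass filtering of channel data
#'
#' Per-channel sixth-order Butterworth low-pass, by default applied zero-phase
#' (forward-backward) so that acoustic arrival times are not shifted — delay
#' fidelity matters more to back-projection than the filter's nominal edge,
#' so the -3 dB single-pass point deepens to -6 dB in the default mode.
#'
#' @param frame Matrix (samples x channels) or 3D array
#'   (samples x channels x frames), sampled at `fs`.
#' @param order Filter order (default 6).
#' @param cutoff Cut-off frequency in MHz (default 8); must be below Nyquist.
#' @param fs Sampling rate in MHz (default 40).
#' @param zero_phase Apply forward-backward (default TRUE).
#' @return Filtered data, same shape.
#' @export
lowpass_butterworth <- function(frame, order = 6, cutoff = 8, fs = 40,
                                zero_phase = TRUE) {
  if (cutoff >= fs / 2)
    stop("'cutoff' must be below the Nyquist frequency", call. = FALSE)
  dims <- dim(frame)
  m <- if (is.null(dims)) matrix(frame, ncol = 1) else matrix(frame, nrow = dims[1])
  if (zero_phase) {
    # forward-backward filtering has zero phase and the squared magnitude
    # |H|^2 of the analog prototype; apply it spectrally (channel traces
    # decay to ~0 at the record ends, so circular wrap-around is benign)
    n <- nrow(m)
    f <- (seq_len(n) - 1) / n * fs
    f <- ifelse(f > fs / 2, fs - f, f)
    H2 <- 1 / (1 + (f / cutoff)^(2 * order))
    out <- Re(stats::mvfft(stats::mvfft(m) * H2, inverse = TRUE)) / n
  } else {
    bt <- signal::butter(order, cutoff / (fs / 2), type = "low")
    out <- apply(m, 2, function(x) as.numeric(signal::filter(bt, x)))
  }
  if (is.null(dims)) as.numeric(out) else array(out, dim = dims)
}

#' Interpolate frame angles from the asynchronous motor log
#'
#' The rotation stage logs (time, angle) pairs on its own clock; each
#' photoacoustic frame is assigned an angle by linear interpolation of that
#' log at the frame's acquisition timestamp.  No extrapolation: every frame
#' timestamp must lie inside the log's span.
#'
#' @param motor_log `data.frame` with columns `time` (s) and `angle` (deg),
#'   timestamps strictly increasing.
#' @param frame_timestamps Frame acquisition times in s.
#' @return Angles in degrees, one per frame.
#' @export
interpolate_frame_angles <- function(motor_log, frame_timestamps) {
  stopifnot(is.data.frame(motor_log), all(c("time", "angle") %in% names(motor_log)))
  if (any(diff(motor_log$time) <= 0))
    stop("motor log timestamps must be strictly increasing", call. = FALSE)
  if (min(frame_timestamps) < min(motor_log$time) ||
      max(frame_timestamps) > max(motor_log$time))
    stop("frame timestamp outside the motor log span (no extrapolation)",
         call. = FALSE)
  stats::approx(motor_log$time, motor_log$angle, xout = frame_timestamps)$y
}

#' Per-frame amplitude normalisation
#'
#' Corrects a frame for the recorded pulse energy, the receive gain and the
#' optical absorption of the coupling-water path:
#' `frame * (ref_energy / pulse_energy) * 10^(-gain_db / 20) *
#'  exp(water_mu_a * water_path_cm)`.
#'
#' @param frame Numeric array of any shape.
#' @param pulse_energy Recorded pulse energy, mJ (> 0).
#' @param ref_energy Reference energy, mJ (default 80).
#' @param gain_db Receive gain applied at acquisition, dB.
#' @param water_path_mm In-water light path in mm (default 95: chamber inner
#'   radius to the rotation axis, constant per scan).
#' @param water_mu_a Water absorption at the scan wavelength, 1/cm.
#' @return Normalised frame.
#' @export
#' @examples
#' normalize_frame(1, 80, 80, 0, 65, 0.022)  # exp(0.022 * 6.5) ~ 1.154
normalize_frame <- function(frame, pulse_energy, ref_energy = 80, gain_db = 0,
                            water_path_mm = 95, water_mu_a = 0) {
  if (pulse_energy <= 0)
    stop("'pulse_energy' must be positive", call. = FALSE)
  frame * (ref_energy / pulse_energy) * 10^(-gain_db / 20) *
    exp(water_mu_a * water_path_mm / 10)
}

#' Signal-conditioning chain applied before reconstruction
#'
#' Applies, in fixed order: running average across frames, zero-phase
#' sixth-order Butterworth low-pass at 8 MHz, and per-frame normalisation by
#' pulse energy, receive gain and water absorption; frame angles are
#' interpolated from the motor log independently.  The whole chain is linear
#' in the input data.
#'
#' @param scan A `scan_data` object from [simulate_scan()] or [read_scan()].
#' @param window Running-average window (odd, default 5).
#' @param cutoff,order Butterworth parameters (defaults 8 MHz, 6).
#' @param water_path_mm Water path for the absorption correction, mm.
#' @return A `processed_scan` object: `pa_frames` (filtered, normalised),
#'   `angles_deg` (one per frame), and a `corrections` data.frame logging the
#'   per-frame energy factor and the constant gain and water factors.
#' @export
preprocess_scan <- function(scan, window = 5, cutoff = 8, order = 6,
                            water_path_mm = 95) {
  stopifnot(inherits(scan, "scan_data"))
  acq <- scan$config$acq
  fr <- running_average_frames(scan$pa_frames, window)
  for (f in seq_len(dim(fr)[3]))   # per frame: bounded working memory
    fr[, , f] <- lowpass_butterworth(fr[, , f], order = order,
                                     cutoff = cutoff,
                                     fs = acq$sampling_rate)
  ref <- scan$config$nominal_energy
  mu_w <- water_absorption(scan$config$medium, scan$wavelength)
  energy_factor <- ref / scan$pulse_energies
  gain_factor <- 10^(-scan$gain_db / 20)
  water_factor <- exp(mu_w * water_path_mm / 10)
  for (f in seq_len(dim(fr)[3]))
    fr[, , f] <- fr[, , f] * energy_factor[f] * gain_factor * water_factor
  angles <- interpolate_frame_angles(scan$motor_log, scan$frame_timestamps)
  structure(list(
    pa_frames = fr,
    angles_deg = angles,
    corrections = data.frame(frame = seq_along(energy_factor),
                             energy_factor = energy_factor,
                             gain_factor = gain_factor,
                             water_factor = water_factor),
    sampling_rate = acq$sampling_rate,
    config = scan$config
  ), class = "processed_scan")
}
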