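#' Absorber constructors
#'
#' Absorbers are the photoacoustic sources of a phantom.  Three shapes are
#' supported: a uniform sphere, a thin filament segment (discretized into
#' sub-resolution spheres for the forward model) and a liquid-filled
#' microcuvette (a cylinder, likewise discretized).
#'
#' `mu_a` may be a scalar (wavelength-independent, 1/cm) or a `data.frame`
#' with columns `wavelength` (nm) and `mu_a` for multispectral phantoms.
#'
#' @param center,start,end 3-vectors in mm.
#' @param radius Sphere radius in mm.
#' @param diameter Filament or cuvette inner diameter in mm.
#' @param axis Unit-ish direction of the cuvette axis (normalised internally).
#' @param length Cuvette length in mm.
#' @param mu_a Optical absorption coefficient, 1/cm (scalar or spectrum table).
#' @param scale Lumped Grueneisen-fluence scale factor (dimensionless,
#'   default 1); multiplies the emitted pressure amplitude.
#' @return An object of class `absorber`.
#' @name absorbers
NULL

.check_mu_a <- function(mu_a) {
  if (is.data.frame(mu_a)) {
    stopifnot(all(c("wavelength", "mu_a") %in% names(mu_a)))
    if (any(mu_a$mu_a < 0)) stop("'mu_a' must be non-negative", call. = FALSE)
  } else if (!is.numeric(mu_a) || any(mu_a < 0)) {
    stop("'mu_a' must be non-negative", call. = FALSE)
  }
  mu_a
}

#' @rdname absorbers
#' @export
sphere_absorber <- function(center, radius, mu_a, scale = 1) {
  stopifnot(length(center) == 3)
  if (radius <= 0) stop("'radius' must be positive", call. = FALSE)
  structure(list(shape = "sphere", center = as.numeric(center),
                 radius = radius, mu_a = .check_mu_a(mu_a), scale = scale),
            class = "absorber")
}

#' @rdname absorbers
#' @export
filament_absorber <- function(start, end, diameter, mu_a, scale = 1) {
  stopifnot(length(start) == 3, length(end) == 3)
  if (diameter <= 0) stop("'diameter' must be positive", call. = FALSE)
  if (all(start == end)) stop("degenerate filament segment", call. = FALSE)
  structure(list(shape = "filament", start = as.numeric(start),
                 end = as.numeric(end), diameter = diameter,
                 mu_a = .check_mu_a(mu_a), scale = scale),
            class = "absorber")
}

#' @rdname absorbers
#' @export
cuvette_absorber <- function(center, axis = c(0, 0, 1), diameter = 0.81,
                             length = 30, mu_a = 0, scale = 1) {
  stopifnot(length(center) == 3, length(axis) == 3)
  if (diameter <= 0 || length <= 0)
    stop("cuvette dimensions must be positive", call. = FALSE)
  structure(list(shape = "cuvette", center = as.numeric(center),
                 axis = as.numeric(axis) / sqrt(sum(axis^2)),
                 diameter = diameter, length = length,
                 mu_a = .check_mu_a(mu_a), scale = scale),
            class = "absorber")
}

#' Absorption coefficient of an absorber at a wavelength
#' @param absorber An absorber.
#' @param wavelength Wavelength in nm (ignored for scalar `mu_a`).
#' @return mu_a in 1/cm.
#' @export
absorber_mu_a <- function(absorber, wavelength = NA) {
  mu <- absorber$mu_a
  if (is.data.frame(mu)) {
    if (is.na(wavelength)) stop("wavelength required for spectral absorber", call. = FALSE)
    stats::approx(mu$wavelength, mu$mu_a, xout = wavelength, rule = 2)$y
  } else mu
}

#' Assemble a phantom
#'
#' @param absorbers List of [absorbers] (photoacoustic sources).
#' @param emitters Optional fluorescence emitters: a `data.frame` with columns
#'   `x`, `y`, `z` (mm), `concentration` (arbitrary concentration units) and
#'   optionally `yield` (quantum-yield proxy, default 1) and `sigma`
#'   (apparent emitter size in mm, default 0.4).
#' @param medium A [medium()] (default 25 degC degassed water).
#' @param scattering_attenuation Single amplitude factor in (0, 1] applied to
#'   all photoacoustic amplitudes to emulate a scattering environment
#'   (default 1 = non-scattering).
#' @return An object of class `phantom`.
#' @export
phantom <- function(absorbers = list(), emitters = NULL,
                    medium = paftom::medium(),
                    scattering_attenuation = 1) {
  if (scattering_attenuation <= 0 || scattering_attenuation > 1)
    stop("'scattering_attenuation' must be in (0, 1]", call. = FALSE)
  stopifnot(all(vapply(absorbers, inherits, TRUE, "absorber")))
  if (!is.null(emitters)) {
    stopifnot(is.data.frame(emitters),
              all(c("x", "y", "z", "concentration") %in% names(emitters)))
    if (is.null(emitters$yield)) emitters$yield <- 1
    if (is.null(emitters$sigma)) emitters$sigma <- 0.4
  }
  structure(list(absorbers = absorbers, emitters = emitters, medium = medium,
                 scattering_attenuation = scattering_attenuation),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d absorber(s), %d emitter(s), scattering attenuation %g\n",
              length(x$absorbers),
              if (is.null(x$emitters)) 0L else nrow(x$emitters),
              x$scattering_attenuation))
  invisible(x)
}

#' Copper-sulfate concentration to absorption coefficient
#'
#' Linear through-the-origin map between CuSO4.5H2O concentration (mM) and
#' optical absorption (1/cm) near 800 nm.  The default coefficient,
#' 0.02506 1/cm/mM, is the origin-fixed least-squares fit through the five
#' calibration pairs used for the sensitivity phantom (1.9 mM / 0.048,
#' 4.9 / 0.122, 10.3 / 0.258, 24.7 / 0.619, 49.6 / 1.243), which are
#' collinear through the origin.
#'
#' @param concentration_mM Concentration(s) in mM.
#' @param coefficient 1/cm per mM.
#' @return mu_a in 1/cm.
#' @export
#' @examples
#' cuso4_mu_a(10.3)   # ~0.258 1/cm
cuso4_mu_a <- function(concentration_mM, coefficient = 0.02506) {
  if (any(concentration_mM < 0))
    stop("'concentration_mM' must be non-negative", call. = FALSE)
  coefficient * concentration_mM
}

#' Table of the sensitivity-phantom calibration samples
#'
#' The five CuSO4.5H2O concentrations used to characterize photoacoustic
#' sensitivity, with their absorption coefficients at 800 nm.
#' @return A tibble with columns `concentration_mM` and `mu_a`.
#' @export
sensitivity_levels <- function() {
  tibble::tibble(concentration_mM = c(1.9, 4.9, 10.3, 24.7, 49.6),
                 mu_a = c(0.048, 0.122, 0.258, 0.619, 1.243))
}

#' Monofilament spatial-resolution phantom
#'
#' Fourteen 50 um black monofilaments in a support matrix: seven threaded
#' vertically (parallel to the rotation axis) spaced 4 mm apart along `x`, and
#' seven threaded horizontally (parallel to `x`) spaced 10 mm apart along `z`,
#' the whole pattern centred on the rotation axis.
#'
#' @param n_vertical,n_horizontal Number of filaments of each orientation
#'   (defaults 7 and 7; reduced counts are used for desk-scale studies).
#' @param vertical_spacing,horizontal_spacing Centre-to-centre spacing in mm
#'   (defaults 4 and 10).
#' @param length Filament length in mm (default 30).
#' @param diameter Filament diameter in mm (default 0.05).
#' @param mu_a Filament absorption coefficient in 1/cm (default 100,
#'   an opaque black polyamide string).
#' @param vertical_radii Optional explicit radial positions (mm along `x`) for
#'   the vertical filaments, overriding the evenly spaced layout.
#' @param horizontal_heights Optional explicit heights (mm) for the horizontal
#'   filaments.
#' @return A [phantom()].
#' @export
#' @examples
#' ph <- resolution_phantom()
#' length(ph$absorbers)   # 14 filaments
resolution_phantom <- function(n_vertical = 7, n_horizontal = 7,
                               vertical_spacing = 4, horizontal_spacing = 10,
                               length = 30, diameter = 0.05, mu_a = 100,
                               vertical_radii = NULL,
                               horizontal_heights = NULL) {
  if (is.null(vertical_radii))
    vertical_radii <- (seq_len(n_vertical) - (n_vertical + 1) / 2) * vertical_spacing
  if (is.null(horizontal_heights))
    horizontal_heights <- (seq_len(n_horizontal) - (n_horizontal + 1) / 2) * horizontal_spacing
  half <- length / 2
  vert <- lapply(vertical_radii, function(r)
    filament_absorber(c(r, 0, -half), c(r, 0, half), diameter, mu_a))
  # horizontal filaments run along x, offset in y so they do not intersect
  # the vertical set
  horiz <- lapply(horizontal_heights, function(z)
    filament_absorber(c(-half, 1.5, z), c(half, 1.5, z), diameter, mu_a))
  phantom(absorbers = c(vert, horiz))
}

#' Microcuvette sensitivity phantom
#'
#' One PTFE microcuvette (inner diameter 0.81 mm) per requested concentration,
#' plus a water control, arranged on a circle of radius 5.4 mm around the
#' phantom centre (4 mm arc spacing in the full six-sample layout).  The
#' absorption of each sample follows the copper-sulfate concentration map
#' [cuso4_mu_a()]; the water control (concentration 0) contributes no
#' photoacoustic source.
#'
#' @param concentrations_mM Concentrations in mM (default the five calibration
#'   levels of [sensitivity_levels()]).
#' @param include_control Add the water-control cuvette (default TRUE).
#' @param ring_radius Placement-circle radius in mm (default 5.4).
#' @param length Cuvette length in mm (default 30).
#' @param diameter Inner diameter in mm (default 0.81).
#' @param scattering_attenuation See [phantom()].
#' @return A [phantom()]; cuvette order follows `concentrations_mM`, control
#'   last.  The placement angles are equally spaced on the ring.
#' @export
sensitivity_phantom <- function(concentrations_mM = sensitivity_levels()$concentration_mM,
                                include_control = TRUE,
                                ring_radius = 5.4, length = 30, diameter = 0.81,
                                scattering_attenuation = 1) {
  if (any(concentrations_mM < 0))
    stop("'concentrations_mM' must be non-negative", call. = FALSE)
  conc <- c(concentrations_mM, if (include_control) 0)
  n <- base::length(conc)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cuv <- lapply(seq_len(n), function(i)
    cuvette_absorber(center = c(ring_radius * cos(ang[i]),
                                ring_radius * sin(ang[i]), 0),
                     axis = c(0, 0, 1), diameter = diameter, length = length,
                     mu_a = cuso4_mu_a(conc[i])))
  ph <- phantom(absorbers = cuv,
                scattering_attenuation = scattering_attenuation)
  ph$concentrations_mM <- conc
  ph
}

#' Multispectral phantom
#'
#' Cuvettes filled with user-supplied contrast-agent spectra (plus a water
#' control), arranged like the sensitivity phantom.  Spectra are
#' `data.frame`s with columns `wavelength` (nm) and `mu_a` (1/cm).
#'
#' @param spectra Named list of spectrum tables, one per agent.
#' @param ring_radius,length,diameter As in [sensitivity_phantom()].
#' @return A [phantom()] with `sample_names` attached (control last).
#' @export
multispectral_phantom <- function(spectra, ring_radius = 5.4, length = 30,
                                  diameter = 0.81) {
  stopifnot(is.list(spectra), base::length(spectra) >= 1)
  n <- base::length(spectra) + 1
  ang <- 2 * pi * (seq_len(n) - 1) / n
  mk <- function(i, mu) cuvette_absorber(
    center = c(ring_radius * cos(ang[i]), ring_radius * sin(ang[i]), 0),
    axis = c(0, 0, 1), diameter = diameter, length = length, mu_a = mu)
  cuv <- c(lapply(seq_along(spectra), function(i) mk(i, spectra[[i]])),
           list(mk(n, 0)))
  ph <- phantom(absorbers = cuv)
  ph$sample_names <- c(names(spectra), "water")
  ph
}

#' Discretize an absorber into point-like spheres
#'
#' The forward model superposes analytic spherical sources; extended shapes
#' are decomposed here.  The axial step is half the shape's diameter, capped
#' at `max_step`: a line of spheres spaced wider than half the shortest
#' in-band acoustic wavelength would radiate grating lobes inside the
#' transducer band and pollute reconstructions with spurious streaks, so
#' wide shapes (cuvettes) are sampled sub-wavelength.  The default cap,
#' 0.08 mm, is a quarter wavelength at the band-pass upper edge.
#' Discretization weights keep the summed source strength independent of the
#' sampling count.
#'
#' @param absorber An absorber.
#' @param wavelength Wavelength in nm used to evaluate spectral `mu_a`.
#' @param max_step Axial sampling cap in mm (default 0.08).
#' @return A list with `centers` (n x 3), `radius`, `mu_a`, `scale`.
#' @export
discretize_absorber <- function(absorber, wavelength = NA, max_step = 0.08) {
  mu <- absorber_mu_a(absorber, wavelength)
  if (absorber$shape == "sphere") {
    return(list(centers = matrix(absorber$center, 1, 3), radius = absorber$radius,
                mu_a = mu, scale = absorber$scale))
  }
  if (absorber$shape == "filament") {
    dir <- absorber$end - absorber$start
    len <- sqrt(sum(dir^2))
    step <- min(absorber$diameter / 2, max_step)
    n <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = n)
    centers <- cbind(absorber$start[1] + tt * dir[1],
                     absorber$start[2] + tt * dir[2],
                     absorber$start[3] + tt * dir[3])
    # weight per sphere so total source strength is independent of n
    return(list(centers = centers, radius = absorber$diameter / 2,
                mu_a = mu, scale = absorber$scale * (len / step) / n))
  }
  # cuvette: spheres of the inner diameter stacked sub-wavelength along the axis
  step <- min(absorber$diameter / 2, max_step)
  n <- max(2L, ceiling(absorber$length / step) + 1L)
  tt <- seq(-absorber$length / 2, absorber$length / 2, length.out = n)
  centers <- cbind(absorber$center[1] + tt * absorber$axis[1],
                   absorber$center[2] + tt * absorber$axis[2],
                   absorber$center[3] + tt * absorber$axis[3])
  list(centers = centers, radius = absorber$diameter / 2,
       mu_a = mu, scale = absorber$scale * (absorber$length / step) / n)
}
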