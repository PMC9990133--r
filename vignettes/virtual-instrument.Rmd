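---
title: "A virtual rotate-scan photoacoustic/fluorescence tomograph: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual rotate-scan photoacoustic/fluorescence tomograph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(paftom)
```

# What this package models

`paftom` is a *virtual instrument*: a forward simulator and reconstruction/
characterization toolchain for a dual-modality preclinical scanner in which
the sample rotates continuously on a vertical axis while (i) a 96-element
vertical-arc ultrasound array records photoacoustic (PA) pressure frames, one
per laser pulse, and (ii) an sCMOS camera records planar fluorescence (FL)
frames through the same rotation.  The package implements the instrument's
published characterization procedures — Gaussian-fit spatial-resolution maps,
contrast-to-noise (CNR) detection limits, origin-fixed linearity regression,
multispectral spectrum extraction and three-bar chart scoring — so that each
procedure can be exercised end-to-end on synthetic phantoms with known ground
truth.

# Coordinate and unit conventions

Right-handed coordinates with `z` the rotation axis (up positive); the origin
is the intersection of the rotation axis with the plane of the array's centre
element; azimuth is counter-clockwise viewed from `+z`.  The sample rotates by
`+theta(t)`; all reconstruction happens in the sample frame by virtually
rotating the detector by `-theta` per frame.  Internal units are mm,
microseconds and MHz; conversions (m/s for the speed of sound, seconds for
schedules, nm for wavelengths) happen at interface boundaries.

# Instrument geometry

The arc has radius 65 mm, 96 elements of 1.3 x 1.3 mm with 0.1 mm gaps, so
the angular pitch is `1.4/65` rad (about 1.234 deg) and the span about
117.3 deg.  The span is not a catalogue number: it is the only reading
consistent with the element pitch and count, and it is treated as derived
geometry, not a tunable.  With an even element count, "centre element on the
scan plane" is approximated by centring the arc on `z = 0`, so the two
centremost elements straddle the plane by half a pitch (0.7 mm).  Whether
the physical array is elevation-focused is unknown; elements are modelled as
flat apertures pointing at the arc centre.

The speed of sound in the coupling water comes from Marczak's (1997)
fifth-order pure-water polynomial (about 1496.7 m/s at the 25 degC bath),
restricted to 0-60 degC; an explicit override is available for non-water
media.

# Forward model

Every absorber is decomposed into uniform spheres — axial step of half the
shape's diameter, capped at 0.08 mm (a quarter wavelength at the band-pass
upper edge): a sphere chain sampled coarser than half the in-band acoustic
wavelength would radiate grating lobes inside the transducer band and flood
reconstructions with spurious background, which is exactly what a 0.4 mm
step does for the 0.81 mm cuvettes — and each sphere emits the closed-form bipolar N-wave: support
`2a/c` centred at the acoustic delay, amplitude proportional to
`mu_a x scale x a / d`, zero time integral.  Discretization weights keep the
summed source strength independent of the sampling count, so amplitudes are
linear in both `mu_a` and absorber volume.

Instrument effects applied to the ideal traces, in order:

1. **Finite aperture (directivity)** — each element face is subdivided into a
   5 x 5 grid of receive points and the arrival-delayed traces averaged.
   This reproduces the high-frequency roll-off of oblique arrivals without a
   full spatial-impulse-response integral.  The grid order is configurable
   (`n_sub`); 3 is visually indistinguishable for near-axis targets, 1
   disables the aperture.
2. **Transducer band-pass** — zero-phase Gaussian amplitude response centred
   at 6 MHz whose -6 dB full width equals 0.55 of the centre frequency.  The
   electrical impulse response (phase) is deliberately not modelled; only the
   amplitude specification is public, and inventing a phase would bias
   arrival times.
3. **Hardware low-pass** — 10 MHz fourth-order Butterworth magnitude, applied
   zero-phase, standing in for the acquisition board's anti-aliasing filter.
4. **Gain** — linear `10^(gain_db/20)`, hardware range 46-91 dB.
5. **Noise** — additive white Gaussian noise, seeded.

N-waves are synthesised on a 4x supersampled time grid (160 MHz) and
decimated after filtering, because a 50 um source's pulse spans only ~1.3
samples at 40 MHz; for cuvette-scale sources (0.81 mm) the pulse spans ~22
samples and `oversample = 1` is used.

Per-pulse laser energies are drawn around the 80 mJ nominal output with 1%
relative jitter, and the rotation stage's angle log is emitted on its own
clock (7.3 Hz with a phase offset), deliberately asynchronous with the frame
timestamps, because the downstream angle interpolator must cope with exactly
that.

A scattering environment is represented only as a single amplitude
attenuation factor in (0, 1]; no fluence transport is modelled.  This
supports relative CNR comparisons but not absolute fluence quantitation.

`perturb_array()` injects manufacturing tolerances (uniform radius offset,
arc-curvature error with the centre element kept at its stand-off, or
per-element radial jitter): simulating with a perturbed geometry while
reconstructing with the nominal one reproduces the dual-peak vertical
elongation that uncompensated hardware tolerances cause in the real
instrument (see *Known limitations*).

The FL channel is an orthographic parallel projection of point-like emitters
(Gaussian apparent size, default 0.4 mm) onto the 40 x 40 mm focal plane at
the rotation axis, plus an optional circular excitation-leakage ring,
Poisson shot noise and 2.5 e- RMS read noise.  Lens perspective and
refraction through the cylindrical chamber are not modelled; with the focal
plane on the axis this parallel-beam reading is the only implementable one,
and it is the dominant FL approximation.  The vertical illumination profile
of the physical light bars is not quantified publicly, so the simulator
ships a uniform profile.

# Signal conditioning

The preprocessing chain is fixed in order and linear end to end:

1. **Running average across frames** (default window 5, odd).  The window is
   not published; 5 frames trades ~5x noise-variance reduction against a
   2 deg tangential smear at the full 10 deg/s rotation speed.  An
   alternative reading — smoothing along the time axis within each trace —
   is possible but not implemented, because the cross-frame reading matches
   "frame-by-frame background noise".
2. **6th-order Butterworth low-pass at 8 MHz**, applied zero-phase so that
   arrival times are not delayed; consequently the nominal -3 dB edge
   deepens to -6 dB, a documented and accepted trade (back-projection
   accuracy depends on delay fidelity, not on the filter edge).  The
   zero-phase response — the squared magnitude of the analog prototype,
   identical to forward-backward IIR filtering — is applied spectrally per
   channel; a single-pass IIR mode (true -3 dB edge, nonzero phase) is
   available.
3. **Per-frame normalisation** by recorded pulse energy, receive gain and
   in-water light absorption `exp(mu_a,w x path)`.  The water path is a
   constant 95 mm (chamber inner radius to the axis) because no per-ray path
   model is published; a constant preserves the chain's linearity.

Frame angles are linearly interpolated from the motor log at the frame
timestamps, with no extrapolation.

# PAT reconstruction

The back-projection filter is the universal-back-projection-style term
`b(t) = 2 p(t) - 2 t dp/dt` with a central-difference derivative.  The
original instrument cites a filtered back-projection implementation whose
exact filter is not printed; this standard spherical-surface filter is used
instead and validated by resolution and linearity properties rather than
bit-level agreement.  Delay-and-sum then accumulates, for every voxel, the
filtered trace of every (frame, element) pair at the geometric delay with
linear interpolation, weighted by the element's subtended solid angle
(`area x cos(incidence) / d^2`; uniform weighting is available — the choice
only shades low-order amplitude).  Voxels with no valid contribution are 0
and flagged in a coverage attribute rather than NaN.  A naive triple-loop R
implementation (`backproject_naive()`) is kept as an independent oracle; the
optimised C++ path must agree with it to 1e-6 on small instances.

Standard-resolution volumes use 0.1 mm isotropic voxels; high-resolution
patches use 0.02 mm.  Detector manufacturing tolerances are deliberately not
compensated in reconstruction, mirroring the physical processing chain.

# FMT reconstruction

Because the projection model is orthographic, each camera row is an
independent sinogram; slices are reconstructed by Hann-windowed
ramp-filtered parallel-beam back-projection (cutoff at the camera Nyquist)
and stacked.  Full 360 deg data is used as acquired — conjugate views
average naturally under the `pi/n` normalisation; whether the original
implementation folded views onto 180 deg is unknown, and the window/angle
handling is configurable.  Negative reconstructed values are preserved
internally (CNR statistics need unclipped noise) and clipped only at export.

# Characterization procedures

*Resolution*: line profiles through each vertical filament (radial and
tangential, 1 mm height steps over +/- 10 mm) and vertical profiles across
horizontal filaments (1 mm lateral steps) are fitted with single 1D
Gaussians `a exp(-(x-m)^2/2s^2) + b`; FWHM `= 2 sqrt(2 ln 2) s`; the
transverse value is the mean of the radial and tangential FWHM and the pair
also yields an elliptical eccentricity.  Fits are initialised from the
profile maximum/centroid/second moment; non-convergent fits or centres
outside the profile span are flagged and excluded from maps.  Dual-peak
profiles are deliberately fitted with a single Gaussian — the procedure's
stated limitation — so they produce (honestly) inflated widths.

*Sensitivity*: segmentation is geometric (the phantom layout is known),
replacing manual segmentation for reproducibility; cuvette masks are
cylinders of the inner radius clipped to `|z| <= 10` mm, and the background
is an 8-12 mm annulus at `|z| <= 10` mm with dilated targets carved out (the
published analysis says only that background was segmented).  CNR follows
`(A_sample - A_background)/sigma_background` exactly; the detection limit is
the smallest level with CNR strictly greater than 2.

*Linearity*: origin-fixed least squares with `r^2` on the *uncentred* total
sum of squares — the standard convention once the intercept is suppressed,
noted explicitly because the centred convention gives different values — and
a t-based 95% CI on the slope.

*Spectra*: per-sample inclusions are background-subtracted per wavelength,
and all spectra share the single positive least-squares scale that matches
the reference (copper sulfate) PA spectrum to its spectrophotometer
optical-density spectrum.

*Chart scoring*: a synthetic three-bar chart (`2^(group+(element-1)/6)`
lp/mm) is rendered with known pattern positions; an element is resolvable
when the bar-normal profile shows three local maxima with peak-to-valley
modulation of at least 10% in both orientations.  Resolutions are reported
as the full line-pair period `1000/R` um, the convention consistent with the
camera's two-pixel (39 um) theoretical limit `2 x fov / pixels`.

# Synthetic phantoms (the study conditions)

* **Resolution phantom**: fourteen 50 um filaments — seven vertical, 4 mm
  apart; seven horizontal, 10 mm apart — centred on the axis.  Desk-scale
  studies reduce this to three vertical filaments at radii 0, 4, 8 mm and
  two horizontal filaments at z = +/-5 mm (the two that fall inside the
  analysed height range), with horizontal filaments offset 1.5 mm in `y` so
  the two sets do not intersect.  Filament `mu_a` is 100 1/cm (an opaque
  black string; only relative amplitude matters for resolution).
* **Sensitivity phantom**: six 0.81 mm-ID PTFE cuvettes on a 5.4 mm ring —
  copper sulfate at 1.9, 4.9, 10.3, 24.7, 49.6 mM plus a water control —
  with `mu_a = 0.02506 1/cm/mM x concentration`, the origin-fixed fit
  through the five published calibration pairs (they are collinear through
  the origin).
* What the generator does *not* emulate: acoustic attenuation and
  heterogeneous sound speed, optical fluence distribution, reflections,
  refraction at the chamber wall, camera lens distortion, breathing motion.
  Tests passing on these phantoms therefore validate the algorithms and
  their implementation, not the physical instrument; printed in-water
  optical resolutions, for instance, are instrument-bound and out of scope.

# Desk-scale study sizes and numerical choices

The packaged studies are sized for a single CPU:

* `resolution_study()`: 120 frames over 360 deg, 2304 samples/channel,
  noise-free, 0.02 mm patches (91 x 91 in-plane) around each filament with
  1 mm height steps.  The record length covers the acoustic window of the
  +/- 10 mm analysis region with margin.
* `sensitivity_study()`: the full 360-frame acquisition (reduced view
  counts raise the angular-streak artifact floor into the calibration band),
  per-cuvette 0.1 mm patches and a 0.3 mm-sampled background annulus.  The
  noise level is not a free parameter: because the chain is linear,
  `recon(signal + sigma * noise) = recon(signal) + sigma * recon(noise)`
  exactly, so the study reconstructs the noise-free scan and a unit-variance
  noise block once each and solves for the sigma that puts the 10.3 mM
  cuvette at CNR 3.2 — inside the instrument's 3-4 band for that cuvette and
  below the desk-scale reconstruction's artifact-limited ceiling (about 3.3),
  so the calibrated noise is strictly positive.  The artifact ceiling is
  reported alongside the result.

Other numerical choices: trace sampling at non-integer delays uses linear
interpolation (nearest-neighbour is an option); Gaussian band-pass and
Butterworth stages are applied in the frequency domain zero-phase; the
back-projection time derivative is central-difference with one-sided ends;
FBP normalisation is `pi / n_angles` over the full circle.

# Known limitations

* The real instrument's longitudinal (vertical) resolution is about 3x worse
  than its transverse resolution, driven by a dual-peak elongation of
  horizontal filaments that the published analysis attributes to
  uncompensated detector manufacturing tolerances (radius/arc-length).  The
  idealised noise-free simulation reproduces the *measurement procedure* but
  not that anisotropy: with an exact nominal geometry the vertical arc's
  +/- 58.6 deg aperture yields longitudinal blur only ~1.2-1.6x transverse.
  `perturb_array()` demonstrates the mechanism (an injected arc-curvature
  error produces the dual-peak vertical elongation, and the longitudinal
  FWHM grows monotonically with the error), but any timing-type tolerance
  large enough to triple the longitudinal width also degrades the
  transverse plane well past the printed transverse range, so no single
  published-consistent tolerance value reproduces both numbers at once.
  The anisotropy ratio is therefore reported as an honest discrepancy of
  the idealised model rather than forced by tuning.
* Single-Gaussian fits over dual-peak profiles inflate longitudinal
  estimates by design (matching the published procedure's limitation).
* The FL channel's orthographic model ignores perspective and refraction;
  absolute FL quantitation is out of scope, linearity and geometry are not.
* No GPU path: the C++ kernels are plain loops, sized for desk-scale grids.

# Reproducing the characterization numbers

`scripts/acceptance.R --seed <int> --out <path>` reruns both desk-scale
studies from scratch with the installed package and writes the mean
transverse FWHM (um), mean longitudinal FWHM (um) and the non-scattering
linearity `r^2` as JSON.  The same studies are callable directly:

```{r example}
st <- resolution_study(seed = 1)
st$maps$summary
sens <- sensitivity_study(seed = 1)
sens$table
sens$r_squared
```
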