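# paftom

A virtual rotate-scan photoacoustic / fluorescence tomography instrument for
R.

Preclinical scanners that combine photoacoustic tomography (PAT) and
fluorescence molecular tomography (FMT) rotate the animal or phantom on a
vertical axis while a curved ultrasound array captures one pressure frame
per laser pulse and an sCMOS camera captures planar fluorescence frames.
Characterizing such an instrument — its spatial resolution, detection
limits, spectral accuracy and linearity — requires a chain of procedures
that are rarely reproducible outside the lab that owns the hardware.
`paftom` re-implements that entire chain as software, for instrument
developers and image-reconstruction researchers: a physics-based forward
simulator (analytic N-wave sources, finite-aperture directivity, transducer
band-pass, hardware gain and noise, asynchronous motor logging), the
matching signal-conditioning and reconstruction algorithms, and the full
quantitative characterization suite, so every procedure can be exercised
end-to-end on synthetic phantoms with known ground truth.

## The models at the core

* **Forward model.** Every absorber is a superposition of uniform spheres;
  a sphere of radius *a* at distance *d* contributes the bipolar N-wave
  `p(t) = (mu_a * Gamma * a / d) * (t0 - t)/tau` for `|t - t0| <= tau`,
  `t0 = d/c`, `tau = a/c`.  Element directivity is modelled by averaging
  arrival-delayed traces over a 5x5 grid of receive points per 1.3 mm
  element; the transducer response is a zero-phase Gaussian band-pass
  (6 MHz centre, 55% fractional bandwidth at -6 dB).
* **PAT reconstruction.** Filtered back-projection with the
  universal-back-projection-style filter `b(t) = 2 p(t) - 2 t dp/dt`,
  delay-and-sum over all (frame, element) pairs with solid-angle weighting,
  in the sample frame (virtual detector rotation).
* **FMT reconstruction.** Each camera row is an independent sinogram;
  slices are recovered by Hann-windowed ramp-filtered parallel-beam
  back-projection and stacked.
* **Characterization.** Spatial resolution as the full width at half
  maximum `FWHM = 2 sqrt(2 ln 2) sigma` of 1-D Gaussian fits to line
  profiles; contrast-to-noise ratio
  `CNR = (A_sample - A_background) / sigma_background`; lower limit of
  detectability as the smallest level with CNR > 2; origin-fixed linear
  regression with uncentred r²; background-subtracted multispectral
  photoacoustic spectra; three-bar chart scoring and the two-pixel camera
  limit `2 * FoV / N_pixels`.

## Worked example

Detection-limit arithmetic on the instrument's printed CNR table, and the
scan schedule:

```r
library(paftom)

rotation_schedule(speed = 10, sweep = 360, prf = 10)$duration
#> [1] 36
rotation_schedule(speed = 10, sweep = 360, prf = 10)$n_frames
#> [1] 360

cnr(12, 2, 5)
#> [1] 2
llod(c(49.6, 24.7, 10.3, 4.9, 1.9), c(18.9, 9.0, 3.7, 1.3, 0.6))
#> [1] 10.3
nyquist_limit(40, 2048)
#> [1] 39.0625
```

The packaged desk-scale studies run the whole pipeline — simulate, condition,
reconstruct, characterize (a few minutes each on one CPU):

```r
res <- resolution_study(seed = 1)
res
#> <resolution_study> transverse 121 um, longitudinal 362 um (ratio 3.00)
res$maps$summary
#> # A tibble: 2 × 4
#>   map          mean_fwhm_um sd_fwhm_um     n
#>   <chr>               <dbl>      <dbl> <int>
#> 1 transverse           121.       31.5    61
#> 2 longitudinal         362.      663.     38

sens <- sensitivity_study(seed = 1001)
sens
#> <sensitivity_study> r^2 = 0.9993, LLOD = 10.3 mM (mu_a 0.258 1/cm)
#> # A tibble: 6 × 4
#>   concentration_mM   mu_a inclusion      cnr
#>              <dbl>  <dbl>     <dbl>    <dbl>
#> 1              1.9 0.0476 0.00352    0.562
#> 2              4.9 0.123  0.00971    1.55
#> 3             10.3 0.258  0.0200     3.2
#> 4             24.7 0.619  0.0452     7.22
#> 5             49.6 1.24   0.0971    15.5
#> 6              0   0      0.0000201  0.00300
```

The resolution study reports the mean transverse FWHM of vertical 50 um
monofilaments (radial/tangential Gaussian fits over a ±10 mm height window
at 0.02 mm voxels) and the mean longitudinal FWHM of horizontal filaments;
the sensitivity study reports mean reconstructed target inclusions of the
copper-sulfate cuvette series, their CNRs against an 8-12 mm background
annulus (noise calibrated so the 10.3 mM cuvette sits in the instrument's
3-4 CNR band), the resulting detection limit, and the origin-fixed
concentration linearity r².

A thin command-line wrapper over the same functions ships in
`inst/cli/paftom` (`simulate`, `recon-pat`, `recon-fmt`, `characterize`).

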