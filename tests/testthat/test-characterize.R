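# synthetic volume with isotropic Gaussian blobs at given centres
blob_volume <- function(centers, fwhm_mm, xlim, ylim, zlim, voxel,
                        amplitude = 1) {
  g <- volume_grid(xlim, ylim, zlim, voxel)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2)))
  xc <- g$coords[[1]]; yc <- g$coords[[2]]; zc <- g$coords[[3]]
  dat <- array(0, dim = c(length(xc), length(yc), length(zc)))
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-(xc - centers[i, 1])^2 / (2 * sig^2))
    gy <- exp(-(yc - centers[i, 2])^2 / (2 * sig^2))
    gz <- exp(-(zc - centers[i, 3])^2 / (2 * sig^2))
    dat <- dat + amplitude * outer(outer(gx, gy), gz)
  }
  volume(dat, g$voxel_size, g$origin)
}

test_that("line profiles interpolate the volume correctly", {
  vol <- volume(array(4, dim = c(11, 11, 5)), 0.5, origin = c(-2.5, -2.5, -1))
  p <- extract_line_profile(vol, c(-2, -2, 0), c(2, 2, 0), 21)
  expect_true(all(p$value == 4))
  # a profile along a voxel row reproduces that row at the nodes
  vol2 <- volume(array(rnorm(11 * 11 * 5), dim = c(11, 11, 5)), 0.5,
                 origin = c(-2.5, -2.5, -1))
  p2 <- extract_line_profile(vol2, c(-2.5, 0, 0), c(2.5, 0, 0), 11)
  expect_equal(p2$value, vol2$data[, 6, 3])
  expect_error(extract_line_profile(vol, c(-2, 0, 0), c(9, 0, 0), 5),
               "outside")
  # profile across a synthetic Gaussian blob recovers its width within 2%
  vb <- blob_volume(matrix(c(0, 0, 0), 1), fwhm_mm = 0.8,
                    c(-2, 2), c(-2, 2), c(-1, 1), 0.05)
  f <- fit_gaussian_fwhm(extract_line_profile(vb, c(-2, 0, 0), c(2, 0, 0), 81))
  expect_equal(f$fwhm, 0.8, tolerance = 0.02)
})

test_that("Gaussian fits satisfy the FWHM-sigma identity exactly", {
  x <- seq(-5, 5, length.out = 101)
  f1 <- fit_gaussian_fwhm(x, 2 * exp(-x^2 / 2) + 0.1)
  expect_equal(f1$sigma, 1, tolerance = 1e-6)
  expect_equal(f1$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(f1$fwhm / f1$sigma, 2 * sqrt(2 * log(2)))
  # 173 um FWHM corresponds to sigma = 73.5 um
  x2 <- seq(-0.4, 0.4, length.out = 81)
  f2 <- fit_gaussian_fwhm(x2, exp(-x2^2 / (2 * 0.0735^2)))
  expect_equal(f2$fwhm * 1000, 173, tolerance = 0.2)
  expect_error(fit_gaussian_fwhm(x[1:4], rep(1, 4)), "5")
})

test_that("Gaussian fit recovers parameters under noise", {
  set.seed(99)
  x <- seq(-4, 4, length.out = 81)
  sig_hat <- replicate(100, {
    y <- exp(-x^2 / (2 * 1.2^2)) + rnorm(81, 0, 0.05)
    fit_gaussian_fwhm(x, y)$sigma
  })
  expect_equal(mean(sig_hat, na.rm = TRUE), 1.2, tolerance = 0.03)
})

test_that("eccentricity follows the ellipse definition", {
  expect_equal(eccentricity(0.2, 0.2), 0)
  expect_equal(eccentricity(5, 3), 0.8)
  expect_equal(eccentricity(3, 5), 0.8)  # orientation-free
  set.seed(1)
  e <- eccentricity(runif(50, 0.01, 10), runif(50, 0.01, 10))
  expect_true(all(e >= 0 & e < 1))
  expect_error(eccentricity(0, 1), "positive")
})

test_that("CNR and LLOD implement the stated definitions", {
  expect_equal(cnr(12, 2, 5), 2)
  expect_equal(cnr(5, 5, 3), 0)
  expect_lt(cnr(1, 2, 5), 0)
  expect_error(cnr(1, 0, 0), "positive")
  # CNR is invariant under affine rescaling a X + b of the whole volume
  a <- 3.7; b <- -2
  expect_equal(cnr(a * 12 + b, a * 2 + b, a * 5), cnr(12, 2, 5))
  conc <- c(49.6, 24.7, 10.3, 4.9, 1.9)
  expect_equal(llod(conc, c(18.9, 9.0, 3.7, 1.3, 0.6)), 10.3)
  expect_equal(llod(conc, rep(10, 5)), 1.9)
  expect_true(is.na(llod(conc, rep(1, 5))))
  expect_true(is.na(llod(10, 2)))  # strict inequality at the threshold
})

test_that("origin-fixed regression uses the uncentred r-squared", {
  f <- fit_linear_origin(1:5, 3 * (1:5))
  expect_equal(f$slope, 3)
  expect_equal(f$r_squared, 1)
  # y orthogonal to x: fitted slope 0, uncentred r^2 = 0
  x <- c(-2, -1, 0, 1, 2); y <- c(1, 1, 5, 1, 1) - 1.8
  f2 <- fit_linear_origin(x, y * as.numeric(sum(x * y) == 0))
  expect_equal(f2$slope, 0)
  expect_equal(f2$r_squared, 0, tolerance = 1e-12)
  expect_error(fit_linear_origin(c(0, 0), c(1, 2)), "degenerate")
  # Monte-Carlo recovery under 1% multiplicative noise
  set.seed(7)
  slopes <- replicate(500, {
    x <- 1:5
    fit_linear_origin(x, 2.5 * x * (1 + 0.01 * rnorm(5)))$slope
  })
  expect_equal(mean(slopes), 2.5, tolerance = 0.01 * 2.5)
  # the 95% CI covers the true slope at about the nominal rate
  covered <- replicate(300, {
    x <- 1:5
    ci <- fit_linear_origin(x, 2.5 * x * (1 + 0.05 * rnorm(5)))$ci95
    ci[1] <= 2.5 && 2.5 <= ci[2]
  })
  expect_gt(mean(covered), 0.85)
})

test_that("theoretical camera limit follows two-pixel sampling", {
  expect_equal(nyquist_limit(40, 2048), 39.0625)
  expect_equal(round(nyquist_limit(40, 2048)), 39)
  expect_equal(nyquist_limit(40, 1024), 78.125)
  expect_equal(nyquist_limit(80, 2048), 2 * nyquist_limit(40, 2048))
})

test_that("mean target inclusion averages the segmented voxels", {
  vol <- volume(array(3, dim = c(5, 5, 5)), 1, origin = c(-2, -2, -2))
  mask <- array(FALSE, dim = c(5, 5, 5)); mask[3, 3, 3] <- TRUE
  expect_equal(mean_target_inclusion(vol, mask), 3)
  vol$data[3, 3, 3] <- 9
  expect_equal(mean_target_inclusion(vol, mask), 9)
  expect_error(mean_target_inclusion(vol, mask & FALSE), "empty")
  # cylinder masks clip to |z| <= 10 mm
  vol2 <- volume(array(1, dim = c(5, 5, 31)), c(1, 1, 1),
                 origin = c(-2, -2, -15))
  m <- cylinder_mask(vol2, c(0, 0), radius = 1.2, z_max = 10)
  zc <- volume_axis(vol2, 3)
  expect_true(all(!m[, , abs(zc) > 10]))
  expect_true(any(m[, , abs(zc) <= 10]))
})

test_that("background annulus excludes dilated targets", {
  vol <- volume(array(0, dim = c(49, 49, 5)), c(0.5, 0.5, 1),
                origin = c(-12, -12, -2))
  m <- annulus_mask(vol, 8, 12, 10, exclude = list(c(9, 0, 0.5)))
  xc <- volume_axis(vol, 1); yc <- volume_axis(vol, 2)
  r <- sqrt(outer(xc^2, yc^2, "+"))
  inner <- which(r < 8 - 1e-9, arr.ind = TRUE)
  expect_false(any(m[cbind(inner, 3)]))
  ix <- which.min(abs(xc - 9)); iy <- which.min(abs(yc))
  expect_false(any(m[ix, iy, ]))
})

test_that("resolution maps recover a known isotropic blur", {
  ph <- resolution_phantom(vertical_radii = c(0, 4), horizontal_heights = 5,
                           n_vertical = 2, n_horizontal = 1)
  centers_v <- lapply(c(0, 4), function(r) cbind(r, 0, seq(-10, 10, 1)))
  vols <- list(
    blob_volume(centers_v[[1]], 0.2, c(-0.8, 0.8), c(-0.8, 0.8), c(-10.5, 10.5),
                c(0.02, 0.02, 0.5)),
    blob_volume(centers_v[[2]], 0.2, c(3.2, 4.8), c(-0.8, 0.8), c(-10.5, 10.5),
                c(0.02, 0.02, 0.5)),
    blob_volume(cbind(seq(-10, 10, 1), 1.5, 5), 0.2, c(-10.5, 10.5),
                c(1.3, 1.7), c(3, 7), c(0.5, 0.02, 0.02)))
  maps <- resolution_maps(vols, ph)
  # 21 height samples per vertical filament over +/- 10 mm
  expect_equal(nrow(maps$transverse), 42)
  expect_equal(sum(maps$transverse$radius == 0), 21)
  # recovered transverse FWHM ~ 200 um everywhere (isotropic blobs)
  expect_equal(maps$transverse$fwhm_transverse,
               rep(0.2, 42), tolerance = 0.03)
  # transverse is the mean of radial and tangential at every entry
  expect_equal(maps$transverse$fwhm_transverse,
               (maps$transverse$fwhm_radial + maps$transverse$fwhm_tangential) / 2)
  expect_equal(maps$longitudinal$fwhm_longitudinal,
               rep(0.2, 21), tolerance = 0.03)
  expect_equal(maps$summary$mean_fwhm_um, c(200, 200), tolerance = 0.03)
})

test_that("multispectral spectra are background-subtracted and normalised", {
  wl <- seq(700, 900, by = 50)
  od_cu <- data.frame(wavelength = wl, od = c(0.2, 0.45, 0.7, 0.9, 1.0))
  spec_ni <- c(1.0, 0.6, 0.35, 0.2, 0.12)
  dims <- c(12, 12, 3)
  mk_vol <- function(iw) {
    d <- array(0.05, dim = dims)            # constant background
    d[2:4, 2:4, ] <- 0.05 + od_cu$od[iw]    # copper-sulfate region
    d[8:10, 8:10, ] <- 0.05 + spec_ni[iw]   # nickel-sulfate region
    volume(d, 1, origin = c(0, 0, -1))
  }
  vols <- lapply(seq_along(wl), mk_vol)
  names(vols) <- wl
  masks <- list(cuso4 = array(FALSE, dims), niso4 = array(FALSE, dims),
                water = array(FALSE, dims))
  masks$cuso4[2:4, 2:4, ] <- TRUE
  masks$niso4[8:10, 8:10, ] <- TRUE
  masks$water[5:6, 11:12, ] <- TRUE
  bg <- array(FALSE, dims); bg[11:12, 2:3, ] <- TRUE
  sp <- pa_spectrum(vols, masks, bg, od_cu, reference_sample = "cuso4")
  cu <- sp$spectra[sp$spectra$sample == "cuso4", ]
  expect_equal(cu$pa_normalized, od_cu$od, tolerance = 0.01)
  # water control is ~0 at all wavelengths
  expect_true(all(abs(sp$spectra$pa_raw[sp$spectra$sample == "water"]) < 1e-9))
  # scaling all volumes leaves normalised spectra unchanged
  vols2 <- lapply(vols, function(v) { v$data <- 5 * v$data; v })
  names(vols2) <- wl
  sp2 <- pa_spectrum(vols2, masks, bg, od_cu, reference_sample = "cuso4")
  expect_equal(sp2$spectra$pa_normalized, sp$spectra$pa_normalized,
               tolerance = 1e-9)
})
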