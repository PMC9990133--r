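test_that("back-projection filter matches closed forms", {
  tg <- seq(0, 10, by = 0.025)
  # constant: zero derivative
  expect_equal(ubp_filter(rep(3, length(tg)), tg), rep(6, length(tg)))
  # linear ramp: 2t - 2t = 0 (interior; one-sided ends are exact too)
  expect_equal(ubp_filter(tg, tg), rep(0, length(tg)), tolerance = 1e-10)
  # sinusoid: matches the analytic 2 sin(wt) - 2 t w cos(wt)
  w <- 2 * pi * 1.3
  p <- sin(w * tg)
  b <- ubp_filter(p, tg)
  ref <- 2 * sin(w * tg) - 2 * tg * w * cos(w * tg)
  core <- 3:(length(tg) - 2)
  expect_equal(b[core], ref[core], tolerance = 0.02 * max(abs(ref)))
  expect_error(ubp_filter(c(1, 2), c(0, 1)), "3 samples")
})

test_that("back-projection is linear and maps zero to zero", {
  sc <- point_scan(n_frames = 6)
  pr <- preprocess_scan(sc, window = 1)
  g <- volume_grid(c(1, 3), c(-1, 1), c(-1, 1), 0.25)
  arr <- detector_array()
  v <- backproject(pr, arr, g)
  pr0 <- pr; pr0$pa_frames <- pr$pa_frames * 0
  expect_equal(backproject(pr0, arr, g)$data, v$data * 0)
  pr3 <- pr; pr3$pa_frames <- pr$pa_frames * 3
  expect_equal(backproject(pr3, arr, g)$data, 3 * v$data, tolerance = 1e-12)
})

test_that("optimised back-projection equals the naive reference", {
  arr <- detector_array(n_elements = 8)
  ph <- phantom(list(sphere_absorber(c(1.5, -1, 0.5), 0.2, 1)))
  sc <- simulate_scan(ph, arr, tiny_acq(1024), tiny_schedule(8), seed = 3,
                      energy_jitter = 0, n_sub = 1)
  pr <- preprocess_scan(sc, window = 1)
  g <- volume_grid(c(-2, 2), c(-2, 2), c(-2, 2), 0.27)
  for (wgt in c("solid_angle", "uniform")) {
    fast <- backproject(pr, arr, g, weighting = wgt)
    ref <- backproject_naive(pr, arr, g, weighting = wgt)
    expect_equal(fast$data, ref$data, tolerance = 1e-6)
  }
})

test_that("a noiseless point source reconstructs at its true position", {
  sc <- point_scan(center = c(2, 0, 0), n_frames = 30)
  pr <- preprocess_scan(sc, window = 1)
  g <- volume_grid(c(0, 4), c(-2, 2), c(-1, 1), 0.1)
  v <- backproject(pr, detector_array(), g)
  expect_equal(peak_position(v), c(2, 0, 0), tolerance = 0.101)
})

test_that("reconstruction is rotationally covariant", {
  g <- volume_grid(c(-4, 4), c(-4, 4), c(-0.5, 0.5), 0.2)
  arr <- detector_array()
  v0 <- backproject(preprocess_scan(point_scan(c(3, 0, 0), n_frames = 24),
                                    window = 1), arr, g)
  v90 <- backproject(preprocess_scan(point_scan(c(0, 3, 0), n_frames = 24),
                                     window = 1), arr, g)
  p0 <- peak_position(v0); p90 <- peak_position(v90)
  # rotating the phantom by 90 deg rotates the peak by 90 deg
  expect_equal(p90, c(-p0[2], p0[1], p0[3]), tolerance = 0.21)
})

test_that("two point sources 4 mm apart reconstruct 4 mm apart", {
  ph <- phantom(list(sphere_absorber(c(-2, 0, 0), 0.05, 1),
                     sphere_absorber(c(2, 0, 0), 0.05, 1)))
  sc <- simulate_scan(ph, detector_array(), tiny_acq(), tiny_schedule(30),
                      seed = 2, energy_jitter = 0, n_sub = 1)
  pr <- preprocess_scan(sc, window = 1)
  g <- volume_grid(c(-3, 3), c(-1, 1), c(-0.4, 0.4), 0.1)
  v <- backproject(pr, detector_array(), g)
  xprof <- extract_line_profile(v, c(-3, 0, 0), c(3, 0, 0), 61)$value
  pk <- which(diff(sign(diff(xprof))) == -2) + 1
  pk <- pk[order(xprof[pk], decreasing = TRUE)][1:2]
  expect_equal(abs(diff(sort(pk))) * 0.1, 4, tolerance = 0.11)
})

test_that("reconstruct_pat honours the requested voxel sizes", {
  sc <- point_scan(n_frames = 6)
  roi <- list(xlim = c(1.6, 2.4), ylim = c(-0.4, 0.4), zlim = c(-0.4, 0.4))
  v <- reconstruct_pat(sc, voxel_size = 0.1, roi = roi)
  expect_equal(v$voxel_size, c(0.1, 0.1, 0.1))
  vhr <- reconstruct_pat(sc, voxel_size = 0.02, roi = roi)
  expect_equal(vhr$voxel_size, c(0.02, 0.02, 0.02))
  expect_equal(vhr$wavelength, 800)
})

test_that("cuvette amplitudes are linear in the absorption coefficient", {
  # five-level sensitivity phantom, noiseless: mean target inclusion vs mu_a
  # must fit a line through the origin with r^2 >= 0.999.  Needs an adequate
  # view count: angular streaks from too few frames add a common pedestal
  arr <- detector_array()
  ph <- sensitivity_phantom()
  sc <- simulate_scan(ph, arr, tiny_acq(2304), tiny_schedule(240), seed = 4,
                      energy_jitter = 0, n_sub = 2, oversample = 1)
  pr <- preprocess_scan(sc, window = 1)
  tg <- (seq_len(dim(pr$pa_frames)[1]) - 1) / pr$sampling_rate
  for (f in seq_len(dim(pr$pa_frames)[3]))
    pr$pa_frames[, , f] <- ubp_filter(pr$pa_frames[, , f], tg)
  conc <- ph$concentrations_mM
  inc <- vapply(seq_along(ph$absorbers), function(i) {
    ctr <- ph$absorbers[[i]]$center[1:2]
    g <- volume_grid(ctr[1] + c(-0.8, 0.8), ctr[2] + c(-0.8, 0.8),
                     c(-10, 10), voxel_size = c(0.1, 0.1, 2))
    v <- backproject(pr, arr, g, filter = "none")
    mean_target_inclusion(v, cylinder_mask(v, ctr, 0.405, z_max = 10))
  }, 0)
  fit <- fit_linear_origin(cuso4_mu_a(conc[conc > 0]), inc[conc > 0])
  expect_gte(fit$r_squared, 0.999)
  # the water control carries no signal
  expect_lt(abs(inc[conc == 0]), 0.02 * max(inc))
})

test_that("injected curvature tolerance degrades longitudinal resolution", {
  # uncompensated arc-curvature error elongates targets along the rotation
  # axis (the dual-peak artifact); the transverse plane is less affected
  arr <- detector_array()
  zfwhm <- function(curv) {
    tru <- if (curv > 0) perturb_array(arr, curvature_error = curv) else NULL
    sc <- point_scan(c(4, 0, 0), n_frames = 24, array_true = tru)
    pr <- preprocess_scan(sc, window = 1)
    g <- volume_grid(c(3.2, 4.8), c(-0.1, 0.1), c(-1.5, 1.5),
                     voxel_size = c(0.02, 0.1, 0.02))
    v <- backproject(pr, arr, g)
    f <- fit_gaussian_fwhm(extract_line_profile(v, c(4, 0, -1.4),
                                                c(4, 0, 1.4), 141))
    f$fwhm
  }
  f0 <- zfwhm(0); f1 <- zfwhm(1.5)
  expect_gt(f1, 1.5 * f0)
})
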