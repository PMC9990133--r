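test_that("spherical source produces the analytic N-wave", {
  ab <- sphere_absorber(c(0, 0, 0), radius = 0.4, mu_a = 1)
  med <- medium(sound_speed = 1500)
  tg <- seq(0, 102.4, by = 1 / 40)  # 40 MHz grid, microseconds
  p <- forward_pressure(ab, c(65, 0, 0), tg, med)
  # arrival centred at 65 mm / 1.5 mm/us = 43.33 us ~ sample 1733 (0-based):
  # the bipolar pulse crosses zero at its centre
  i_on <- min(which(p != 0)); i_off <- max(which(p != 0))
  expect_equal((i_on + i_off) / 2, 43.3333 * 40 + 1, tolerance = 1)
  # support width 2 a / c
  expect_equal((i_off - i_on) / 40, 2 * 0.4 / 1.5, tolerance = 0.06)
  # leading compression, trailing rarefaction
  expect_gt(p[i_on + 1], 0)
  expect_lt(p[i_off - 1], 0)
  # linearity in mu_a
  p2 <- forward_pressure(sphere_absorber(c(0, 0, 0), 0.4, 2), c(65, 0, 0), tg, med)
  expect_equal(p2, 2 * p)
  # zero time integral (discretization-limited at the pulse edges)
  expect_lt(abs(sum(p)), 0.05 * sum(abs(p)))
  # halving the distance doubles the peak amplitude (before bandpass)
  p_half <- forward_pressure(ab, c(32.5, 0, 0), tg, med)
  expect_equal(max(abs(p_half)) / max(abs(p)), 2, tolerance = 0.02)
  expect_error(forward_pressure(ab, c(0.1, 0, 0), tg, med), "inside")
})

test_that("transducer band-pass has the specified -6 dB fractional bandwidth", {
  f <- seq(0, 20, by = 0.001)
  H <- bandpass_response(f)
  lvl <- max(H) * 10^(-6 / 20)
  band <- range(f[H >= lvl])
  expect_equal(diff(band) / 6, 0.55, tolerance = 0.01)
  # measured through apply_instrument on an impulse (low-pass disabled)
  arr <- detector_array()
  acq <- acquisition_config(hardware_lowpass = Inf)
  x <- matrix(0, 4096, 1); x[2048, 1] <- 1
  y <- apply_instrument(x, arr, acq)
  spec <- abs(stats::fft(y[, 1]))[1:2048]
  fg <- (0:2047) / 4096 * 40
  lvl <- max(spec) * 10^(-6 / 20)
  bw <- diff(range(fg[spec >= lvl]))
  expect_equal(bw / 6, 0.55, tolerance = 0.01)
})

test_that("instrument chain is deterministic without noise and scales with it", {
  arr <- detector_array()
  acq <- acquisition_config()
  x <- matrix(rnorm(4096 * 4), 4096, 4)
  expect_identical(apply_instrument(x, arr, acq),
                   apply_instrument(x, arr, acq))
  # doubling the noise sigma doubles a signal-free region's sd
  z <- matrix(0, 4096, 8)
  n1 <- apply_instrument(z, arr, acq, noise_sigma = 1, seed = 3)
  n2 <- apply_instrument(z, arr, acq, noise_sigma = 2, seed = 3)
  expect_equal(sd(n2) / sd(n1), 2, tolerance = 1e-6)
})

test_that("simulated scans are superposable, periodic and seed-reproducible", {
  arr <- detector_array()
  acq <- tiny_acq()
  sch <- tiny_schedule(4)
  a1 <- sphere_absorber(c(2, 0, 0), 0.1, 1)
  a2 <- sphere_absorber(c(-3, 1, 2), 0.15, 0.5)
  sim <- function(abs_list, ...)
    simulate_scan(phantom(abs_list), arr, acq, sch, seed = 5,
                  energy_jitter = 0, n_sub = 2, ...)
  both <- sim(list(a1, a2))
  expect_equal(dim(both$pa_frames)[3], sch$n_frames)
  expect_equal(both$pa_frames,
               sim(list(a1))$pa_frames + sim(list(a2))$pa_frames,
               tolerance = 1e-12)
  # frame at 0 deg equals frame at 360 deg for a static phantom
  per <- simulate_scan(phantom(list(a1)), arr, acq, tiny_schedule(2),
                       seed = 1, energy_jitter = 0, n_sub = 2,
                       angles_deg = c(0, 360))
  expect_equal(per$pa_frames[, , 1], per$pa_frames[, , 2], tolerance = 1e-9)
  # bit-identical under a fixed seed, including noise
  s1 <- simulate_scan(phantom(list(a1)), arr, acq, sch, seed = 11,
                      noise_sigma = 0.01, n_sub = 1)
  s2 <- simulate_scan(phantom(list(a1)), arr, acq, sch, seed = 11,
                      noise_sigma = 0.01, n_sub = 1)
  expect_identical(s1$pa_frames, s2$pa_frames)
  expect_identical(s1$pulse_energies, s2$pulse_energies)
})

test_that("motor log is asynchronous with the frame clock and spans the scan", {
  sc <- point_scan(n_frames = 6)
  expect_false(any(sc$motor_log$time %in% sc$frame_timestamps))
  expect_lte(min(sc$motor_log$time), min(sc$frame_timestamps))
  expect_gte(max(sc$motor_log$time), max(sc$frame_timestamps))
  expect_true(all(diff(sc$motor_log$time) > 0))
  expect_true(all(sc$pulse_energies > 0))
})

test_that("scattering attenuation scales photoacoustic amplitudes", {
  arr <- detector_array()
  acq <- tiny_acq(); sch <- tiny_schedule(2)
  ab <- list(sphere_absorber(c(3, 0, 0), 0.1, 1))
  full <- simulate_scan(phantom(ab), arr, acq, sch, seed = 1,
                        energy_jitter = 0, n_sub = 1)
  half <- simulate_scan(phantom(ab, scattering_attenuation = 0.5), arr, acq,
                        sch, seed = 1, energy_jitter = 0, n_sub = 1)
  expect_equal(half$pa_frames, 0.5 * full$pa_frames, tolerance = 1e-12)
})

test_that("fluorescence projection geometry follows the rotation", {
  cam <- camera_model(pixels = c(128, 128))
  angs <- seq(0, 350, by = 10)
  sch <- rotation_schedule(10, 360, length(angs) / 36)
  # on-axis emitter: projected centroid fixed
  ph0 <- phantom(list(sphere_absorber(c(0, 0, 0), 0.1, 1)),
                 emitters = data.frame(x = 0, y = 0, z = 3,
                                       concentration = 1))
  fl0 <- simulate_fl_scan(ph0, cam, sch, noise = FALSE, angles_deg = angs)
  cent <- apply(fl0, 3, function(img) {
    cs <- colSums(img); sum(cs * seq_along(cs)) / sum(cs)
  })
  expect_lt(diff(range(cent)), 1e-6)
  # off-axis emitter: column trace is a sinusoid of amplitude r / pitch
  r <- 5
  ph1 <- phantom(list(sphere_absorber(c(0, 0, 0), 0.1, 1)),
                 emitters = data.frame(x = r, y = 0, z = 0,
                                       concentration = 1))
  fl1 <- simulate_fl_scan(ph1, cam, sch, noise = FALSE, angles_deg = angs)
  cent1 <- apply(fl1, 3, function(img) {
    cs <- colSums(img); sum(cs * seq_along(cs)) / sum(cs)
  })
  fitamp <- function(th, y) {
    X <- cbind(sin(th), cos(th), 1)
    cf <- qr.solve(X, y)
    sqrt(cf[1]^2 + cf[2]^2)
  }
  amp <- fitamp(angs * pi / 180, cent1)
  expect_equal(amp, r / cam$pixel_pitch[1], tolerance = 0.01)
  # residual from a pure sinusoid is tiny
  # total intensity proportional to concentration
  ph2 <- ph1; ph2$emitters$concentration <- 3
  fl2 <- simulate_fl_scan(ph2, cam, sch, noise = FALSE, angles_deg = angs)
  expect_equal(sum(fl2), 3 * sum(fl1), tolerance = 1e-9)
})
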