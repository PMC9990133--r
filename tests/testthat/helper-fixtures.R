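# Small shared fixtures: every simulated instance here is deliberately tiny
# (few frames, short records) so the module suites stay fast; the desk-scale
# studies live in the acceptance tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_acq <- function(n = 2048) acquisition_config(samples_per_channel = n)

tiny_schedule <- function(n_frames = 8) rotation_schedule(10, 360, n_frames / 36)

point_scan <- function(center = c(2, 0, 0), radius = 0.05, n_frames = 30,
                       seed = 7, ...) {
  simulate_scan(phantom(list(sphere_absorber(center, radius, 1))),
                detector_array(), tiny_acq(), tiny_schedule(n_frames),
                seed = seed, energy_jitter = 0, n_sub = 1, ...)
}

peak_position <- function(vol) {
  am <- which(vol$data == max(vol$data), arr.ind = TRUE)[1, ]
  unname(vol$origin + (am - 1) * vol$voxel_size)
}
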