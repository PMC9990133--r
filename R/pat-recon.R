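#' Reconstructed volume container
#'
#' A 3D scalar grid in the sample frame.  `data[i, j, k]` lives at world
#' coordinate `origin + (c(i, j, k) - 1) * voxel_size` (mm), axes (x, y, z).
#'
#' @param data 3D numeric array.
#' @param voxel_size Voxel size in mm, scalar or per-axis length-3.
#' @param origin World coordinate of the centre of voxel `[1, 1, 1]`, mm.
#' @param wavelength Optional acquisition wavelength, nm.
#' @return An object of class `pa_volume`.
#' @export
volume <- function(data, voxel_size, origin = c(0, 0, 0), wavelength = NA) {
  stopifnot(length(dim(data)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("'voxel_size' must be positive", call. = FALSE)
  if (!all(is.finite(data))) stop("volume data must be finite", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin), wavelength = wavelength),
            class = "pa_volume")
}

#' @export
print.pa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pa_volume> %d x %d x %d voxels at %s mm, origin (%s) mm\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Axis coordinates of a volume
#' @param vol A `pa_volume`.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return Numeric vector of voxel-centre coordinates in mm.
#' @export
volume_axis <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$voxel_size[axis]
}

#' Regular voxel-grid specification
#'
#' @param xlim,ylim,zlim Extents in mm (voxel centres span these inclusively).
#' @param voxel_size mm, scalar or per-axis.
#' @return A list with `coords` (list of axis coordinate vectors),
#'   `voxel_size` and `origin`, accepted by [backproject()].
#' @export
volume_grid <- function(xlim, ylim, zlim, voxel_size = 0.1) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  coords <- list(seq(xlim[1], xlim[2], by = voxel_size[1]),
                 seq(ylim[1], ylim[2], by = voxel_size[2]),
                 seq(zlim[1], zlim[2], by = voxel_size[3]))
  list(coords = coords, voxel_size = voxel_size,
       origin = c(xlim[1], ylim[1], zlim[1]))
}

#' Back-projection filter
#'
#' Universal-back-projection-style filtered trace
#' `b(t) = 2 p(t) - 2 t dp/dt`, the standard exact-geometry-inspired filter
#' for spherical detection surfaces, with a central-difference time
#' derivative (one-sided at the record ends).
#'
#' @param trace Numeric vector, matrix (samples x channels) or 3D array;
#'   filtering runs along the first (time) dimension.
#' @param time_grid Uniform sample times in microseconds.
#' @return Filtered data, same shape.
#' @export
ubp_filter <- function(trace, time_grid) {
  n <- length(time_grid)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  dt <- time_grid[2] - time_grid[1]
  dims <- dim(trace)
  m <- if (is.null(dims)) matrix(trace, ncol = 1) else matrix(trace, nrow = n)
  dp <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 2), n - 1), , drop = FALSE]) /
    (dt * c(1, rep(2, n - 2), 1))
  out <- 2 * m - 2 * time_grid * dp
  if (is.null(dims)) as.numeric(out) else array(out, dim = dims)
}

.grid_voxels <- function(grid) {
  cx <- grid$coords[[1]]; cy <- grid$coords[[2]]; cz <- grid$coords[[3]]
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  cbind(rep(cx, times = ny * nz),
        rep(rep(cy, each = nx), times = nz),
        rep(cz, each = nx * ny))
}

#' Delay-and-sum back-projection onto a voxel grid
#'
#' For each voxel, sums the (filtered) traces of every (frame, element) pair
#' sampled by linear interpolation at the acoustic delay
#' `t = |voxel - element_position(frame angle)| / c`, weighted by the solid
#' angle the element subtends at the voxel (`element area * cos(incidence) /
#' d^2`; uniform weighting available), and normalises by the total weight.
#' The reconstruction is performed in the sample frame: each frame's elements
#' are rotated by minus the frame angle.  Contributions whose delay falls
#' outside the recorded window are skipped and counted.
#'
#' @param processed A `processed_scan` from [preprocess_scan()] (or a
#'   compatible list with `pa_frames`, `angles_deg`, `sampling_rate`).
#' @param array The (nominal) [detector_array()].
#' @param grid A [volume_grid()].
#' @param sound_speed Speed of sound in m/s (default: from the scan's medium).
#' @param filter `"ubp"` (default) applies [ubp_filter()] to all traces
#'   first; `"none"` back-projects the traces as given.
#' @param weighting `"solid_angle"` (default) or `"uniform"`.
#' @return A [volume()]; attributes `coverage` (total weight per voxel) and
#'   `n_skipped` record sampling coverage, and voxels with no valid
#'   contribution are 0.
#' @export
backproject <- function(processed, array, grid, sound_speed = NULL,
                        filter = c("ubp", "none"),
                        weighting = c("solid_angle", "uniform")) {
  filter <- match.arg(filter)
  weighting <- match.arg(weighting)
  if (is.null(sound_speed))
    sound_speed <- speed_of_sound(processed$config$medium)
  c_mm_us <- sound_speed / 1000
  fs <- processed$sampling_rate
  tr <- processed$pa_frames
  stopifnot(length(dim(tr)) == 3, length(processed$angles_deg) == dim(tr)[3])
  if (filter == "ubp") {
    tg <- (seq_len(dim(tr)[1]) - 1) / fs
    tr <- ubp_filter(tr, tg)
  }
  vox <- .grid_voxels(grid)
  res <- cpp_backproject(tr, dim(tr), array$element_positions,
                         processed$angles_deg * pi / 180, vox,
                         c_mm_us, fs, weighting == "solid_angle",
                         array$element_width * array$element_height)
  nx <- length(grid$coords[[1]]); ny <- length(grid$coords[[2]])
  nz <- length(grid$coords[[3]])
  vol <- volume(array(res$values, dim = c(nx, ny, nz)),
                voxel_size = grid$voxel_size, origin = grid$origin)
  attr(vol, "coverage") <- array(res$weight, dim = c(nx, ny, nz))
  attr(vol, "n_skipped") <- res$n_skipped
  vol
}

#' Reference back-projection (naive triple loop)
#'
#' Independent plain-R implementation of the same delay-and-sum used to
#' validate the optimised path on small instances.
#'
#' @inheritParams backproject
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A [volume()].
#' @export
backproject_naive <- function(processed, array, grid, sound_speed = NULL,
                              filter = c("ubp", "none"),
                              weighting = c("solid_angle", "uniform"),
                              interpolation = c("linear", "nearest")) {
  filter <- match.arg(filter)
  weighting <- match.arg(weighting)
  interpolation <- match.arg(interpolation)
  if (is.null(sound_speed))
    sound_speed <- speed_of_sound(processed$config$medium)
  c_mm_us <- sound_speed / 1000
  fs <- processed$sampling_rate
  tr <- processed$pa_frames
  if (filter == "ubp")
    tr <- ubp_filter(tr, (seq_len(dim(tr)[1]) - 1) / fs)
  n_samp <- dim(tr)[1]; n_el <- dim(tr)[2]; n_frames <- dim(tr)[3]
  cx <- grid$coords[[1]]; cy <- grid$coords[[2]]; cz <- grid$coords[[3]]
  acc <- array(0, dim = c(length(cx), length(cy), length(cz)))
  wsum <- acc
  area <- array$element_width * array$element_height
  for (f in seq_len(n_frames)) {
    th <- -processed$angles_deg[f] * pi / 180
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    epos <- array$element_positions %*% t(Rz)
    for (e in seq_len(n_el)) {
      p <- epos[e, ]
      nrm <- -p / sqrt(sum(p^2))
      for (i in seq_along(cx)) for (j in seq_along(cy)) for (k in seq_along(cz)) {
        dv <- c(cx[i], cy[j], cz[k]) - p
        d <- sqrt(sum(dv^2))
        ti <- d / c_mm_us * fs + 1  # 1-based fractional sample
        if (ti < 1 || ti >= n_samp) next
        val <- if (interpolation == "nearest") tr[round(ti), e, f] else {
          i0 <- floor(ti)
          tr[i0, e, f] * (1 - (ti - i0)) + tr[i0 + 1, e, f] * (ti - i0)
        }
        w <- if (weighting == "solid_angle")
          area * max(sum(dv * nrm) / d, 0) / d^2 else 1
        acc[i, j, k] <- acc[i, j, k] + w * val
        wsum[i, j, k] <- wsum[i, j, k] + w
      }
    }
  }
  out <- ifelse(wsum > 0, acc / wsum, 0)
  vol <- volume(out, voxel_size = grid$voxel_size, origin = grid$origin)
  attr(vol, "coverage") <- wsum
  vol
}

#' Photoacoustic tomography reconstruction
#'
#' Full chain: signal conditioning ([preprocess_scan()]), back-projection
#' filtering ([ubp_filter()]) and delay-and-sum ([backproject()]).  Standard
#' resolution uses 0.1 mm isotropic voxels; high-resolution mode uses 0.02 mm
#' voxels on a restricted region of interest.
#'
#' @param scan A `scan_data`.
#' @param voxel_size Voxel size in mm (scalar or per-axis); 0.1 default,
#'   0.02 for HR.
#' @param roi List with `xlim`, `ylim`, `zlim` in mm (default a 20 mm cube
#'   about the origin).
#' @param window Running-average window (default 5).
#' @param weighting See [backproject()].
#' @param sound_speed Optional override, m/s.
#' @return A [volume()] carrying the scan wavelength.
#' @export
reconstruct_pat <- function(scan, voxel_size = 0.1,
                            roi = list(xlim = c(-10, 10), ylim = c(-10, 10),
                                       zlim = c(-10, 10)),
                            window = 5, weighting = "solid_angle",
                            sound_speed = NULL) {
  proc <- preprocess_scan(scan, window = window)
  grid <- volume_grid(roi$xlim, roi$ylim, roi$zlim, voxel_size)
  vol <- backproject(proc, scan$config$array, grid, sound_speed = sound_speed,
                     weighting = weighting)
  vol$wavelength <- scan$wavelength
  vol
}
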