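#' Sinogram container
#'
#' One transverse row of the multi-angle fluorescence stack: intensities of a
#' fixed image row collected across all frames, ordered by rotation angle.
#'
#' @param data Matrix (n_angles x n_columns) of intensities (per-pixel
#'   integrated counts).
#' @param angles_deg Frame angles in degrees (the interpolated motor angles
#'   shared with the photoacoustic reconstruction).
#' @param column_pitch Camera pixel pitch at the focal plane, mm.
#' @param z_row Height of the row at the focal plane, mm.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(data, angles_deg, column_pitch, z_row = 0) {
  stopifnot(is.matrix(data), nrow(data) == length(angles_deg))
  structure(list(data = data, angles_deg = angles_deg,
                 column_pitch = column_pitch, z_row = z_row),
            class = "sinogram")
}

#' Build per-row sinograms from a fluorescence frame stack
#'
#' @param fl_frames Array (rows x cols x frames) as produced by
#'   [simulate_fl_scan()] (rows top to bottom, +z to -z).
#' @param angles_deg One angle per frame, degrees.
#' @param camera The [camera_model()] (provides the pixel pitch).
#' @param rows Which image rows to extract (default all).
#' @return A list of [sinogram()] objects, one per requested row.
#' @export
build_sinograms <- function(fl_frames, angles_deg, camera, rows = NULL) {
  d <- dim(fl_frames)
  if (length(angles_deg) != d[3])
    stop("frame count and angle count differ", call. = FALSE)
  if (is.null(rows)) rows <- seq_len(d[1])
  zc <- ((d[1] + 1) / 2 - rows) * camera$pixel_pitch[2]
  lapply(seq_along(rows), function(i) {
    sinogram(t(fl_frames[rows[i], , ]), angles_deg,
             column_pitch = camera$pixel_pitch[1], z_row = zc[i])
  })
}

#' Forward parallel-beam projection (x-ray transform) of a slice
#'
#' Orthographic projection used by the round-trip validation of the inverse:
#' at angle `theta` the projection coordinate of a point `(x, y)` is
#' `s = x sin(theta) + y cos(theta)`, matching the camera geometry of
#' [simulate_fl_scan()].  Pixel values are deposited onto the detector
#' columns with linear splitting; the output is in per-column integrated
#' units (line integral x pitch).
#'
#' @param image Matrix (nx x ny) with `image[i, j]` at `(xcoord[i], ycoord[j])`.
#' @param xcoord,ycoord Pixel-centre coordinates, mm.
#' @param angles_deg Projection angles, degrees.
#' @param n_columns Number of detector columns.
#' @param column_pitch Detector column pitch, mm.
#' @return Matrix (n_angles x n_columns).
#' @export
radon_forward <- function(image, xcoord, ycoord, angles_deg,
                          n_columns, column_pitch) {
  stopifnot(nrow(image) == length(xcoord), ncol(image) == length(ycoord))
  px <- rep(xcoord, times = length(ycoord))
  py <- rep(ycoord, each = length(xcoord))
  # pixel mass lands in a column of width `column_pitch`, so per-column
  # integrated units are just the deposited mass
  vals <- as.numeric(image) * (xcoord[2] - xcoord[1]) * (ycoord[2] - ycoord[1])
  cen <- (n_columns + 1) / 2
  out <- matrix(0, length(angles_deg), n_columns)
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    s <- (px * sin(th) + py * cos(th)) / column_pitch + cen
    i0 <- floor(s); fr <- s - i0
    ok <- i0 >= 1 & i0 < n_columns
    out[a, ] <- out[a, ] +
      tabulate_w(i0[ok], vals[ok] * (1 - fr[ok]), n_columns) +
      tabulate_w(i0[ok] + 1L, vals[ok] * fr[ok], n_columns)
  }
  out
}

# weighted tabulate
tabulate_w <- function(bin, w, nbins) {
  as.numeric(unname(rowsum(c(w, rep(0, nbins)), c(bin, seq_len(nbins)))))
}

#' Invert one sinogram by filtered back-projection
#'
#' Hann-windowed ramp-filtered parallel-beam back-projection over all
#' available angles; full 360 degree data is handled naturally (conjugate
#' views average).  The ramp cutoff sits at the detector Nyquist frequency.
#'
#' @param sino A [sinogram()].
#' @param xcoord,ycoord Output slice pixel-centre coordinates, mm.
#' @param window `"hann"` (default) or `"ramp"` (no apodisation).
#' @return Matrix (length(xcoord) x length(ycoord)); negative values are
#'   preserved (clipping happens only at export).
#' @export
invert_slice <- function(sino, xcoord, ycoord, window = c("hann", "ramp")) {
  window <- match.arg(window)
  stopifnot(inherits(sino, "sinogram"))
  if (length(unique(sino$angles_deg)) < 2)
    stop("need at least 2 distinct angles", call. = FALSE)
  p <- sino$data / sino$column_pitch  # to line-integral units
  n_ang <- nrow(p); n_col <- ncol(p)
  npad <- 2^ceiling(log2(2 * n_col))
  pp <- cbind(p, matrix(0, n_ang, npad - n_col))
  nu <- (seq_len(npad) - 1) / npad / sino$column_pitch
  nu <- ifelse(nu > 1 / (2 * sino$column_pitch), nu - 1 / sino$column_pitch, nu)
  nyq <- 1 / (2 * sino$column_pitch)
  H <- abs(nu)
  if (window == "hann") H <- H * 0.5 * (1 + cos(pi * nu / nyq))
  q <- t(Re(stats::mvfft(stats::mvfft(t(pp)) * H, inverse = TRUE)) / npad)
  q <- q[, seq_len(n_col), drop = FALSE]
  cen <- (n_col + 1) / 2
  out <- matrix(0, length(xcoord), length(ycoord))
  px <- rep(xcoord, times = length(ycoord))
  py <- rep(ycoord, each = length(xcoord))
  for (a in seq_len(n_ang)) {
    th <- sino$angles_deg[a] * pi / 180
    s <- (px * sin(th) + py * cos(th)) / sino$column_pitch + cen
    i0 <- floor(s); fr <- s - i0
    i0 <- pmin(pmax(i0, 1), n_col - 1)
    out <- out + matrix(q[a, i0] * (1 - fr) + q[a, i0 + 1] * fr,
                        length(xcoord), length(ycoord))
  }
  out * pi / n_ang
}

#' Fluorescence molecular tomography reconstruction
#'
#' Stacks per-row inverse x-ray transforms of the multi-angle frame stack
#' into a 3D volume.  The default grid matches the camera field of view:
#' 40 x 40 x 40 mm at 0.1 mm voxels (reduced grids are used for desk-scale
#' work by passing `xlim`/`ylim`/`voxel_size`).  Because the projection model
#' is orthographic, image rows are independent and reconstruct independent
#' transverse slices.
#'
#' @param fl_frames Array (rows x cols x frames).
#' @param angles_deg One angle per frame, degrees.
#' @param camera The [camera_model()].
#' @param xlim,ylim In-plane extents, mm.
#' @param voxel_size In-plane voxel size, mm (default 0.1); the slice spacing
#'   is the camera's vertical pixel pitch.
#' @param rows Image rows to reconstruct (default all).
#' @param window Filter window, see [invert_slice()].
#' @return A [volume()] (negative values preserved).
#' @export
reconstruct_fmt <- function(fl_frames, angles_deg, camera,
                            xlim = c(-20, 20), ylim = c(-20, 20),
                            voxel_size = 0.1, rows = NULL,
                            window = "hann") {
  d <- dim(fl_frames)
  if (is.null(rows)) rows <- seq_len(d[1])
  sinos <- build_sinograms(fl_frames, angles_deg, camera, rows)
  xc <- seq(xlim[1], xlim[2], by = voxel_size)
  yc <- seq(ylim[1], ylim[2], by = voxel_size)
  zc <- vapply(sinos, function(s) s$z_row, 0)
  dat <- array(0, dim = c(length(xc), length(yc), length(rows)))
  ord <- order(zc)  # ascending z for the volume axis
  for (k in seq_along(ord))
    dat[, , k] <- invert_slice(sinos[[ord[k]]], xc, yc, window = window)
  vol <- volume(dat, voxel_size = c(voxel_size, voxel_size,
                                    camera$pixel_pitch[2]),
                origin = c(xlim[1], ylim[1], min(zc)))
  vol
}
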