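#' Write / read a raw-scan container
#'
#' Scans are stored as a self-describing directory container with one group
#' per data stream — `pa/` (frames, timestamps, gain, wavelength), `motor/`
#' (angle log), `laser/` (per-pulse energies) and optionally `fl/` (camera
#' frames) — plus a JSON metadata file and a serialized configuration
#' snapshot, so the round trip is lossless field for field.  Frame arrays are
#' written as IEEE doubles with recorded dimensions and byte order.
#'
#' @param scan A `scan_data` object.
#' @param path Container directory (created; must not already contain a scan).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "scan_data"))
  for (g in c("pa", "motor", "laser")) dir.create(file.path(path, g),
                                                  recursive = TRUE,
                                                  showWarnings = FALSE)
  .write_array <- function(a, f) {
    con <- file(f, "wb"); on.exit(close(con))
    writeBin(as.numeric(a), con, size = 8, endian = "little")
  }
  .write_array(scan$pa_frames, file.path(path, "pa", "frames.bin"))
  meta <- list(dims = dim(scan$pa_frames),
               frame_timestamps = scan$frame_timestamps,
               gain_db = scan$gain_db, wavelength = scan$wavelength,
               config_hash = config_hash(scan$config))
  jsonlite::write_json(meta, file.path(path, "pa", "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(scan$motor_log, file.path(path, "motor", "log.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(energy_mJ = scan$pulse_energies),
                   file.path(path, "laser", "energies.csv"), row.names = FALSE)
  if (!is.null(scan$fl_frames)) {
    dir.create(file.path(path, "fl"), showWarnings = FALSE)
    .write_array(scan$fl_frames, file.path(path, "fl", "frames.bin"))
    jsonlite::write_json(list(dims = dim(scan$fl_frames),
                              angles_deg = attr(scan$fl_frames, "angles_deg")),
                         file.path(path, "fl", "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  saveRDS(scan$config, file.path(path, "config.rds"))
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  for (g in c("pa", "motor", "laser"))
    if (!dir.exists(file.path(path, g)))
      stop(sprintf("container schema error: missing group '%s'", g),
           call. = FALSE)
  meta <- jsonlite::read_json(file.path(path, "pa", "meta.json"),
                              simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(file.path(path, "pa", "frames.bin"), "rb")
  frames <- array(readBin(con, "double", n, size = 8, endian = "little"),
                  dim = meta$dims)
  close(con)
  motor <- utils::read.csv(file.path(path, "motor", "log.csv"))
  energies <- utils::read.csv(file.path(path, "laser", "energies.csv"))$energy_mJ
  fl <- NULL
  if (dir.exists(file.path(path, "fl"))) {
    fm <- jsonlite::read_json(file.path(path, "fl", "meta.json"),
                              simplifyVector = TRUE)
    con <- file(file.path(path, "fl", "frames.bin"), "rb")
    fl <- array(readBin(con, "double", prod(fm$dims), size = 8,
                        endian = "little"), dim = fm$dims)
    close(con)
    attr(fl, "angles_deg") <- fm$angles_deg
  }
  structure(list(pa_frames = frames,
                 frame_timestamps = meta$frame_timestamps,
                 motor_log = motor, pulse_energies = energies,
                 wavelength = meta$wavelength, gain_db = meta$gain_db,
                 fl_frames = fl,
                 config = readRDS(file.path(path, "config.rds"))),
            class = "scan_data")
}

#' Hash of a configuration snapshot
#'
#' MD5 digest of the canonical JSON serialisation, embedded in every artifact
#' so a run is traceable to its exact configuration.
#'
#' @param config A configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(config), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Write a reconstructed volume to disk
#'
#' NIfTI output records the voxel spacing (mm) and origin in the header;
#' multipage TIFF writes one page per transverse slice (values min-max
#' normalised to the file range, negative values clipped at export when
#' `clip_negative`).
#'
#' @param vol A [volume()].
#' @param path Output file.
#' @param format `"nifti"` or `"tiff"` (default from the file extension).
#' @param clip_negative Clip negative values to 0 at export (default TRUE for
#'   fluorescence volumes written to TIFF; internal data stay unclipped).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL, clip_negative = TRUE) {
  stopifnot(inherits(vol, "pa_volume"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, nii = "nifti", tif = "tiff", tiff = "tiff",
                     stop("unsupported format: ", ext, call. = FALSE))
  }
  if (format == "nifti") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required for NIfTI output", call. = FALSE)
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$voxel_size
    RNifti::writeNifti(img, path)
  } else if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output", call. = FALSE)
    d <- vol$data
    if (clip_negative) d <- pmax(d, 0)
    rng <- range(d)
    if (diff(rng) > 0) d <- (d - rng[1]) / diff(rng)
    pages <- lapply(seq_len(dim(d)[3]), function(k) t(d[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else stop("unsupported format: ", format, call. = FALSE)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#'
#' @param path NIfTI file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input", call. = FALSE)
  img <- RNifti::readNifti(path)
  volume(array(as.numeric(img), dim = dim(img)),
         voxel_size = RNifti::pixdim(img))
}

#' Read a run configuration from YAML
#'
#' Builds instrument objects from a YAML file whose keys mirror the
#' constructor arguments (`instrument$array`, `instrument$acquisition`,
#' `instrument$camera`, `instrument$medium`, `scan$schedule`); missing keys
#' fall back to the instrument defaults.
#'
#' @param path YAML file.
#' @return A list with `array`, `acq`, `camera`, `medium`, `schedule` and the
#'   raw parsed list under `raw`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(fn, args) do.call(fn, if (is.null(args)) list() else args)
  inst <- raw$instrument
  list(array = build(detector_array, inst$array),
       acq = build(acquisition_config, inst$acquisition),
       camera = build(camera_model, inst$camera),
       medium = build(medium, inst$medium),
       schedule = build(rotation_schedule, raw$scan$schedule),
       raw = raw)
}
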