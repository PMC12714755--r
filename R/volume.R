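#' Construct a reconstructed volume
#'
#' A 3-D grid tagged with voxel spacing and physical units.  Units are one
#' of `"mu_per_mm"` (linear attenuation), `"HU"` (Hounsfield) or
#' `"mg_per_cm3"` (basis-material density).
#'
#' @param values 3-D numeric array `[x, y, z]` (z = axial/rotation axis).
#' @param voxel_mm voxel spacing, scalar (isotropic) or length-3.
#' @param units volume units.
#' @param bin optional energy-bin tag.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(values, voxel_mm,
                      units = c("mu_per_mm", "HU", "mg_per_cm3"),
                      bin = NULL) {
  units <- match.arg(units)
  if (length(dim(values)) != 3L) stopf("volume values must be a 3-D array")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (any(voxel_mm <= 0)) stopf("voxel spacing must be positive")
  if (!all(is.finite(values))) stopf("volume values must be finite")
  structure(list(values = values, voxel_mm = as.numeric(voxel_mm),
                 units = units, bin = bin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.3g mm [%s]%s\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$units,
              if (is.null(x$bin)) "" else paste0(" bin=", x$bin)))
  invisible(x)
}

vol_units <- function(vol) vol$units

#' Export a volume as an axial slice series
#'
#' Writes one file per axial plane, named `<n>.dcm` (or `.raw`) with `n`
#' zero-padded and starting at 00001.  `dicom_series` requires HU units and
#' writes minimal single-frame CT DICOM files (explicit VR little endian,
#' signed 16-bit pixels, rescale slope 1 / intercept 0 so stored values are
#' HU directly).  `raw_stack` writes 32-bit float little-endian slices plus
#' a `volume.yaml` sidecar describing shape, spacing and units.
#'
#' @param vol a [ct_volume].
#' @param out_dir output directory (created if needed).
#' @param format `"dicom_series"` or `"raw_stack"`.
#' @param start_index index of the first slice file name (supports
#'   concatenating several couch volumes into one numbered series).
#' @return Character vector of files written, invisibly.
#' @export
export_volume <- function(vol, out_dir,
                          format = c("dicom_series", "raw_stack"),
                          start_index = 1L) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "ct_volume"))
  if (format == "dicom_series" && vol$units != "HU")
    stopf("dicom_series export requires HU units, got '%s'", vol$units)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(vol$values)[3]
  files <- character(nz)
  for (k in seq_len(nz)) {
    n <- start_index + k - 1L
    slice <- t(vol$values[, , k])  # DICOM rows = y, columns = x
    if (format == "dicom_series") {
      files[k] <- file.path(out_dir, sprintf("%05d.dcm", n))
      write_dicom_slice(slice, files[k], instance = n,
                        pixel_mm = vol$voxel_mm[1:2],
                        slice_mm = vol$voxel_mm[3],
                        z_mm = (k - 1) * vol$voxel_mm[3])
    } else {
      files[k] <- file.path(out_dir, sprintf("%05d.raw", n))
      con <- file(files[k], "wb")
      writeBin(as.numeric(slice), con, size = 4L, endian = "little")
      close(con)
    }
  }
  if (format == "raw_stack") {
    yaml::write_yaml(list(shape = dim(vol$values), voxel_mm = vol$voxel_mm,
                          units = vol$units, dtype = "float32le",
                          slice_axis = 3L),
                     file.path(out_dir, "volume.yaml"))
  }
  invisible(files)
}
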