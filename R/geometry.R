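#' Circular cone-beam scan geometry
#'
#' Flat-panel circular cone-beam geometry: the source rotates about the
#' isocenter at radius `sid_mm`, the detector opposite at `sdd_mm - sid_mm`,
#' with the mid-detector row containing the central ray.  The instrument's
#' full-scale values are the defaults; [desk_geometry()] returns the reduced
#' profile used for CPU-scale work.
#'
#' @param sid_mm source-to-isocenter distance (mm).
#' @param sdd_mm source-to-detector distance (mm).
#' @param pixel_mm detector pixel pitch (mm, square pixels).
#' @param n_channels detector channels (horizontal, fan direction).
#' @param n_rows detector rows (vertical, cone direction).
#' @param n_views number of views over `span_deg`.
#' @param span_deg angular span of the orbit (<= 360).
#' @param couch_spacing_mm axial spacing between successive bed positions.
#' @return A `scan_geometry` object with an `angles_deg` field.
#' @export
scan_geometry <- function(sid_mm = 140, sdd_mm = 325, pixel_mm = 0.1,
                          n_channels = 2063L, n_rows = 505L,
                          n_views = 1440L, span_deg = 360,
                          couch_spacing_mm = 15) {
  if (sid_mm <= 0 || sdd_mm <= sid_mm)
    stopf("need 0 < sid_mm < sdd_mm")
  if (span_deg > 360 + 1e-9) stopf("angular span cannot exceed 360 degrees")
  angles <- seq(0, span_deg, length.out = n_views + 1L)[seq_len(n_views)]
  structure(list(sid_mm = sid_mm, sdd_mm = sdd_mm, pixel_mm = pixel_mm,
                 n_channels = as.integer(n_channels),
                 n_rows = as.integer(n_rows),
                 n_views = as.integer(n_views), span_deg = span_deg,
                 angles_deg = angles, couch_spacing_mm = couch_spacing_mm),
            class = "scan_geometry")
}

#' @rdname scan_geometry
#' @param n_views desk-scale view count.
#' @export
desk_geometry <- function(n_views = 180L) {
  scan_geometry(pixel_mm = 0.75, n_channels = 256L, n_rows = 64L,
                n_views = n_views)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> SID %g / SDD %g mm, %d x %d px @ %g mm, %d views / %g deg\n",
              x$sid_mm, x$sdd_mm, x$n_rows, x$n_channels, x$pixel_mm,
              x$n_views, x$span_deg))
  invisible(x)
}

# lateral field of view at the isocenter (mm)
geometry_fov_mm <- function(geom) {
  geom$n_channels * geom$pixel_mm * geom$sid_mm / geom$sdd_mm
}

# detector pixel centre positions (world mm) for gantry angle `angle_deg`,
# ordered column-major over [rows, channels]
detector_pixel_positions <- function(geom, angle_deg) {
  th <- angle_deg * pi / 180
  w_hat <- c(cos(th), sin(th), 0)
  e_u <- c(-sin(th), cos(th), 0)
  e_v <- c(0, 0, 1)
  center <- (geom$sid_mm - geom$sdd_mm) * w_hat
  u <- (seq_len(geom$n_channels) - (geom$n_channels + 1) / 2) * geom$pixel_mm
  v <- ((geom$n_rows + 1) / 2 - seq_len(geom$n_rows)) * geom$pixel_mm
  uu <- rep(u, each = geom$n_rows)
  vv <- rep(v, times = geom$n_channels)
  cbind(center[1] + uu * e_u[1] + vv * e_v[1],
        center[2] + uu * e_u[2] + vv * e_v[2],
        center[3] + uu * e_u[3] + vv * e_v[3])
}

source_position <- function(geom, angle_deg) {
  th <- angle_deg * pi / 180
  c(geom$sid_mm * cos(th), geom$sid_mm * sin(th), 0)
}
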