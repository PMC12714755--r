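#' Water-based Hounsfield scale calibration
#'
#' Computes the per-bin HU scaling factor `1000 / mu_water` from a
#' reconstructed water-cylinder volume: the mean attenuation inside a
#' region of interest known to be water.
#'
#' @param water_vol a [ct_volume] in `mu_per_mm` units.
#' @param roi list with `radius_mm` (cylinder ROI radius about the volume
#'   centre) and optional `z_half_mm` (axial half-extent, default a quarter
#'   of the volume height); or a logical mask array.
#' @return A `hu_scale`: scalar scale factor (HU * mm) tagged with the bin.
#' @export
hu_scale_from_water <- function(water_vol, roi = list(radius_mm = 10)) {
  stopifnot(inherits(water_vol, "ct_volume"))
  if (water_vol$units != "mu_per_mm")
    stopf("HU calibration needs a mu_per_mm volume")
  if (is.array(roi)) {
    sel <- roi
  } else {
    d <- dim(water_vol$values)
    ax <- phantom_axes(d, water_vol$voxel_mm[1])
    zh <- if (!is.null(roi$z_half_mm)) roi$z_half_mm else
      d[3] * water_vol$voxel_mm[3] / 4
    R2 <- outer(ax[[1]]^2, ax[[2]]^2, "+")
    sel <- array(FALSE, d)
    zok <- abs(ax[[3]]) <= zh
    sel[, , zok] <- R2 <= roi$radius_mm^2
  }
  mu <- mean(water_vol$values[sel])
  if (!is.finite(mu) || mu <= 1e-9)
    stopf("non-positive mean attenuation in ROI (%.3g): not a water region", mu)
  structure(1000 / mu, bin = water_vol$bin, class = "hu_scale")
}

#' Convert attenuation to Hounsfield units
#'
#' `HU = mu * (1000 / mu_water) - 1000`, so water maps to 0 and vacuum to
#' -1000.
#'
#' @param vol a [ct_volume] in `mu_per_mm` units.
#' @param scale a `hu_scale` (or bare positive number, HU * mm).
#' @return A [ct_volume] in HU.
#' @export
to_hounsfield <- function(vol, scale) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$units != "mu_per_mm")
    stopf("HU conversion expects mu_per_mm input, got '%s'", vol$units)
  s <- as.numeric(scale)
  if (!is.finite(s) || s <= 0) stopf("HU scale factor must be positive")
  ct_volume(vol$values * s - 1000, vol$voxel_mm, units = "HU", bin = vol$bin)
}

#' Ring-artifact power of an axial slice
#'
#' Resamples the slice to polar coordinates about `center`, takes the
#' angular mean to get a radial profile, removes the smooth radial
#' component with a local quadratic (Savitzky-Golay) fit of half-width
#' `cutoff` samples -- which passes smooth curved profiles exactly up to
#' second order -- and returns the mean squared high-pass residual:
#' concentric rings of amplitude `a` contribute proportionally to `a^2`,
#' radially smooth content contributes ~nothing.
#'
#' @param slice 2-D matrix (e.g. one plane of a reconstructed volume).
#' @param center `(row, col)` of the rotation centre, default the slice
#'   centre.
#' @param n_theta angular samples per radius.
#' @param cutoff radial high-pass scale in samples (Gaussian sigma).
#' @param r_max_frac largest sampled radius as a fraction of the
#'   half-width.
#' @return Scalar ring power.
#' @export
ring_power_metric <- function(slice, center = NULL, n_theta = 256L,
                              cutoff = 6, r_max_frac = 0.9) {
  nr <- nrow(slice); nc <- ncol(slice)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc)
    stopf("ring metric center (%.1f, %.1f) lies outside the slice",
          center[1], center[2])
  rmax <- r_max_frac * (min(nr, nc) / 2 - 1)
  radii <- seq(1, rmax, by = 0.5)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[seq_len(n_theta)]
  prof <- vapply(radii, function(r) {
    rr <- center[1] + r * sin(th)
    cc <- center[2] + r * cos(th)
    mean(bilinear(slice, rr, cc))
  }, numeric(1))
  # Savitzky-Golay order-2 smoothing kernel, half-width `cutoff`
  hw <- max(2L, as.integer(cutoff))
  x <- -hw:hw
  X <- cbind(1, x, x^2)
  k <- (X %*% solve(crossprod(X), t(X)))[hw + 1L, ]
  padded <- c(rep(prof[1], hw), prof, rep(prof[length(prof)], hw))
  smooth <- stats::filter(padded, k, sides = 2)[(hw + 1):(hw + length(prof))]
  mean((prof - smooth)^2)
}
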