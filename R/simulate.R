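#' Forward-project a phantom for one view
#'
#' Exact Siddon-style ray/voxel traversal from the source through the
#' labelled phantom to every detector pixel centre, returning per-material
#' intersection lengths in mm.
#'
#' @param phantom a [ct_phantom].
#' @param geom a [scan_geometry].
#' @param angle_deg gantry angle in degrees.
#' @return A `path_view`: list with `lengths` (`[n_pixels, n_materials]`
#'   matrix, pixels ordered column-major over `[rows, channels]`),
#'   `materials`, detector shape and the angle.
#' @export
forward_paths <- function(phantom, geom, angle_deg) {
  if (2 * phantom$support_radius_mm > geometry_fov_mm(geom) + 1e-9)
    warnf("phantom extent (%.1f mm) exceeds the lateral FOV (%.1f mm); projections will be truncated",
          2 * phantom$support_radius_mm, geometry_fov_mm(geom))
  n_mat <- length(phantom$materials)
  lengths <- .cpp_siddon_forward(
    as.integer(phantom$labels), dim(phantom$labels), phantom$voxel_mm,
    n_mat, source_position(geom, angle_deg),
    detector_pixel_positions(geom, angle_deg))
  structure(list(lengths = lengths, materials = phantom$materials,
                 n_rows = geom$n_rows, n_channels = geom$n_channels,
                 angle_deg = angle_deg),
            class = "path_view")
}

# analytic path lengths through laterally infinite slabs perpendicular to
# the central beam axis (gantry at 0 deg): path = thickness / cos(angle
# between the ray and the axis).  Used for the slab calibration series,
# where the slabs cover the whole beam.
slab_paths <- function(geom, pmma_mm, al_mm) {
  src <- source_position(geom, 0)
  px <- detector_pixel_positions(geom, 0)
  d <- sweep(px, 2, src)
  cosphi <- abs(d[, 1]) / sqrt(rowSums(d^2))
  lengths <- cbind(pmma_mm / cosphi, al_mm / cosphi)
  lengths[, 1] <- lengths[, 1] * (pmma_mm > 0)
  lengths[, 2] <- lengths[, 2] * (al_mm > 0)
  structure(list(lengths = lengths,
                 materials = list(bundled_material("pmma"),
                                  bundled_material("aluminum")),
                 n_rows = geom$n_rows, n_channels = geom$n_channels,
                 angle_deg = 0),
            class = "path_view")
}

# linear attenuation per mm for each material on the spectrum grid:
# matrix [n_materials, n_energies]
material_mu_matrix <- function(materials, energies_keV) {
  t(vapply(materials, function(m)
    mass_attenuation(m, energies_keV) * m$density_g_cm3 / 10,
    numeric(length(energies_keV))))
}

# transmission matrix exp(-sum_m mu_m(E) path_m) over the energies with
# nonzero fluence: [n_pixels, n_active_energies]
path_transmission <- function(paths, spectrum) {
  act <- spectrum_active(spectrum)
  if (length(paths$materials) == 0L || ncol(paths$lengths) == 0L)
    return(matrix(1, nrow(paths$lengths), length(act)))
  mu <- material_mu_matrix(paths$materials, spectrum$energies_keV[act])
  exp(-paths$lengths %*% mu)
}

# indices of energy-grid entries carrying fluence (computation is restricted
# to these; zero-fluence entries cannot contribute counts)
spectrum_active <- function(spectrum) which(spectrum$fluence > 0)

#' Detect photon counts for one view and one acquired bin
#'
#' Expected counts per pixel are `gain * exposure * sum_E fluence(E) *
#' transmission(E)` over energies above the bin threshold (per-pixel
#' threshold dispersion shifts the lower bin edge, with fractional weighting
#' of the boundary 1 keV energy bin).  With `noise`, recorded values are
#' Poisson draws; all values are clipped to `[0, counter_max]` (silent
#' saturation, as in hardware) and stuck pixels overwrite their reading.
#'
#' @param paths a `path_view` from [forward_paths()] (or a transmission
#'   matrix precomputed with the same pixel ordering, via `transmission`).
#' @param spectrum a `ct_spectrum`.
#' @param det a [detector_model].
#' @param bin `"total"` or `"high"` (the low bin is never acquired).
#' @param seed RNG seed (`NULL` with `noise = FALSE` for the noiseless
#'   expectation).
#' @param noise draw Poisson counting noise?
#' @param drift apply the detector's gain drift (object scans); flats are
#'   acquired with `drift = FALSE`.
#' @param transmission optional precomputed transmission matrix (shared
#'   between the two bins of one view).
#' @return A counts-kind [proj_image].
#' @export
detect_counts <- function(paths, spectrum, det, bin = c("total", "high"),
                          seed = NULL, noise = TRUE, drift = TRUE,
                          transmission = NULL) {
  bin <- match.arg(bin)
  thr <- det$thresholds_keV[if (bin == "total") 1L else 2L]
  if (thr >= spectrum$kvp) stopf("bin threshold above tube voltage")
  A <- if (is.null(transmission)) path_transmission(paths, spectrum) else
    transmission
  act <- spectrum_active(spectrum)
  E <- spectrum$energies_keV[act]
  fl <- spectrum$fluence[act]
  npix <- nrow(A)
  if (is.null(det$threshold_jitter_keV)) {
    w <- pmin(pmax(E + 0.5 - thr, 0), 1)
    lam <- as.numeric(A %*% (fl * w))
  } else {
    tpix <- thr + as.numeric(det$threshold_jitter_keV)
    W <- pmin(pmax(outer(-tpix, E + 0.5, "+"), 0), 1)
    lam <- rowSums(A * sweep(W, 2, fl, "*"))
  }
  lam <- lam * det$exposure
  if (!is.null(det$gain)) lam <- lam * as.numeric(det$gain)
  if (drift && !is.null(det$gain_drift)) lam <- lam * as.numeric(det$gain_drift)
  counts <- if (noise) with_seed(seed, rpois(npix, lam)) else round(lam)
  counts <- pmin(pmax(counts, 0), det$counter_max)
  m <- matrix(counts, det$n_rows, det$n_channels)
  if (!is.null(det$bad_pixels) && nrow(det$bad_pixels) > 0) {
    bp <- det$bad_pixels
    low <- bp$mode == "stuck_low"
    m[cbind(bp$row[low], bp$channel[low])] <-
      if (noise) with_seed(derive_seed(seed, "stuck"),
                           sample(0:4, sum(low), replace = TRUE)) else 0L
    m[cbind(bp$row[!low], bp$channel[!low])] <- det$counter_max - 1L
  }
  proj_image(m, bin = bin, kind = "counts", angle_deg = paths$angle_deg)
}

# averaged flat field: mean of n_flat Poisson repeats of the no-object
# expectation (sum of N independent Poisson counts is Poisson(N * lambda))
average_flat <- function(geom, spectrum, det, bin, n_flat, seed,
                         noise = TRUE) {
  thr <- det$thresholds_keV[if (bin == "total") 1L else 2L]
  act <- spectrum_active(spectrum)
  E <- spectrum$energies_keV[act]
  fl <- spectrum$fluence[act]
  if (is.null(det$threshold_jitter_keV)) {
    w <- pmin(pmax(E + 0.5 - thr, 0), 1)
    lam <- rep(sum(fl * w), geom$n_rows * geom$n_channels)
  } else {
    tpix <- thr + as.numeric(det$threshold_jitter_keV)
    W <- pmin(pmax(outer(-tpix, E + 0.5, "+"), 0), 1)
    lam <- as.numeric(W %*% fl)
  }
  lam <- lam * det$exposure
  if (!is.null(det$gain)) lam <- lam * as.numeric(det$gain)
  lam <- pmin(lam, det$counter_max)  # saturation caps each repeat's mean
  vals <- if (noise)
    with_seed(seed, rpois(length(lam), lam * n_flat) / n_flat) else lam
  m <- matrix(vals, geom$n_rows, geom$n_channels)
  proj_image(m, bin = bin, kind = "counts", angle_deg = NA_real_)
}

#' Acquire a complete circular scan
#'
#' Simulates one circular orbit: per-view Total and High bin frames plus
#' averaged flat fields (default 1440 repeats).  Deterministic given `seed`.
#'
#' @param phantom a [ct_phantom].
#' @param geom a [scan_geometry].
#' @param det a [detector_model].
#' @param spectrum a `ct_spectrum`.
#' @param seed scan seed; per-view streams are derived from it.
#' @param noise Poisson counting noise on/off.
#' @param n_flat flat-field repeats averaged into the air tables.
#' @return List with `total`, `high` ([proj_stack]s of counts) and `flats`
#'   (per-bin averaged [proj_image]s).
#' @export
acquire_scan <- function(phantom, geom, det, spectrum, seed = 1L,
                         noise = TRUE, n_flat = 1440L) {
  K <- geom$n_views
  tot <- array(0, dim = c(geom$n_rows, geom$n_channels, K))
  hig <- array(0, dim = c(geom$n_rows, geom$n_channels, K))
  for (k in seq_len(K)) {
    paths <- forward_paths(phantom, geom, geom$angles_deg[k])
    A <- path_transmission(paths, spectrum)
    tot[, , k] <- detect_counts(paths, spectrum, det, "total",
                                seed = derive_seed(seed, paste0("t", k)),
                                noise = noise, transmission = A)
    hig[, , k] <- detect_counts(paths, spectrum, det, "high",
                                seed = derive_seed(seed, paste0("h", k)),
                                noise = noise, transmission = A)
  }
  list(total = proj_stack(tot, geom$angles_deg, bin = "total", kind = "counts"),
       high = proj_stack(hig, geom$angles_deg, bin = "high", kind = "counts"),
       flats = list(
         total = average_flat(geom, spectrum, det, "total", n_flat,
                              derive_seed(seed, "flat_t"), noise),
         high = average_flat(geom, spectrum, det, "high", n_flat,
                             derive_seed(seed, "flat_h"), noise)))
}

#' Acquire the PMMA/aluminium slab calibration series
#'
#' One flat scan per (PMMA, aluminium) thickness combination, each the
#' average of `n_frames` repeats, as used to calibrate the non-uniformity
#' correction.  Default thickness lists give the 7 x 8 = 56 scan series.
#'
#' @param pmma_mm,al_mm slab thickness lists in mm (must include 0).
#' @param geom,det,spectrum,seed,noise as in [acquire_scan()].
#' @param n_frames repeats averaged per scan.
#' @return List of entries `list(pmma_mm, al_mm, total, high)` with
#'   counts-kind frames.
#' @export
acquire_slab_series <- function(pmma_mm = c(0, 5, 10, 15, 20, 30, 40),
                                al_mm = c(0, 0.5, 1, 1.5, 2, 3, 4, 5),
                                geom = desk_geometry(), det = NULL,
                                spectrum = generate_spectrum(),
                                seed = 1L, noise = TRUE, n_frames = 600L) {
  if (any(pmma_mm < 0) || any(al_mm < 0))
    stopf("slab thicknesses must be non-negative")
  if (is.null(det)) det <- ideal_detector(geom)
  out <- list()
  for (tp in pmma_mm) for (ta in al_mm) {
    paths <- slab_paths(geom, tp, ta)
    A <- path_transmission(paths, spectrum)
    sseed <- derive_seed(seed, sprintf("slab_%g_%g", tp, ta))
    avg_bin <- function(bin, tag) {
      img <- detect_counts(paths, spectrum, det, bin, seed = NULL,
                           noise = FALSE, transmission = A)
      lam <- pmin(unclass(img), det$counter_max)
      vals <- if (noise)
        with_seed(derive_seed(sseed, tag),
                  rpois(length(lam), lam * n_frames) / n_frames)
      else as.numeric(lam)
      proj_image(matrix(vals, det$n_rows, det$n_channels), bin = bin,
                 kind = "counts", angle_deg = NA_real_)
    }
    out[[length(out) + 1L]] <- list(pmma_mm = tp, al_mm = ta,
                                    total = avg_bin("total", "t"),
                                    high = avg_bin("high", "h"))
  }
  out
}

#' Write a scan to the dataset's on-disk layout
#'
#' Writes per-view frames as `<root>/{High,Total}/proj_<j>.raw` (1-based,
#' five-digit indices), averaged flats as `<root>/air_table_<bin>.raw`, and
#' an `acq_para.yaml` manifest mirroring the acquisition parameters.
#'
#' @param scan output of [acquire_scan()].
#' @param geom the [scan_geometry] used.
#' @param root output directory.
#' @return `root`, invisibly.
#' @export
write_scan_tree <- function(scan, geom, root) {
  for (b in c("total", "high")) {
    sub <- file.path(root, if (b == "total") "Total" else "High")
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    st <- scan[[b]]
    for (k in seq_len(n_views(st)))
      write_raw_frame(stack_frame(st, k),
                      file.path(sub, sprintf("proj_%05d.raw", k)))
    write_raw_frame(proj_image(round(unclass(scan$flats[[b]])), bin = b,
                               kind = "counts"),
                    file.path(root, sprintf("air_table_%s.raw", b)))
  }
  yaml::write_yaml(list(kvp = 80, sid_mm = geom$sid_mm, sdd_mm = geom$sdd_mm,
                        pixel_mm = geom$pixel_mm, n_rows = geom$n_rows,
                        n_channels = geom$n_channels,
                        angles_deg = as.numeric(geom$angles_deg),
                        angle_index_base = 1L),
                   file.path(root, "acq_para.yaml"))
  invisible(root)
}

#' @rdname write_scan_tree
#' @param series output of [acquire_slab_series()].
#' @export
write_slab_series <- function(series, root) {
  for (s in series) {
    sub <- file.path(root, sprintf("PMMA_%g_AL_%g", s$pmma_mm, s$al_mm))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    for (b in c("total", "high"))
      write_raw_frame(proj_image(round(unclass(s[[b]])), bin = b,
                                 kind = "counts"),
                      file.path(sub, sprintf("proj_%s.raw", b)))
  }
  invisible(root)
}
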