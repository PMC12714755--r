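#' Construct a labelled voxel phantom
#'
#' @param labels 3-D integer array; 0 = air, label `m` indexes
#'   `materials[[m]]`.
#' @param voxel_mm isotropic voxel size in mm.
#' @param materials list of [ct_material] objects, one per nonzero label.
#' @return A `ct_phantom` object (isocenter-centred grid).
#' @export
ct_phantom <- function(labels, voxel_mm, materials) {
  if (length(dim(labels)) != 3L) stopf("phantom labels must be a 3-D array")
  if (voxel_mm <= 0) stopf("voxel size must be positive")
  mx <- max(labels)
  if (mx > length(materials))
    stopf("label %d has no material (only %d materials given)", mx,
          length(materials))
  # lateral support radius (mm) of the occupied voxels, for FOV checks
  d <- dim(labels)
  occ_xy <- which(rowSums(labels != 0L, dims = 2L) > 0L, arr.ind = TRUE)
  support <- if (nrow(occ_xy) == 0L) 0 else {
    ax <- phantom_axes(d[1:2], voxel_mm)
    max(sqrt(ax[[1]][occ_xy[, 1]]^2 + ax[[2]][occ_xy[, 2]]^2)) +
      voxel_mm / sqrt(2)
  }
  structure(list(labels = labels, voxel_mm = voxel_mm, materials = materials,
                 support_radius_mm = support),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<ct_phantom> %d x %d x %d @ %.3g mm; materials: %s\n",
              d[1], d[2], d[3], x$voxel_mm,
              paste(vapply(x$materials, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

# voxel-centre coordinate grids (mm, isocenter origin)
phantom_axes <- function(n, voxel_mm) {
  lapply(n, function(ni) (seq_len(ni) - (ni + 1) / 2) * voxel_mm)
}

#' Build a test phantom
#'
#' Voxel phantom builders for the scenarios the pipeline needs:
#' * `walnut`: ellipsoidal high-density shell enclosing irregular pulp lobes
#'   and air cavities (seeded blob noise), a stand-in for a real nut;
#' * `water_cylinder`: uniform water disk for HU calibration;
#' * `hap_rods`: PMMA cylindrical holder with three hydroxyapatite rods of
#'   configurable loading (default 50/100/200 mg/cm^3);
#' * `slab_stack`: homogeneous PMMA and aluminium slabs stacked along the
#'   beam axis (x), spanning the full lateral grid.
#'
#' All builders are pure functions of `(kind, params, seed)`.
#'
#' @param kind phantom kind.
#' @param params named list of overrides, see Details.
#' @param seed RNG seed for the stochastic (walnut) interior.
#' @details Common params: `n` (grid size, default 96), `voxel_mm`
#'   (default 0.5).  Walnut: `outer_diameter_mm` (default 36, must lie in
#'   `[30, 45]`), `shell_thickness_mm` (default 2).  Water cylinder:
#'   `diameter_mm` (36), `height_mm` (full grid).  HAP rods:
#'   `holder_diameter_mm` (30), `rod_diameter_mm` (6),
#'   `densities_mg_cm3` (50, 100, 200).  Slab stack: `pmma_mm` (10),
#'   `al_mm` (1).
#' @return A `ct_phantom`.
#' @export
build_phantom <- function(kind = c("walnut", "water_cylinder", "hap_rods",
                                   "slab_stack"),
                          params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  n <- as.integer(p("n", 96L))
  voxel <- p("voxel_mm", 0.5)
  if (n < 4L || voxel <= 0) stopf("grid and voxel size must be positive")
  ax <- phantom_axes(c(n, n, n), voxel)
  X <- array(rep(ax[[1]], times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax[[2]], each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax[[3]], each = n * n), dim = c(n, n, n))
  labels <- array(0L, dim = c(n, n, n))

  if (kind == "water_cylinder") {
    r <- p("diameter_mm", 36) / 2
    h <- p("height_mm", n * voxel) / 2
    labels[X^2 + Y^2 <= r^2 & abs(Z) <= h] <- 1L
    return(ct_phantom(labels, voxel, list(bundled_material("water"))))
  }

  if (kind == "hap_rods") {
    rh <- p("holder_diameter_mm", 30) / 2
    rr <- p("rod_diameter_mm", 6) / 2
    dens <- p("densities_mg_cm3", c(50, 100, 200))
    labels[X^2 + Y^2 <= rh^2] <- 1L
    ring <- rh * 0.55
    mats <- list(bundled_material("pmma"))
    for (i in seq_along(dens)) {
      th <- 2 * pi * (i - 1) / length(dens)
      cx <- ring * cos(th); cy <- ring * sin(th)
      labels[(X - cx)^2 + (Y - cy)^2 <= rr^2] <- i + 1L
      mats[[i + 1L]] <- hap_rod_material(dens[i])
    }
    return(ct_phantom(labels, voxel, mats))
  }

  if (kind == "slab_stack") {
    tp <- p("pmma_mm", 10); ta <- p("al_mm", 1)
    if (tp < 0 || ta < 0) stopf("slab thicknesses must be non-negative")
    # PMMA slab centred upstream of the aluminium slab, both full lateral span
    x0 <- -(tp + ta) / 2
    labels[X >= x0 & X < x0 + tp] <- 1L
    labels[X >= x0 + tp & X < x0 + tp + ta] <- 2L
    return(ct_phantom(labels, voxel,
                      list(bundled_material("pmma"),
                           bundled_material("aluminum"))))
  }

  # walnut
  D <- p("outer_diameter_mm", 36)
  if (D < 30 || D > 45)
    stopf("walnut outer diameter must be within [30, 45] mm")
  tsh <- p("shell_thickness_mm", 2)
  a <- D / 2; b <- 0.92 * a; cc <- 1.05 * a    # mildly triaxial
  if (2 * cc > n * voxel) cc <- n * voxel / 2 * 0.95
  r_out <- sqrt((X / a)^2 + (Y / b)^2 + (Z / cc)^2)
  r_in <- sqrt((X / (a - tsh))^2 + (Y / (b - tsh))^2 + (Z / (cc - tsh))^2)
  labels[r_out <= 1] <- 1L                      # shell
  inside <- r_in <= 1
  field <- with_seed(seed, {
    k <- 40L
    ctr <- matrix(runif(3 * k, -0.7, 0.7), ncol = 3)
    amp <- runif(k, 0.5, 1)
    sig <- runif(k, 0.12, 0.3)
    f <- array(0, dim = dim(labels))
    for (i in seq_len(k)) {
      d2 <- ((X / a) - ctr[i, 1])^2 + ((Y / b) - ctr[i, 2])^2 +
        ((Z / cc) - ctr[i, 3])^2
      f <- f + amp[i] * exp(-d2 / (2 * sig[i]^2))
    }
    f
  })
  thr <- quantile(field[inside], p("air_fraction", 0.35))
  labels[inside & field >= thr] <- 2L          # pulp lobes
  labels[inside & field < thr] <- 0L           # air cavities
  ct_phantom(labels, voxel, list(bundled_material("walnut_shell"),
                                 bundled_material("walnut_pulp")))
}
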