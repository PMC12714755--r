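# Image-domain two-material decomposition and virtual monoenergetic
# synthesis.
#
# Each voxel is modelled as a linear mixture of two basis materials; the
# water-normalized attenuation NA = mu/mu_water * 1000 (= HU + 1000) of the
# low and high bin images is a 2x2 linear map of the basis densities, so
# per-voxel decomposition is one matrix inverse.  The low/high pair is used
# because those bins have minimal spectral overlap.

#' Water-normalized attenuation from HU
#'
#' `NA = HU + 1000` (water 1000, vacuum 0): the quantity the decomposition
#' algebra is exact in.
#'
#' @param hu a [ct_volume] in HU.
#' @return Numeric array of normalized attenuation.
#' @export
na_from_hu <- function(hu) {
  stopifnot(inherits(hu, "ct_volume"))
  if (hu$units != "HU") stopf("normalized attenuation needs an HU volume")
  hu$values + 1000
}

#' Build a decomposition matrix from calibration sample means
#'
#' Entry `(b, m)` is the water-normalized attenuation of basis material `m`
#' in bin `b` per unit density: `(mean_HU(b, m) + 1000) / density_m`, the
#' matrix inverted per voxel by [decompose()].
#'
#' @param mean_hu 2x2 matrix of mean HU values, rows = bins (low, high),
#'   columns = the two basis materials.
#' @param densities_g_cm3 the two sample densities (g/cm^3, > 0).
#' @param basis_names optional material labels.
#' @return An `md_matrix` with the 2x2 `entries` and its condition number.
#' @export
md_matrix_from_samples <- function(mean_hu, densities_g_cm3,
                                   basis_names = colnames(mean_hu)) {
  if (!all(dim(mean_hu) == c(2L, 2L))) stopf("mean_hu must be 2 x 2")
  if (any(densities_g_cm3 <= 0)) stopf("densities must be positive")
  entries <- sweep(mean_hu + 1000, 2, densities_g_cm3, "/")
  kap <- kappa(entries, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8)
    stopf("singular decomposition matrix: basis materials '%s' and '%s' are spectrally collinear",
          basis_names[1] %||% "1", basis_names[2] %||% "2")
  structure(list(entries = entries,
                 basis_names = basis_names %||% c("material1", "material2"),
                 bins = c("low", "high"), condition = kap),
            class = "md_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic decomposition matrix from material tables
#'
#' Computes the same matrix directly from mass-attenuation tables at the
#' two bins' effective energies: entry `(b, m) =
#' (mu/rho_m(E_b) / mu_water(E_b)) * 1000` per g/cm^3.
#'
#' @param mat1,mat2 basis [ct_material]s.
#' @param e_low_keV,e_high_keV effective energies of the low and high bins.
#' @param water the water reference material.
#' @return An `md_matrix`.
#' @export
md_matrix_analytic <- function(mat1, mat2, e_low_keV, e_high_keV,
                               water = bundled_material("water")) {
  ent <- function(m, E)
    mass_attenuation(m, E) /
      (mass_attenuation(water, E) * water$density_g_cm3) * 1000
  entries <- rbind(c(ent(mat1, e_low_keV), ent(mat2, e_low_keV)),
                   c(ent(mat1, e_high_keV), ent(mat2, e_high_keV)))
  colnames(entries) <- c(mat1$name, mat2$name)
  # entries are already per unit density; feed them back through the sample
  # constructor (mean_hu = entries - 1000 at density 1) to share validation
  md_matrix_from_samples(entries - 1000, c(1, 1),
                         basis_names = c(mat1$name, mat2$name))
}

#' @export
print.md_matrix <- function(x, ...) {
  cat(sprintf("<md_matrix> basis (%s, %s), condition number %.3g\n",
              x$basis_names[1], x$basis_names[2], x$condition))
  print(round(x$entries, 2))
  invisible(x)
}

#' Per-voxel two-material decomposition
#'
#' Solves the 2x2 water-normalized mixture model for every voxel of a
#' co-registered low/high HU volume pair; densities are reported in
#' mg/cm^3.  Negative outputs (decomposition noise) are kept, not clipped;
#' their fraction is reported in the summary attribute.
#'
#' @param hu_low,hu_high [ct_volume]s in HU, same shape.
#' @param matrix an `md_matrix`.
#' @return List with `rho1`, `rho2` ([ct_volume]s, mg/cm^3, tagged with the
#'   basis names) and `summary` (negative-voxel fractions).
#' @export
decompose <- function(hu_low, hu_high, matrix) {
  stopifnot(inherits(matrix, "md_matrix"))
  if (!identical(dim(hu_low$values), dim(hu_high$values)))
    stopf("low/high volumes must have identical shape")
  inv <- solve(matrix$entries)
  nal <- na_from_hu(hu_low); nah <- na_from_hu(hu_high)
  r1 <- (inv[1, 1] * nal + inv[1, 2] * nah) * 1000  # g/cm^3 -> mg/cm^3
  r2 <- (inv[2, 1] * nal + inv[2, 2] * nah) * 1000
  v1 <- ct_volume(r1, hu_low$voxel_mm, units = "mg_per_cm3",
                  bin = matrix$basis_names[1])
  v2 <- ct_volume(r2, hu_low$voxel_mm, units = "mg_per_cm3",
                  bin = matrix$basis_names[2])
  list(rho1 = v1, rho2 = v2,
       summary = c(neg_frac_1 = mean(r1 < 0), neg_frac_2 = mean(r2 < 0)))
}

#' Synthesize a virtual monoenergetic image
#'
#' From water/hydroxyapatite basis density maps, the linear attenuation at
#' energy `E` is `mu_E = mu/rho_water(E) rho_water + mu/rho_HAP(E)
#' rho_HAP`, converted to HU against water's linear attenuation at that
#' same energy -- pure water maps to 0 HU at every energy.
#'
#' @param densities list with `rho1` (water map) and `rho2` (HAP map) in
#'   mg/cm^3, as returned by [decompose()] with a water/HAP basis.
#' @param energy_keV synthesis energy, within 15-80 keV.
#' @param water,hap the reference materials.
#' @return A [ct_volume] in HU.
#' @export
synthesize_vmi <- function(densities, energy_keV,
                           water = bundled_material("water"),
                           hap = bundled_material("hydroxyapatite")) {
  if (energy_keV < 15 || energy_keV > 80)
    stopf("VMI energy %g keV outside the supported 15-80 keV range", energy_keV)
  rw <- densities$rho1$values / 1000  # g/cm^3
  rh <- densities$rho2$values / 1000
  muw <- mass_attenuation(water, energy_keV)
  muh <- mass_attenuation(hap, energy_keV)
  mu_e <- muw * rw + muh * rh                    # cm^-1 per unit density grid
  mu_water_lin <- muw * water$density_g_cm3
  hu <- mu_e / mu_water_lin * 1000 - 1000
  ct_volume(hu, densities$rho1$voxel_mm, units = "HU",
            bin = sprintf("vmi_%gkeV", energy_keV))
}
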