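# Materials with energy-resolved mass attenuation.
#
# Bundled tables come from a two-component analytic model: a photoelectric
# term falling as E^-3 plus a Compton term following the Klein-Nishina total
# cross-section shape.  Each material is pinned by its mass attenuation at
# two anchor energies (20 and 60 keV), chosen near tabulated values for the
# real materials; the walnut shell/pulp entries are synthetic stand-ins (no
# reference attenuation exists for them).  Users can substitute measured
# tables via the TSV interface; the rest of the package only sees the table.

#' Klein-Nishina total cross-section shape
#'
#' Relative (unnormalized) Klein-Nishina total Compton cross-section as a
#' function of photon energy; used as the Compton energy dependence of the
#' bundled material model.
#'
#' @param energy_keV photon energy in keV.
#' @return Relative cross-section values.
#' @export
klein_nishina <- function(energy_keV) {
  a <- energy_keV / 510.999
  (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
    log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
}

#' Construct a material from a mass-attenuation table
#'
#' @param name material label.
#' @param density_g_cm3 bulk density in g/cm^3 (> 0).
#' @param energies_keV energy grid (1 keV spacing, covering at least
#'   10-80 keV).
#' @param mu_over_rho mass attenuation coefficients, cm^2/g, all positive.
#' @return A `ct_material` object.
#' @export
ct_material <- function(name, density_g_cm3, energies_keV, mu_over_rho) {
  if (density_g_cm3 <= 0) stopf("material density must be positive")
  if (length(energies_keV) != length(mu_over_rho))
    stopf("energy grid and attenuation table lengths differ")
  if (min(energies_keV) > 10 || max(energies_keV) < 80)
    stopf("attenuation table must cover at least [10, 80] keV")
  if (any(mu_over_rho <= 0)) stopf("mass attenuation must be positive")
  structure(list(name = name, density_g_cm3 = density_g_cm3,
                 energies_keV = as.numeric(energies_keV),
                 mu_over_rho = as.numeric(mu_over_rho)),
            class = "ct_material")
}

#' @export
print.ct_material <- function(x, ...) {
  cat(sprintf("<ct_material> %s: rho = %.3g g/cm3, mu/rho(30 keV) = %.4g cm2/g\n",
              x$name, x$density_g_cm3, mass_attenuation(x, 30)))
  invisible(x)
}

material_from_anchors <- function(name, density_g_cm3, mu20, mu60,
                                  energies_keV = 10:120) {
  # solve a * (30/E)^3 + b * kn(E)/kn(30) through the two anchors
  basis <- function(E) cbind((30 / E)^3, klein_nishina(E) / klein_nishina(30))
  ab <- solve(basis(c(20, 60)), c(mu20, mu60))
  mu <- as.numeric(basis(energies_keV) %*% ab)
  ct_material(name, density_g_cm3, energies_keV, mu)
}

# anchor values (cm^2/g at 20 and 60 keV) near tabulated data for the real
# materials; shell/pulp are synthetic with a deliberate spectral contrast
# (shell more photoelectric) so the two-material decomposition is
# well-conditioned after denoising.
material_anchor_db <- list(
  water          = list(rho = 1.000, mu20 = 0.8096, mu60 = 0.2059),
  pmma           = list(rho = 1.190, mu20 = 0.5714, mu60 = 0.1924),
  aluminum       = list(rho = 2.699, mu20 = 3.4410, mu60 = 0.2778),
  hydroxyapatite = list(rho = 3.180, mu20 = 4.5000, mu60 = 0.3200),
  walnut_shell   = list(rho = 1.200, mu20 = 0.9500, mu60 = 0.2100),
  walnut_pulp    = list(rho = 0.950, mu20 = 0.5200, mu60 = 0.1950)
)

#' Bundled materials
#'
#' Returns one of the package's bundled materials: `water`, `pmma`,
#' `aluminum`, `hydroxyapatite`, `walnut_shell`, `walnut_pulp`.  The walnut
#' shell and pulp entries are synthetic stand-ins.
#'
#' @param name material name.
#' @return A `ct_material`.
#' @export
bundled_material <- function(name) {
  if (!name %in% names(material_anchor_db))
    stopf("unknown bundled material '%s'", name)
  a <- material_anchor_db[[name]]
  material_from_anchors(name, a$rho, a$mu20, a$mu60)
}

#' Hydroxyapatite calibration-rod material
#'
#' Models a QRM-style HAP rod of nominal concentration `c` mg/cm^3 as a
#' water-equivalent matrix loaded with `c` mg of HAP per cm^3: linear
#' attenuation is the additive mixture, density 1 + c/1000 g/cm^3.
#'
#' @param concentration_mg_cm3 HAP loading (e.g. 50, 100, 200).
#' @return A `ct_material`.
#' @export
hap_rod_material <- function(concentration_mg_cm3) {
  w <- bundled_material("water"); h <- bundled_material("hydroxyapatite")
  c_g <- concentration_mg_cm3 / 1000
  rho <- 1 + c_g
  mu_lin <- w$mu_over_rho * 1 + h$mu_over_rho * c_g  # cm^-1 on shared grid
  ct_material(sprintf("hap_rod_%g", concentration_mg_cm3), rho,
              w$energies_keV, mu_lin / rho)
}

#' Interpolate a material's mass attenuation coefficient
#'
#' Cubic interpolation of the stored 1 keV table; exact at grid nodes; no
#' extrapolation outside the table range.
#'
#' @param material a `ct_material`.
#' @param energy_keV query energies (keV), within the table range.
#' @return Mass attenuation in cm^2/g.
#' @export
mass_attenuation <- function(material, energy_keV) {
  rng <- range(material$energies_keV)
  if (any(energy_keV < rng[1] | energy_keV > rng[2]))
    stopf("energy outside table range [%g, %g] keV", rng[1], rng[2])
  f <- splinefun(material$energies_keV, material$mu_over_rho, method = "fmm")
  f(energy_keV)
}

#' Read and write mass-attenuation tables
#'
#' Plain TSV with a comment header and columns `energy_keV`, `mu_over_rho`
#' (cm^2/g); the format users drop measured tables into.
#'
#' @param material a `ct_material`.
#' @param path TSV file path.
#' @return `write_material_table` returns `path` invisibly;
#'   `read_material_table` returns a `ct_material`.
#' @export
write_material_table <- function(material, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# material: %s", material$name), con)
  writeLines(sprintf("# density_g_cm3: %.6g", material$density_g_cm3), con)
  writeLines("energy_keV\tmu_over_rho", con)
  writeLines(sprintf("%g\t%.8g", material$energies_keV,
                     material$mu_over_rho), con)
  invisible(path)
}

#' @rdname write_material_table
#' @param name,density_g_cm3 overrides; defaults come from the file header.
#' @export
read_material_table <- function(path, name = NULL, density_g_cm3 = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(name)) {
    m <- grep("^# material:", hdr, value = TRUE)
    name <- if (length(m)) trimws(sub("^# material:", "", m[1])) else "unnamed"
  }
  if (is.null(density_g_cm3)) {
    m <- grep("^# density_g_cm3:", hdr, value = TRUE)
    if (!length(m)) stopf("no density in table header and none supplied")
    density_g_cm3 <- as.numeric(sub("^# density_g_cm3:", "", m[1]))
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  ct_material(name, density_g_cm3, tab$energy_keV, tab$mu_over_rho)
}
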