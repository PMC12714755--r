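#' Generate the filtered X-ray tube spectrum
#'
#' Analytic bremsstrahlung model: unfiltered fluence proportional to
#' `(kvp - E)` below the tube voltage and zero above (the Kramers thin-target
#' shape), hardened by an aluminium filter via Beer-Lambert attenuation.
#' Characteristic lines are not modelled.  The spectrum is normalized so
#' that the summed fluence over the energy grid equals a configurable
#' photons-per-pixel budget (expected photons arriving at one detector pixel
#' per view with no object in the beam).
#'
#' @param kvp tube voltage in kV (40-120).
#' @param filter_mm_al aluminium filter thickness in mm (>= 0).
#' @param photons_per_pixel total fluence budget per detector pixel per view.
#' @param energies_keV energy grid, 1 keV spacing.
#' @return A `ct_spectrum`: list with `energies_keV`, `fluence` (photons per
#'   1 keV bin per pixel per view), `kvp`, `filter_mm_al`.
#' @export
generate_spectrum <- function(kvp = 80, filter_mm_al = 0.5,
                              photons_per_pixel = 3000,
                              energies_keV = 10:120) {
  if (kvp < 40 || kvp > 120) stopf("kvp must be within [40, 120]")
  if (filter_mm_al < 0) stopf("filter thickness must be non-negative")
  E <- as.numeric(energies_keV)
  fl <- pmax(kvp - E, 0)
  if (filter_mm_al > 0) {
    al <- bundled_material("aluminum")
    mu_lin <- mass_attenuation(al, pmin(E, max(al$energies_keV))) *
      al$density_g_cm3                      # cm^-1
    fl <- fl * exp(-mu_lin * filter_mm_al / 10)
  }
  tot <- sum(fl)
  if (tot <= 0) stopf("degenerate spectrum: zero total fluence")
  structure(list(energies_keV = E, fluence = fl * photons_per_pixel / tot,
                 kvp = kvp, filter_mm_al = filter_mm_al),
            class = "ct_spectrum")
}

#' @export
print.ct_spectrum <- function(x, ...) {
  cat(sprintf("<ct_spectrum> %g kVp, %.2g mm Al, %.4g photons/pixel, mean E = %.3g keV\n",
              x$kvp, x$filter_mm_al, sum(x$fluence),
              sum(x$energies_keV * x$fluence) / sum(x$fluence)))
  invisible(x)
}

#' Fluence-weighted effective energy of an acquisition bin
#'
#' The mean photon energy of the spectrum restricted to a threshold bin;
#' used to build analytic decomposition matrices and pick the reference
#' energy of a bin's attenuation image.
#'
#' @param spectrum a `ct_spectrum`.
#' @param threshold_keV lower bin edge (upper edge is the tube voltage).
#' @param upper_keV optional upper edge (for the derived low bin).
#' @return Effective energy in keV.
#' @export
bin_effective_energy <- function(spectrum, threshold_keV,
                                 upper_keV = Inf) {
  sel <- spectrum$energies_keV >= threshold_keV &
    spectrum$energies_keV < upper_keV
  if (!any(sel)) stopf("no spectrum support in bin [%g, %g) keV",
                       threshold_keV, upper_keV)
  sum(spectrum$energies_keV[sel] * spectrum$fluence[sel]) /
    sum(spectrum$fluence[sel])
}
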