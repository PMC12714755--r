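# Shared micro-scale fixtures, built in code.  The micro profile (32 x 16
# detector, 24 views, 32^3 phantom) keeps per-file unit tests in seconds;
# the desk profile prescribed for the end-to-end suites lives in
# test-acceptance.R.

micro_geometry <- function(n_views = 24L) {
  scan_geometry(pixel_mm = 3, n_channels = 32L, n_rows = 16L,
                n_views = n_views)
}

micro_water <- function(n = 32L) {
  build_phantom("water_cylinder", list(n = n, voxel_mm = 0.8,
                                       diameter_mm = 22))
}

# cube of water, side_mm, centred: exact axis-aligned path lengths
cube_phantom <- function(n = 24L, voxel_mm = 1, side_mm = 10) {
  labels <- array(0L, dim = c(n, n, n))
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_mm
  sel <- abs(ax) <= side_mm / 2 - voxel_mm / 2 + 1e-9
  labels[sel, sel, sel] <- 1L
  ct_phantom(labels, voxel_mm, list(bundled_material("water")))
}

# cache heavy per-file fixtures across tests within one run
fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}
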