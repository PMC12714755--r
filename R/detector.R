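#' Dual-threshold photon-counting detector model
#'
#' Describes the counting detector: two energy thresholds (total and high
#' bins; the low bin is only ever derived by subtraction), a 12-bit counter
#' ceiling, a per-pixel multiplicative gain map, optional per-pixel energy
#' threshold dispersion, optional gain drift between flat-field acquisition
#' and object scans, and a table of stuck pixels.
#'
#' Gain is removed exactly by flat-field normalisation when it is identical
#' at flat and scan time; the two mechanisms that survive normalisation --
#' and that the correction chain exists for -- are threshold dispersion
#' (signal-dependent response error) and gain drift (static log-domain
#' offset producing rings).
#'
#' @param n_rows,n_channels detector shape.
#' @param thresholds_keV the two counting thresholds, strictly increasing.
#' @param counter_max counter ceiling (12-bit: 4096).
#' @param gain per-pixel multiplicative gain map (`[rows, channels]`,
#'   positive), or `NULL` for unity.
#' @param threshold_jitter_keV per-pixel additive threshold offset map, or
#'   `NULL` for none.
#' @param gain_drift per-pixel multiplicative drift applied at object-scan
#'   time only, or `NULL` for none.
#' @param bad_pixels data.frame with columns `row`, `channel`, `mode`
#'   (`"stuck_low"` or `"stuck_high"`), or `NULL`.
#' @param exposure relative exposure scale (1 = the protocol's 70 ms).
#' @return A `detector_model` object.
#' @export
detector_model <- function(n_rows, n_channels, thresholds_keV = c(15, 30),
                           counter_max = 4096L, gain = NULL,
                           threshold_jitter_keV = NULL, gain_drift = NULL,
                           bad_pixels = NULL, exposure = 1) {
  if (length(thresholds_keV) != 2L || diff(thresholds_keV) <= 0)
    stopf("need two strictly increasing thresholds")
  shape <- c(n_rows, n_channels)
  chk <- function(m, what, positive = TRUE) {
    if (is.null(m)) return(NULL)
    if (!identical(dim(m), as.integer(shape)))
      stopf("%s map must be %d x %d", what, shape[1], shape[2])
    if (!all(is.finite(m)) || (positive && any(m <= 0)))
      stopf("%s map must be finite%s", what, if (positive) " and positive" else "")
    m
  }
  structure(list(n_rows = as.integer(n_rows),
                 n_channels = as.integer(n_channels),
                 thresholds_keV = thresholds_keV,
                 counter_max = as.integer(counter_max),
                 gain = chk(gain, "gain"),
                 threshold_jitter_keV = chk(threshold_jitter_keV,
                                            "threshold jitter", positive = FALSE),
                 gain_drift = chk(gain_drift, "gain drift"),
                 bad_pixels = bad_pixels, exposure = exposure),
            class = "detector_model")
}

#' @rdname detector_model
#' @param geom a [scan_geometry] supplying the detector shape.
#' @export
ideal_detector <- function(geom, thresholds_keV = c(15, 30),
                           counter_max = 4096L) {
  detector_model(geom$n_rows, geom$n_channels, thresholds_keV, counter_max)
}

#' Simulate a realistic imperfect detector
#'
#' Builds a detector whose gain map is a smooth low-order polynomial field
#' times per-tile offsets (tile seams) times per-pixel log-normal jitter,
#' with per-tile plus per-pixel energy-threshold dispersion, optional gain
#' drift relative to flat-field time, and randomly placed stuck pixels.
#' Deterministic given `seed`.
#'
#' @param geom a [scan_geometry].
#' @param seed RNG seed.
#' @param tile_width tile width in channels (tile seams in the gain and
#'   threshold maps).
#' @param gain_sigma per-pixel log-normal gain jitter (sd of log gain).
#' @param tile_sigma per-tile log-gain offset sd.
#' @param threshold_sigma_keV per-pixel threshold dispersion sd (keV).
#' @param drift_sigma log-gain drift sd between flat and scan time
#'   (0 = no drift).
#' @param n_bad number of stuck pixels.
#' @inheritParams detector_model
#' @return A `detector_model`.
#' @export
random_detector <- function(geom, seed = 1L, tile_width = 128L,
                            gain_sigma = 0.01, tile_sigma = 0.03,
                            threshold_sigma_keV = 0.4, drift_sigma = 0,
                            n_bad = 0L, thresholds_keV = c(15, 30),
                            counter_max = 4096L) {
  nr <- geom$n_rows; nc <- geom$n_channels
  with_seed(derive_seed(seed, "detector"), {
    i <- (seq_len(nr) - nr / 2) / nr
    j <- (seq_len(nc) - nc / 2) / nc
    smooth <- outer(i, j, function(a, b)
      0.03 * a + 0.05 * b - 0.04 * a * b + 0.06 * b^2)
    tile_of <- (seq_len(nc) - 1L) %/% tile_width
    tile_off <- stats::rnorm(max(tile_of) + 1L, 0, tile_sigma)
    tiles <- matrix(tile_off[tile_of + 1L], nr, nc, byrow = TRUE)
    jit <- matrix(stats::rnorm(nr * nc, 0, gain_sigma), nr, nc)
    gain <- exp(smooth + tiles + jit)
    thr_tile <- stats::rnorm(max(tile_of) + 1L, 0, threshold_sigma_keV)
    thr <- matrix(thr_tile[tile_of + 1L], nr, nc, byrow = TRUE) +
      matrix(stats::rnorm(nr * nc, 0, threshold_sigma_keV / 2), nr, nc)
    drift <- if (drift_sigma > 0)
      exp(matrix(stats::rnorm(nr * nc, 0, drift_sigma), nr, nc)) else NULL
    bad <- NULL
    if (n_bad > 0L) {
      idx <- sample.int(nr * nc, n_bad)
      bad <- data.frame(row = (idx - 1L) %% nr + 1L,
                        channel = (idx - 1L) %/% nr + 1L,
                        mode = sample(c("stuck_low", "stuck_high"), n_bad,
                                      replace = TRUE, prob = c(0.8, 0.2)),
                        stringsAsFactors = FALSE)
    }
    detector_model(nr, nc, thresholds_keV, counter_max, gain = gain,
                   threshold_jitter_keV = thr, gain_drift = drift,
                   bad_pixels = bad)
  })
}
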