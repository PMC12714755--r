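# shared micro slab-calibration fixture: detector with tile-structured
# threshold dispersion (the signal-dependent response error the polynomial
# model exists for), noiseless slab series, air-corrected log frames
stepc_fixture <- function() cached("stepc", {
  geom <- micro_geometry()
  sp <- generate_spectrum()
  det <- random_detector(geom, seed = 7, gain_sigma = 0, tile_sigma = 0.02,
                         tile_width = 8L, threshold_sigma_keV = 0.4)
  series <- acquire_slab_series(geom = geom, det = det, spectrum = sp,
                                seed = 2, noise = FALSE)
  flats <- list(
    total = pcctk:::average_flat(geom, sp, det, "total", 1L, NULL, FALSE),
    high = pcctk:::average_flat(geom, sp, det, "high", 1L, NULL, FALSE))
  frames <- lapply(series, function(s)
    list(total = air_correct(s$total, flats$total),
         high = air_correct(s$high, flats$high)))
  hold <- which(vapply(series, function(s)
    s$pmma_mm == 15 && s$al_mm == 1.5, logical(1)))
  list(geom = geom, sp = sp, det = det, frames = frames, hold = hold,
       table = stepc_calibrate(frames[-hold]))
})

test_that("calibration yields 5-coefficient tables of the detector shape", {
  fx <- stepc_fixture()
  expect_identical(dim(fx$table$coeffs$total),
                   c(fx$geom$n_rows, fx$geom$n_channels, 5L))
  expect_identical(dim(fx$table$coeffs$high),
                   c(fx$geom$n_rows, fx$geom$n_channels, 5L))
  expect_true(all(is.finite(unlist(fx$table$coeffs))))
  expect_error(stepc_calibrate(fx$frames[1:3]), "at least 6")
})

test_that("calibration strongly reduces residual non-uniformity, including held out", {
  fx <- stepc_fixture()
  for (b in c("total", "high")) {
    rms <- fx$table$fit_rms[[b]]
    expect_lt(rms[["after"]], 0.1 * rms[["before"]])
  }
  # held-out thickness: residual non-uniformity strictly smaller
  ho <- fx$frames[[fx$hold]]
  for (b in c("total", "high")) {
    before <- sd(fit_uniformity_surface(ho[[b]])$residual)
    corrected <- unclass(ho[[b]]) -
      pcctk:::stepc_predict(fx$table, b, ho$total, ho$high)
    after <- sd(fit_uniformity_surface(
      proj_image(corrected, b, "log"))$residual)
    expect_lt(after, before)
  }
})

test_that("an all-zero table is the identity and an ideal detector needs none", {
  fx <- stepc_fixture()
  zero <- fx$table
  for (b in names(zero$coeffs)) zero$coeffs[[b]][] <- 0
  st <- proj_stack(array(rnorm(16 * 32 * 3, 1, 0.1), dim = c(16, 32, 3)),
                   0:2, bin = "total", kind = "log")
  sth <- proj_stack(array(rnorm(16 * 32 * 3, 0.6, 0.1), dim = c(16, 32, 3)),
                    0:2, bin = "high", kind = "log")
  expect_equal(stepc_apply(st, zero, high = sth)$data, st$data)
  expect_error(stepc_apply(st, zero), "paired high")

  # ideal detector: predicted errors ~0, correction changes frames < 1% RMS
  geom <- fx$geom; sp <- fx$sp
  det0 <- ideal_detector(geom)
  series0 <- acquire_slab_series(geom = geom, det = det0, spectrum = sp,
                                 noise = FALSE)
  flat0 <- pcctk:::average_flat(geom, sp, det0, "total", 1L, NULL, FALSE)
  flat0h <- pcctk:::average_flat(geom, sp, det0, "high", 1L, NULL, FALSE)
  frames0 <- lapply(series0, function(s)
    list(total = air_correct(s$total, flat0),
         high = air_correct(s$high, flat0h)))
  tab0 <- stepc_calibrate(frames0)
  f <- frames0[[20]]
  pred <- pcctk:::stepc_predict(tab0, "total", f$total, f$high)
  expect_lt(sqrt(mean(pred^2)), 0.01 * max(sqrt(mean(unclass(f$total)^2)), 0.1))
})

test_that("correction is idempotent: a second calibration pass finds ~nothing", {
  fx <- stepc_fixture()
  corrected <- lapply(fx$frames, function(f) {
    ct <- unclass(f$total) -
      pcctk:::stepc_predict(fx$table, "total", f$total, f$high)
    ch <- unclass(f$high) -
      pcctk:::stepc_predict(fx$table, "high", f$total, f$high)
    list(total = proj_image(ct, "total", "log"),
         high = proj_image(ch, "high", "log"))
  })
  tab2 <- stepc_calibrate(corrected[-fx$hold])
  f1 <- fx$frames[[fx$hold]]; f2 <- corrected[[fx$hold]]
  first <- pcctk:::stepc_predict(fx$table, "total", f1$total, f1$high)
  second <- pcctk:::stepc_predict(tab2, "total", f2$total, f2$high)
  expect_lt(sqrt(mean(second^2)), 0.2 * sqrt(mean(first^2)))
})

test_that("coefficient tables round-trip through the float32 disk format", {
  fx <- stepc_fixture()
  dir <- withr::local_tempdir()
  write_stepc_table(fx$table, dir)
  expect_true(file.exists(file.path(dir, "STEPC_table_total.data")))
  back <- read_stepc_table(dir)
  expect_equal(back$coeffs$total, fx$table$coeffs$total, tolerance = 1e-6)
  expect_identical(names(back$coeffs), names(fx$table$coeffs))
})
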