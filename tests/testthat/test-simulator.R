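test_that("forward projector is exact on axis-aligned rays and empty phantoms", {
  geom <- micro_geometry()
  cube <- cube_phantom(n = 32, voxel_mm = 1, side_mm = 10)
  pv <- forward_paths(cube, geom, 0)
  L <- matrix(pv$lengths[, 1], geom$n_rows, geom$n_channels)
  # near-axial rays cross the full 10 mm cube; the only correction is the
  # exact secant of the small ray obliquity (detector offset 1.5 mm in u, v)
  sec <- sqrt(325^2 + 1.5^2 + 1.5^2) / 325
  expect_equal(L[8, 16], 10 * sec, tolerance = 1e-9)
  expect_equal(L[9, 17], 10 * sec, tolerance = 1e-9)

  empty <- ct_phantom(array(0L, dim = c(16, 16, 16)), 1,
                      list(bundled_material("water")))
  pv0 <- forward_paths(empty, geom, 45)
  expect_true(all(pv0$lengths == 0))
})

test_that("oblique Siddon paths agree with a dense ray-marching oracle", {
  geom <- micro_geometry()
  ph <- micro_water()
  ang <- 37.5
  pv <- forward_paths(ph, geom, ang)
  src <- pcctk:::source_position(geom, ang)
  px <- pcctk:::detector_pixel_positions(geom, ang)
  vox <- ph$voxel_mm; n <- dim(ph$labels)[1]
  set.seed(11)
  for (idx in sample(which(pv$lengths[, 1] > 5), 5)) {
    p <- px[idx, ]
    len <- sqrt(sum((p - src)^2))
    tt <- seq(0, 1, by = 0.01 * vox / len)  # 0.01-voxel marching step
    pts <- cbind(src[1] + tt * (p[1] - src[1]),
                 src[2] + tt * (p[2] - src[2]),
                 src[3] + tt * (p[3] - src[3]))
    ijk <- floor(sweep(pts, 2, -n * vox / 2) / vox) + 1
    ok <- ijk >= 1 & ijk <= n
    inside <- rowSums(ok) == 3
    lab <- rep(0L, length(tt))
    lab[inside] <- ph$labels[ijk[inside, , drop = FALSE]]
    march <- sum(lab == 1L) * 0.01 * vox
    expect_equal(pv$lengths[idx, 1], march, tolerance = 0.005)
  }
})

test_that("detected counts follow Beer-Lambert, gain, and saturation", {
  geom <- micro_geometry()
  sp <- generate_spectrum(photons_per_pixel = 3000)
  det <- ideal_detector(geom)
  empty <- ct_phantom(array(0L, dim = c(8, 8, 8)), 1,
                      list(bundled_material("water")))
  pv <- forward_paths(empty, geom, 0)
  flat <- detect_counts(pv, sp, det, "total", noise = FALSE)
  w <- pmin(pmax(sp$energies_keV + 0.5 - 15, 0), 1)
  expect_true(all(flat == round(sum(sp$fluence * w))))

  # gain 2 doubles counts exactly before clipping
  det2 <- detector_model(geom$n_rows, geom$n_channels,
                         gain = matrix(2, geom$n_rows, geom$n_channels),
                         counter_max = 100000L)
  flat2 <- detect_counts(pv, sp, det2, "total", noise = FALSE)
  expect_equal(unclass(flat2), 2 * unclass(flat), ignore_attr = TRUE)

  # a 12-bit counter saturates at 4096 under a hot beam
  hot <- generate_spectrum(photons_per_pixel = 1e6)
  sat <- detect_counts(pv, hot, det, "total", noise = FALSE)
  expect_true(all(sat == 4096))
  noisy <- detect_counts(pv, hot, det, "total", seed = 1, noise = TRUE)
  expect_lte(max(noisy), 4096)
})

test_that("bin nesting holds: High counts never exceed Total (noiseless)", {
  geom <- micro_geometry(n_views = 4L)
  sp <- generate_spectrum()
  det <- random_detector(geom, seed = 2, threshold_sigma_keV = 0.3)
  ph <- micro_water()
  scan <- acquire_scan(ph, geom, det, sp, noise = FALSE, n_flat = 1L)
  expect_true(all(scan$high$data <= scan$total$data))
  expect_true(all(scan$flats$high <= scan$flats$total))
})

test_that("seeded acquisition is bit-reproducible", {
  geom <- micro_geometry(n_views = 3L)
  sp <- generate_spectrum()
  det <- random_detector(geom, seed = 5, n_bad = 4L)
  ph <- micro_water()
  s1 <- acquire_scan(ph, geom, det, sp, seed = 77)
  s2 <- acquire_scan(ph, geom, det, sp, seed = 77)
  expect_identical(s1$total$data, s2$total$data)
  expect_identical(s1$flats$high, s2$flats$high)
  s3 <- acquire_scan(ph, geom, det, sp, seed = 78)
  expect_false(identical(s3$total$data, s1$total$data))
})

test_that("slab series covers the thickness grid and obeys Beer-Lambert", {
  geom <- micro_geometry()
  sp <- generate_spectrum()
  det <- ideal_detector(geom)
  series <- acquire_slab_series(geom = geom, det = det, spectrum = sp,
                                noise = FALSE)
  expect_length(series, 7L * 8L)

  # (0, 0) combination equals the flat field
  z <- Filter(function(s) s$pmma_mm == 0 && s$al_mm == 0, series)[[1]]
  flat <- pcctk:::average_flat(geom, sp, det, "total", 1L, NULL, FALSE)
  # slab frames are integer counts, the analytic flat is not: within 1 count
  expect_lt(max(abs(unclass(z$total) - unclass(flat))), 1)

  # counts strictly decrease with added PMMA at fixed aluminium
  at <- function(p, a, bin) {
    s <- Filter(function(x) x$pmma_mm == p && x$al_mm == a, series)[[1]]
    unclass(s[[bin]])
  }
  expect_true(all(at(5, 1, "total") < at(0, 1, "total")))
  expect_true(all(at(20, 1, "total") < at(10, 1, "total")))
  expect_error(acquire_slab_series(pmma_mm = c(-5, 0), geom = geom,
                                   det = det, spectrum = sp),
               "non-negative")
})

test_that("mean of seeded noisy flats converges to the analytic expectation", {
  # Poisson law: mean of N repeats within 4 sigma / sqrt(N) per pixel
  geom <- scan_geometry(pixel_mm = 0.75, n_channels = 32L, n_rows = 32L,
                        n_views = 4L)
  sp <- generate_spectrum(photons_per_pixel = 2000)
  det <- random_detector(geom, seed = 3, threshold_sigma_keV = 0.3)
  lam <- unclass(pcctk:::average_flat(geom, sp, det, "total", 1L, NULL,
                                      noise = FALSE))
  N <- 200L
  acc <- matrix(0, geom$n_rows, geom$n_channels)
  for (i in seq_len(N))
    acc <- acc + unclass(pcctk:::average_flat(geom, sp, det, "total", 1L,
                                              seed = 1000L + i, noise = TRUE))
  m <- acc / N
  bound <- 4 * sqrt(lam) / sqrt(N)
  expect_true(all(abs(m - lam) <= bound))
})

test_that("scan trees round-trip through the directory scanner", {
  geom <- micro_geometry(n_views = 5L)
  sp <- generate_spectrum()
  det <- ideal_detector(geom)
  ph <- micro_water()
  scan <- acquire_scan(ph, geom, det, sp, seed = 1, noise = FALSE, n_flat = 1L)
  root <- withr::local_tempdir()
  write_scan_tree(scan, geom, root)
  man <- scan_directory(root, "walnut_couch")
  expect_equal(nrow(man), 2L * 5L)
  back <- read_raw_frame(man$path[man$bin == "total" & man$index == 2],
                         raw_frame_spec(geom$n_channels, geom$n_rows))
  expect_equal(unclass(back), scan$total$data[, , 3], ignore_attr = TRUE)

  series <- acquire_slab_series(pmma_mm = c(0, 10), al_mm = c(0, 1),
                                geom = geom, det = det, spectrum = sp,
                                noise = FALSE)
  sroot <- withr::local_tempdir()
  write_slab_series(series, sroot)
  sm <- scan_directory(sroot, "slab_series")
  expect_equal(nrow(sm), 4L * 2L)
})
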