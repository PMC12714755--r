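mk_counts <- function(vals, bin = "total")
  proj_image(matrix(vals, 2, 2), bin = bin, kind = "counts", angle_deg = 0)

test_that("low bin is total minus high, clipped at zero with telemetry", {
  low <- derive_low(mk_counts(100), mk_counts(30, "high"))
  expect_true(all(low == 70))
  expect_identical(attr(low, "bin"), "low")
  expect_identical(attr(low, "clip_count"), 0L)

  eq <- derive_low(mk_counts(55), mk_counts(55, "high"))
  expect_true(all(eq == 0))

  clip <- derive_low(mk_counts(c(30, 100, 100, 100)),
                     mk_counts(c(40, 10, 10, 10), "high"))
  expect_equal(unclass(clip)[1, 1], 0)
  expect_identical(attr(clip, "clip_count"), 1L)

  expect_error(derive_low(mk_counts(10), proj_image(matrix(1, 3, 3))),
               "identical shape")
})

test_that("air correction computes -ln(I_obj/I_air) with a one-count clamp", {
  air <- mk_counts(1000)
  expect_true(all(abs(air_correct(mk_counts(1000), air)) < 1e-12))
  expect_equal(unclass(air_correct(mk_counts(1000 / exp(1)), air))[1, 1], 1,
               tolerance = 1e-3)
  # zero object counts hit the clamp: P = ln(1000)
  expect_equal(unclass(air_correct(mk_counts(0), air))[1, 1], log(1000),
               tolerance = 1e-12)
  expect_identical(attr(air_correct(mk_counts(10), air), "kind"), "log")
  expect_error(air_correct(mk_counts(10), mk_counts(0)), "all-zero")
  expect_error(air_correct(mk_counts(10), mk_counts(5, "high")), "bin")
})

test_that("air correction inverts exactly: exp(-P) * I_air == clamped I_obj", {
  set.seed(4)
  obj <- proj_image(matrix(rpois(64, 800), 8, 8))
  air <- proj_image(matrix(rpois(64, 1000) + 1, 8, 8))
  P <- air_correct(obj, air)
  back <- exp(-unclass(P)) * pmax(unclass(air), 1)
  expect_equal(back, pmax(unclass(obj), 1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("count-domain bin additivity survives the log chain (noiseless)", {
  geom <- micro_geometry(n_views = 2L)
  sp <- generate_spectrum()
  det <- ideal_detector(geom)
  scan <- acquire_scan(micro_water(), geom, det, sp, noise = FALSE,
                       n_flat = 1L)
  low <- derive_low(scan$total, scan$high)
  # Total = High + Low exactly where no clipping occurred
  expect_equal(scan$total$data, scan$high$data + low$data, tolerance = 1e-9)
  flat_low <- derive_low(scan$flats$total, scan$flats$high)
  Pl <- air_correct(low, flat_low)
  expect_true(all(is.finite(Pl$data)))
})

test_that("uniformity surface fitting recovers quadratics and spikes", {
  nr <- 12; nc <- 20
  i <- matrix((seq_len(nr) - 1) / (nr - 1), nr, nc)
  j <- matrix((seq_len(nc) - 1) / (nc - 1), nr, nc, byrow = TRUE)
  quad <- 2 + 0.5 * i - 0.3 * j + 0.2 * i^2 - 0.4 * i * j + 0.1 * j^2
  fit <- fit_uniformity_surface(proj_image(quad, kind = "log"))
  expect_lt(max(abs(fit$residual)), 1e-10)

  spiked <- quad; spiked[5, 7] <- spiked[5, 7] + 1
  fit2 <- fit_uniformity_surface(proj_image(spiked, kind = "log"))
  expect_equal(which.max(abs(fit2$residual)), which(row(quad) == 5 & col(quad) == 7))
  expect_gt(fit2$residual[5, 7], 0.9)
  expect_lt(max(abs(fit2$residual[-which(row(quad) == 5 & col(quad) == 7)])),
            0.1)

  const <- fit_uniformity_surface(proj_image(matrix(3.7, 8, 8), kind = "log"))
  expect_lt(max(abs(const$surface - 3.7)), 1e-10)

  expect_error(fit_uniformity_surface(proj_image(matrix(1, 8, 8), kind = "log"),
                                      good_mask = matrix(FALSE, 8, 8)),
               "fewer than 6")
})

test_that("bad-pixel detection uses strict below-5 / above-4090 rules", {
  m <- matrix(2000L, 6, 6)
  m[2, 3] <- 4L    # below 5: bad
  m[2, 4] <- 5L    # exactly 5: good
  m[5, 5] <- 4091L # above 4090: bad
  m[5, 6] <- 4090L # exactly 4090: good
  st <- proj_stack(array(m, dim = c(6, 6, 2)), c(0, 1))
  bad <- detect_bad_pixels(st)
  expect_equal(nrow(bad), 2L)
  expect_true(any(bad$row == 2 & bad$channel == 3))
  expect_true(any(bad$row == 5 & bad$channel == 5))

  clean <- proj_stack(array(2000L, dim = c(4, 4, 3)), c(0, 1, 2))
  expect_equal(nrow(detect_bad_pixels(clean)), 0L)

  # union with a prior table
  prior <- data.frame(row = 1L, channel = 1L)
  expect_equal(nrow(detect_bad_pixels(clean, prior = prior)), 1L)
})

test_that("bad pixels are linearly interpolated along their row", {
  m <- matrix(0, 3, 4)
  m[1, ] <- c(10, -99, 20, 30)
  m[2, ] <- c(10, -99, -99, 40)
  m[3, ] <- c(-99, 7, 8, 9)
  bad <- data.frame(row = c(1L, 2L, 2L, 3L), channel = c(2L, 2L, 3L, 1L))
  out <- interp_bad_pixels(m, bad)
  expect_equal(out[1, 2], 15)
  expect_equal(out[2, 2:3], c(20, 30))
  expect_equal(out[3, 1], 7)  # edge run takes nearest good value

  allbad <- data.frame(row = 1L, channel = 1:4)
  expect_error(interp_bad_pixels(matrix(1, 1, 4), allbad), "no good pixels")
})
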