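# analytic log projections of an infinite cylinder (radius R, attenuation
# mu per mm): independent line-integral oracle for FDK fidelity
analytic_cylinder_stack <- function(geom, R = 10, mu = 0.02) {
  K <- geom$n_views
  data <- array(0, dim = c(geom$n_rows, geom$n_channels, K))
  for (k in seq_len(K)) {
    src <- pcctk:::source_position(geom, geom$angles_deg[k])
    px <- pcctk:::detector_pixel_positions(geom, geom$angles_deg[k])
    d <- sweep(px, 2, src)
    dn <- d / sqrt(rowSums(d^2))
    A <- dn[, 1]^2 + dn[, 2]^2
    B <- 2 * (src[1] * dn[, 1] + src[2] * dn[, 2])
    C <- src[1]^2 + src[2]^2 - R^2
    disc <- pmax(B^2 - 4 * A * C, 0)
    data[, , k] <- matrix(mu * sqrt(disc) / A, geom$n_rows, geom$n_channels)
  }
  proj_stack(data, geom$angles_deg, bin = "total", kind = "log")
}

fdk_fixture <- function() cached("fdk", {
  geom <- micro_geometry(n_views = 90L)
  st <- analytic_cylinder_stack(geom)
  vol <- fdk_reconstruct(st, geom, vol_spec = list(n = 48, voxel_mm = 0.8))
  list(geom = geom, st = st, vol = vol)
})

test_that("FDK is linear and maps zero projections to a zero volume", {
  fx <- fdk_fixture()
  zero <- fx$st; zero$data[] <- 0
  vz <- fdk_reconstruct(zero, fx$geom, vol_spec = list(n = 16, voxel_mm = 1))
  expect_true(all(vz$values == 0))

  sc <- fx$st; sc$data <- 2.5 * fx$st$data
  v2 <- fdk_reconstruct(sc, fx$geom, vol_spec = list(n = 24, voxel_mm = 1))
  v1 <- fdk_reconstruct(fx$st, fx$geom, vol_spec = list(n = 24, voxel_mm = 1))
  expect_equal(v2$values, 2.5 * v1$values, tolerance = 1e-10)

  short <- proj_stack(fx$st$data[, , 1:30],
                      fx$st$angles_deg[1:30], "total", "log")
  expect_error(fdk_reconstruct(short, fx$geom), "360")
})

test_that("FDK recovers the attenuation of an analytic water cylinder", {
  fx <- fdk_fixture()
  v <- fx$vol$values
  ax <- (seq_len(48) - 24.5) * 0.8
  R2 <- outer(ax^2, ax^2, "+")
  sel <- array(FALSE, dim(v)); sel[, , 22:27] <- R2 <= 6^2
  expect_equal(mean(v[sel]), 0.02, tolerance = 0.03)
  expect_identical(fx$vol$units, "mu_per_mm")
})

test_that("FDK of a rotationally symmetric object is rotationally symmetric", {
  fx <- fdk_fixture()
  mid <- fx$vol$values[, , 24]
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  spread <- vapply(c(4, 8, 11) / 0.8, function(r) {
    vals <- pcctk:::bilinear(mid, 24.5 + r * sin(th), 24.5 + r * cos(th))
    diff(range(vals))
  }, numeric(1))
  expect_lt(max(spread), 0.02 * diff(range(mid)) + 1e-12)
})

test_that("TV denoising fixes constants, suppresses noise, preserves edges", {
  const <- ct_volume(array(5, dim = c(16, 16, 16)), 1)
  expect_equal(tv_denoise(const)$values, const$values, tolerance = 1e-12)

  set.seed(21)
  n <- 32
  truth <- array(0, dim = c(n, n, n))
  truth[9:24, 9:24, 9:24] <- 100
  noisy <- truth + array(rnorm(n^3, 0, 10), dim = c(n, n, n))
  den <- tv_denoise(ct_volume(noisy, 1), niter = 100, lam = 20)$values
  flat <- den[12:21, 12:21, 12:21]
  expect_lt(sd(flat), 0.5 * 10)
  # edge half-max crossing stays within one voxel
  prof <- apply(den[, 12:21, 12:21], 1, mean)
  half <- min(which(prof > 50))
  expect_lte(abs(half - 9), 1)

  # weight -> 0 limit returns the input
  near <- tv_denoise(ct_volume(noisy, 1), niter = 50, lam = 0.01)$values
  expect_lt(max(abs(near - noisy)), 0.5)

  # never increases total variation
  for (s in 1:3) {
    set.seed(s)
    x <- array(rnorm(12^3), dim = c(12, 12, 12))
    v <- ct_volume(x, 1)
    expect_lte(total_variation(tv_denoise(v, niter = 30, lam = 10)),
               total_variation(v))
  }
})

test_that("HU conversion follows the water-normalisation identity", {
  uni <- ct_volume(array(0.025, dim = c(8, 8, 8)), 1)
  sc <- hu_scale_from_water(uni, roi = array(TRUE, dim = c(8, 8, 8)))
  expect_equal(as.numeric(sc), 1000 / 0.025)

  vals <- array(c(0, 0.025, 0.05), dim = c(3, 1, 1))
  hu <- to_hounsfield(ct_volume(vals, 1), sc)
  expect_equal(as.numeric(hu$values), c(-1000, 0, 1000))
  expect_identical(hu$units, "HU")
  expect_error(to_hounsfield(hu, sc), "mu_per_mm")

  air <- ct_volume(array(1e-12, dim = c(8, 8, 8)), 1)
  expect_error(hu_scale_from_water(air, roi = array(TRUE, dim = c(8, 8, 8))),
               "not a water region")
})

test_that("ring power metric is zero for radial fields and quadratic in amplitude", {
  n <- 64
  ax <- seq_len(n) - (n + 1) / 2
  R <- sqrt(outer(ax^2, ax^2, "+"))
  radial <- 100 * exp(-R / 20)
  # floor comes only from polar-resampling interpolation wiggle
  expect_lt(ring_power_metric(radial), 1e-3 * var(as.numeric(radial)))

  pw <- vapply(c(3, 6, 12), function(a)
    ring_power_metric(radial + a * sin(R * 2)), numeric(1))
  expect_equal(pw[2] / pw[1], 4, tolerance = 0.1)
  expect_equal(pw[3] / pw[1], 16, tolerance = 0.1)

  expect_error(ring_power_metric(radial, center = c(-5, 10)), "outside")
})
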