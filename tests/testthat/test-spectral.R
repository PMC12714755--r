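test_that("normalized attenuation maps HU to the water-1000 scale", {
  hu <- ct_volume(array(c(-1000, 0, 1000), dim = c(3, 1, 1)), 1, units = "HU")
  expect_equal(as.numeric(na_from_hu(hu)), c(0, 1000, 2000))
  mu <- ct_volume(array(1, dim = c(2, 2, 2)), 1)
  expect_error(na_from_hu(mu), "HU")
})

test_that("decomposition matrices come out right and reject collinear bases", {
  # a water sample (0 HU in both bins, density 1) contributes the column
  # (1000, 1000)
  mh <- cbind(water = c(0, 0), other = c(500, 250))
  M <- md_matrix_from_samples(mh, c(1, 1.5))
  expect_equal(M$entries[, 1], c(1000, 1000), ignore_attr = TRUE)
  expect_equal(M$entries[, 2], c(1500, 1250) / 1.5, ignore_attr = TRUE)
  expect_true(is.finite(M$condition))

  same <- cbind(a = c(200, 100), b = c(200, 100))
  expect_error(md_matrix_from_samples(same, c(1, 1)), "collinear")

  # sample means synthesized from the analytic forward model reproduce the
  # analytic matrix
  sp <- generate_spectrum()
  eL <- bin_effective_energy(sp, 15, 30); eH <- bin_effective_energy(sp, 30)
  Ma <- md_matrix_analytic(bundled_material("walnut_shell"),
                           bundled_material("walnut_pulp"), eL, eH)
  dens <- c(1.2, 0.95)
  mean_hu <- sweep(Ma$entries, 2, dens, "*") - 1000
  Mb <- md_matrix_from_samples(mean_hu, dens)
  expect_equal(Mb$entries, Ma$entries, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("decompose inverts the forward mixture model to machine precision", {
  sp <- generate_spectrum()
  M <- md_matrix_analytic(bundled_material("water"),
                          bundled_material("hydroxyapatite"),
                          bin_effective_energy(sp, 15, 30),
                          bin_effective_energy(sp, 30))
  # a voxel holding exactly 1 g/cm^3 of basis material m reads back as
  # (1000, 0) mg/cm^3
  na_col <- M$entries[, 1]
  hu_low <- ct_volume(array(na_col[1] - 1000, dim = c(2, 2, 2)), 1,
                      units = "HU")
  hu_high <- ct_volume(array(na_col[2] - 1000, dim = c(2, 2, 2)), 1,
                       units = "HU")
  d <- decompose(hu_low, hu_high, M)
  expect_equal(as.numeric(d$rho1$values), rep(1000, 8), tolerance = 1e-9)
  expect_equal(as.numeric(d$rho2$values), rep(0, 8), tolerance = 1e-9)

  # 100 seeded random density fields: synthesize NA via the forward model,
  # decompose, recover exactly
  set.seed(33)
  for (i in 1:100) {
    rho <- matrix(runif(2 * 6, -0.2, 2.5), 2)  # g/cm^3, negatives allowed
    na <- M$entries %*% rho
    hl <- ct_volume(array(na[1, ] - 1000, dim = c(6, 1, 1)), 1, units = "HU")
    hh <- ct_volume(array(na[2, ] - 1000, dim = c(6, 1, 1)), 1, units = "HU")
    d <- decompose(hl, hh, M)
    expect_equal(as.numeric(d$rho1$values), rho[1, ] * 1000,
                 tolerance = 1e-9)
    expect_equal(as.numeric(d$rho2$values), rho[2, ] * 1000,
                 tolerance = 1e-9)
  }
  expect_error(decompose(hu_low,
                         ct_volume(array(0, dim = c(3, 3, 3)), 1,
                                   units = "HU"), M),
               "identical shape")
})

test_that("decomposition noise amplification matches the inverse row norms", {
  sp <- generate_spectrum()
  M <- md_matrix_analytic(bundled_material("walnut_shell"),
                          bundled_material("walnut_pulp"),
                          bin_effective_energy(sp, 15, 30),
                          bin_effective_energy(sp, 30))
  inv <- solve(M$entries)
  set.seed(5)
  n <- 24
  sigma <- 30
  hl <- ct_volume(array(rnorm(n^3, 0, sigma), dim = c(n, n, n)), 1,
                  units = "HU")
  hh <- ct_volume(array(rnorm(n^3, 0, sigma), dim = c(n, n, n)), 1,
                  units = "HU")
  d <- decompose(hl, hh, M)
  expect_equal(sd(d$rho1$values) / (sigma * 1000),
               sqrt(sum(inv[1, ]^2)), tolerance = 0.05)
  expect_equal(sd(d$rho2$values) / (sigma * 1000),
               sqrt(sum(inv[2, ]^2)), tolerance = 0.05)
})

test_that("VMI synthesis honours the water reference at every energy", {
  mk <- function(w, h) list(
    rho1 = ct_volume(array(w, dim = c(2, 2, 2)), 1, units = "mg_per_cm3"),
    rho2 = ct_volume(array(h, dim = c(2, 2, 2)), 1, units = "mg_per_cm3"))
  for (E in c(15, 30, 47, 80)) {
    vmi <- synthesize_vmi(mk(1000, 0), E)
    expect_equal(as.numeric(vmi$values), rep(0, 8), tolerance = 1e-9)
  }
  expect_equal(as.numeric(synthesize_vmi(mk(0, 0), 40)$values),
               rep(-1000, 8), tolerance = 1e-9)

  # HAP-bearing voxels lose HU monotonically with energy (photoelectric
  # contrast decays), and VMI is linear in the density maps
  hus <- vapply(15:80, function(E)
    synthesize_vmi(mk(1000, 200), E)$values[1], numeric(1))
  expect_true(all(diff(hus) < 0))
  a <- synthesize_vmi(mk(500, 100), 50)$values
  b <- synthesize_vmi(mk(1000, 200), 50)$values
  expect_equal(b + 1000, 2 * (a + 1000), tolerance = 1e-9)

  expect_error(synthesize_vmi(mk(1, 1), 10), "range")
})
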