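test_that("refractive index takes the absorbing branch", {
  expect_equal(refractive_index(4), 2 + 0i, tolerance = 1e-14)
  expect_equal(refractive_index(-1), 0 + 1i, tolerance = 1e-14)
  expect_equal(refractive_index(3 + 4i), 2 + 1i, tolerance = 1e-14)
  set.seed(3)
  z <- complex(real = stats::rnorm(50), imaginary = stats::rnorm(50))
  N <- refractive_index(z)
  expect_true(all(Im(N) >= 0))
  expect_equal(N^2, z, tolerance = 1e-12)
})

test_that("decadic absorption coefficient", {
  expect_equal(absorption_coefficient(100, 0), 0)
  expect_equal(absorption_coefficient(100, 0.1),
               4 * pi * 100 * 0.1 * log10(exp(1)), tolerance = 1e-12)
  expect_equal(absorption_coefficient(100, 0.1), 54.575, tolerance = 1e-4)
  expect_equal(absorption_coefficient(200, 0.1),
               2 * absorption_coefficient(100, 0.1), tolerance = 1e-12)
})

test_that("concentration of unit cells", {
  expect_equal(concentration(0.1, 19.15), 8.672, tolerance = 1e-3)
  expect_equal(concentration(0.2, 19.15), 2 * concentration(0.1, 19.15),
               tolerance = 1e-12)
  # identity C * V * N_A = f * 1000 (with V in cm^3)
  uc <- unit_constants()
  expect_equal(concentration(0.37, 123) * 123e-24 * uc$n_avogadro,
               0.37 * 1000, tolerance = 1e-10)
})

test_that("integrated molar absorption unit bridge", {
  a1 <- integrated_molar_absorption(1)
  expect_equal(a1, 4225.6, tolerance = 0.0005 * 4225.6)
  expect_equal(a1 / 100, 42.256, tolerance = 0.022)   # km/mol equivalence
  expect_equal(integrated_molar_absorption(0), 0)
  expect_equal(integrated_molar_absorption(2, degeneracy = 3), 6 * a1,
               tolerance = 1e-12)
})

test_that("molecular spectrum: Lorentzian height, area, additivity", {
  band <- tibble::tibble(frequency = 500, a_integrated = 4225.6, sigma = 10)
  grid <- seq(500 - 500, 500 + 500, by = 0.05)   # +/- 50 sigma
  sp <- molecular_spectrum(band, grid, concentration = 2)
  expect_equal(max(sp$molar_absorption), 2 * 4225.6 / (pi * 10),
               tolerance = 1e-6)
  expect_equal(max(sp$molar_absorption), 268.99, tolerance = 1e-4 * 268.99)
  area <- sum(sp$molar_absorption) * 0.05
  expect_equal(area, 4225.6, tolerance = 0.005 * 4225.6)
  # alpha = C a pointwise, exactly
  expect_equal(sp$absorption, 2 * sp$molar_absorption, tolerance = 1e-14)
  # two identical bands double the spectrum pointwise
  two <- molecular_spectrum(dplyr::bind_rows(band, band), grid)
  expect_equal(two$molar_absorption, 2 * sp$molar_absorption / 1,
               tolerance = 1e-12)
})

test_that("powder spectrum pipeline: consistency and Froehlich limit", {
  m <- mgo_model(sigma = 10)
  sc <- mixing_scenario("maxwell", 0.1, 2, sphere_L(), m$cell_volume)
  sp <- powder_spectrum(m, sc, spectral_grid(300, 800, 0.2))
  # a * C = alpha pointwise
  C <- attr(sp, "concentration")
  expect_equal(sp$molar_absorption * C, sp$absorption, tolerance = 1e-12)
  expect_true(all(sp$absorption >= 0))
  # dilute, lightly damped sphere: peak at the Froehlich frequency
  eps_s <- mgo_static()
  target <- 388.3 * sqrt((eps_s + 2 * 2) / (3.14 + 2 * 2))
  m2 <- mgo_model(sigma = 1)
  sc2 <- mixing_scenario("maxwell", 1e-6, 2, sphere_L(), m2$cell_volume)
  grid <- spectral_grid(480, 620, 0.1)
  sp2 <- powder_spectrum(m2, sc2, grid)
  pk <- find_spectrum_peaks(sp2)
  expect_equal(pk$wavenumber[which.max(pk$height)], target, tolerance = 0.1 /
                 target)
  # for eps_e = 1 the dilute sphere peak lies strictly between TO and LO
  sc3 <- mixing_scenario("maxwell", 1e-6, 1, sphere_L(), m2$cell_volume)
  sp3 <- powder_spectrum(m2, sc3, spectral_grid(300, 800, 0.1))
  pk3 <- find_spectrum_peaks(sp3)
  nu3 <- pk3$wavenumber[which.max(pk3$height)]
  expect_gt(nu3, 388.3)
  expect_lt(nu3, 388.3 * sqrt(eps_s / 3.14))
})

test_that("AP route peaks at the TO frequencies at low loading", {
  cal <- from_oscillator_table(reference_models()$calcite, sigma = 5)
  sc <- mixing_scenario("ap", 0.01, 2, sphere_L(), cal$cell_volume)
  sp <- powder_spectrum(cal, sc, spectral_grid(600, 800, 0.2))
  pk <- find_spectrum_peaks(sp, min_height = 0.05)
  expect_equal(sort(pk$wavenumber), c(620.1, 732.0), tolerance = 1e-3)
})

test_that("grid machinery: inclusive endpoints and refinement stability", {
  g <- spectral_grid(0, 300, 0.2)
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 300, tolerance = 1e-9)
  expect_equal(diff(g)[1], 0.2, tolerance = 1e-12)
  expect_error(spectral_grid(10, 5), "v_min")
  # halving the increment moves no reported peak by more than a coarse step
  m <- mgo_model(sigma = 10)
  sc <- mixing_scenario("maxwell", 0.1, 2, sphere_L(), m$cell_volume)
  p1 <- find_spectrum_peaks(powder_spectrum(m, sc, spectral_grid(300, 800,
                                                                 0.8)))
  p2 <- find_spectrum_peaks(powder_spectrum(m, sc, spectral_grid(300, 800,
                                                                 0.4)))
  expect_equal(p1$wavenumber[which.max(p1$height)],
               p2$wavenumber[which.max(p2$height)], tolerance = 0.8 / 500)
})

test_that("refractive branch stays physical across fixtures x shapes x rules", {
  models <- list(mgo_model(10),
                 from_oscillator_table(reference_models()$zno, sigma = 5),
                 from_oscillator_table(reference_models()$calcite, sigma = 5))
  cell <- crystal_cell(diag(3) * 5)
  shapes <- list(shape_depolarization(cell, shape_spec("sphere")),
                 shape_depolarization(cell, shape_spec("plate", c(0, 0, 1))),
                 shape_depolarization(cell, shape_spec("needle", c(0, 0, 1))))
  grid <- spectral_grid(100, 1600, 5)
  for (m in models) {
    eps_i <- permittivity(m, grid)
    for (sh in shapes) {
      for (method in c("maxwell", "ap")) {
        sc <- mixing_scenario(method, 0.1, 2, sh, m$cell_volume)
        eff <- effective_medium(sc, eps_i)
        expect_true(all(Im(refractive_index(eff$values)) >= 0))
      }
    }
  }
})
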