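test_that("Young's modulus recovers the slope of the linear region", {
  eps <- seq(0, 0.2, by = 0.002)
  exact <- stress_strain_curve(eps, 4.1e6 * eps)
  expect_equal(young_modulus(exact), 4.1e6, tolerance = 1e-12)

  flat <- stress_strain_curve(eps, rep(0, length(eps)))
  expect_equal(young_modulus(flat), 0, tolerance = 1e-12)

  set.seed(12)
  noisy <- stress_strain_curve(eps, 4.1e6 * eps +
                                 rnorm(length(eps), 0, 0.01 * 4.1e6 * 0.2))
  expect_equal(young_modulus(noisy), 4.1e6, tolerance = 0.05)

  expect_error(young_modulus(exact, strain_window = c(0.9, 1)), "window")
})

test_that("UTS is the curve maximum, also under post-peak softening", {
  eps <- seq(0, 1, by = 0.01)
  rising <- stress_strain_curve(eps, 6e6 * eps)
  expect_equal(ultimate_tensile_strength(rising), 6e6)

  soft <- generate_stress_strain(pdms_4to1(), "dogbone_tension")
  expect_equal(ultimate_tensile_strength(soft), 6e6, tolerance = 1e-12)
  # the peak is interior, not the final sample
  expect_lt(soft$stress[length(soft$stress)],
            ultimate_tensile_strength(soft))
})

test_that("pure-shear tearing energy follows Gc = W(lambda_c) * h0", {
  # constructed so that W(lambda_c) = 9.8 kJ/m^3 exactly: linear curve,
  # sigma = E*eps, W = E*eps^2/2
  E <- 4.1e6
  eps <- seq(0, 0.2, length.out = 400)
  curve <- stress_strain_curve(eps, E * eps,
                               test_type = "pure_shear_unnotched")
  eps_c <- sqrt(2 * 9.8e3 / E)
  # trapezoid on a linear function is exact
  pair <- pure_shear_pair(curve, 1 + eps_c, 10e-3)
  expect_equal(tearing_energy_pure_shear(pair), 98, tolerance = 1e-6)

  # doubling the specimen height doubles the tearing energy
  pair2 <- pure_shear_pair(curve, 1 + eps_c, 20e-3)
  expect_equal(tearing_energy_pure_shear(pair2), 196, tolerance = 1e-6)

  # zero stress stores no energy
  dead <- stress_strain_curve(eps, rep(0, length(eps)),
                              test_type = "pure_shear_unnotched")
  expect_equal(tearing_energy_pure_shear(pure_shear_pair(dead, 1.1, 1e-2)),
               0)

  # a curve shorter than the critical stretch is unusable
  expect_error(tearing_energy_pure_shear(pure_shear_pair(curve, 1.5, 1e-2)),
               "span")
})

test_that("tearing energy is stable under resampling density", {
  m <- pdms_10to1()
  pair <- generate_stress_strain(m, "pure_shear", n_points = 400L)
  coarse <- generate_stress_strain(m, "pure_shear", n_points = 60L)
  g1 <- tearing_energy_pure_shear(pair)
  g2 <- tearing_energy_pure_shear(coarse)
  expect_equal(g1, m$Gc, tolerance = 1e-9)
  expect_equal(g2, m$Gc, tolerance = 1e-9)
  # evaluating the fine pair's W at the coarse pair's critical stretch
  # changes the estimate by < 0.5% (trapezoid convergence)
  cross <- strain_energy_density(pair$unnotched, coarse$critical_stretch) *
    coarse$specimen_height
  expect_equal(cross, m$Gc, tolerance = 0.005)
})

test_that("replicate summaries give mean, sample sd and length scale", {
  m <- summarize_material("demo", Gc = c(90, 98, 106),
                          sigma_c = rep(6e6, 3), E = rep(4.1e6, 3))
  expect_equal(m$Gc, 98)
  expect_equal(m$Gc_sd, 8)
  expect_equal(m$sigma_c_sd, 0)

  w <- testthat::capture_warnings(
    single <- summarize_material("one", Gc = 98, sigma_c = 6e6, E = 4.1e6))
  expect_match(w, "fewer than 2", all = TRUE)
  expect_length(w, 3)
  expect_equal(single$Gc_sd, 0)

  # a Table-1-like batch reproduces the 10:1 length scale
  m10 <- summarize_material("10:1-like", Gc = c(190, 197, 204),
                            sigma_c = c(5.4e6, 5.5e6, 5.6e6),
                            E = rep(1.6e6, 3))
  expect_equal(unname(material_length_scale(m10)[["value"]]), 35.8e-6,
               tolerance = 1e-3)
})

test_that("characterization pipeline recovers generator truth from batches", {
  for (mat in list(pdms_4to1(), pdms_10to1())) {
    batch <- generate_material_batch(mat, n = 8, noise = 0.002, seed = 31)
    est <- vapply(batch$specimens, function(s) {
      # PDMS stays linear well past 5% strain; the wider window keeps the
      # per-specimen slope noise below the specimen-to-specimen dispersion
      c(E = young_modulus(s$tensile, strain_window = c(0, 0.2)),
        UTS = ultimate_tensile_strength(s$tensile),
        Gc = tearing_energy_pure_shear(s$pure_shear))
    }, c(E = 0, UTS = 0, Gc = 0))
    fit <- summarize_material(mat$name, Gc = est["Gc", ],
                              sigma_c = est["UTS", ], E = est["E", ])
    # the pipeline must recover the specimens it was actually given ...
    expect_equal(fit$Gc, mean(batch$truth$Gc), tolerance = 0.01)
    expect_equal(fit$sigma_c, mean(batch$truth$sigma_c), tolerance = 0.005)
    expect_equal(fit$E, mean(batch$truth$E), tolerance = 0.05)
    # ... and the batch means must be consistent with the target material
    expect_equal(fit$Gc, mat$Gc, tolerance = 3 * mat$Gc_sd / sqrt(8) /
                   mat$Gc)
    expect_equal(fit$sigma_c, mat$sigma_c,
                 tolerance = 3 * mat$sigma_c_sd / sqrt(8) / mat$sigma_c)
    expect_equal(fit$E, mat$E, tolerance = 3 * mat$E_sd / sqrt(8) / mat$E)
  }
})

test_that("zero-noise generated specimens are recovered exactly", {
  m <- pdms_4to1()
  tens <- generate_stress_strain(m, "dogbone_tension")
  expect_equal(young_modulus(tens), m$E, tolerance = 1e-12)
  expect_equal(ultimate_tensile_strength(tens), m$sigma_c,
               tolerance = 1e-12)
  ps <- generate_stress_strain(m, "pure_shear")
  expect_equal(tearing_energy_pure_shear(ps), m$Gc, tolerance = 1e-9)
})
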