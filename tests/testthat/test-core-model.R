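test_that("lower-bound force is Gc*t with propagated uncertainty", {
  # thin tough pseudoleaf: the printed ~40 mN physical minimum
  lb <- lower_bound_force(pdms_10to1(), sheet_spec(200e-6))
  expect_equal(unname(lb[["F_min"]]), 39.4e-3, tolerance = 1e-10)

  # hand-propagated oracle: sqrt((210e-6*9)^2 + (98*10e-6)^2)
  m <- material_properties("m", Gc = 98, Gc_sd = 9, sigma_c = 6e6,
                           E = 4.1e6)
  lb2 <- lower_bound_force(m, sheet_spec(210e-6, 10e-6))
  expect_equal(unname(lb2[["F_min"]]), 20.58e-3, tolerance = 1e-10)
  expect_equal(unname(lb2[["F_min_sd"]]),
               sqrt((210e-6 * 9)^2 + (98 * 10e-6)^2), tolerance = 1e-12)

  # zero-toughness limit approaches zero force; Gc = 0 itself is rejected
  tiny <- material_properties("tiny", Gc = 1e-12, sigma_c = 1, E = 1)
  expect_lt(lower_bound_force(tiny, sheet_spec(1e-3))[["F_min"]], 1e-14)
  expect_error(material_properties("bad", Gc = 0, sigma_c = 1, E = 1),
               "positive")
})

test_that("propagated sd of Gc*t matches a Monte-Carlo estimate", {
  set.seed(101)
  for (mat in list(pdms_4to1(), pdms_10to1())) {
    t0 <- 210e-6
    t_sd <- 10e-6
    lb <- lower_bound_force(mat, sheet_spec(t0, t_sd))
    draws <- rnorm(1e5, mat$Gc, mat$Gc_sd) * rnorm(1e5, t0, t_sd)
    expect_equal(unname(lb[["F_min_sd"]]), sd(draws), tolerance = 0.05)
  }
})

test_that("sharpness number reproduces the pristine and worn regimes", {
  cfg <- cut_model_config()
  pristine <- blade_geometry(162e-9, label = "pristine")
  worn <- blade_geometry(11712e-9, label = "forager")

  expect_equal(sharpness_number(cfg, pdms_4to1(), pristine), 0.0198,
               tolerance = 1e-2)
  expect_equal(sharpness_number(cfg, pdms_10to1(), pristine), 0.00905,
               tolerance = 1e-2)
  expect_equal(sharpness_number(cfg, pdms_4to1(), worn), 1.434,
               tolerance = 1e-3)
  expect_lt(sharpness_number(cfg, pdms_10to1(), worn), 0.7)
  expect_identical(sharpness_number(cfg, pdms_4to1(), blade_geometry(0)), 0)
})

test_that("sharpness number is invariant under unit rescaling", {
  # rescale force by f and length by l: sigma_c ~ f/l^2, R ~ l, Gc ~ f/l
  cfg <- cut_model_config()
  f <- 1e3
  l <- 1e-2
  base <- sharpness_number(cfg, material_properties("m", 98, 6e6, 4e6),
                           blade_geometry(162e-9))
  scaled <- sharpness_number(
    cfg, material_properties("m", 98 * f / l, 6e6 * f / l^2, 4e6 * f / l^2),
    blade_geometry(162e-9 * l))
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("regime classification uses a strict threshold", {
  cfg <- cut_model_config()
  expect_identical(classify_sharpness(0.02, cfg), "ideally_sharp")
  expect_identical(classify_sharpness(1.4, cfg), "geometry_dominated")
  expect_identical(classify_sharpness(0.05, cfg), "transitional")
  expect_identical(classify_sharpness(0.3, cfg), "transitional")
  expect_identical(classify_sharpness(1, cfg), "geometry_dominated")
  expect_error(classify_sharpness(-0.1, cfg), "non-negative")
})

test_that("predicted force combines lower bound and geometric penalty", {
  cfg <- cut_model_config()
  # worn forager blade on the brittle thick pseudoleaf: ~95 mN (~100)
  p <- predict_cutting_force(cfg, pdms_4to1(), blade_geometry(11712e-9),
                             sheet_spec(400e-6))
  expect_equal(p$F_pred, 95.4e-3, tolerance = 1e-3)
  expect_equal(p$normalized_force - 1, p$omega, tolerance = 1e-15)
  expect_identical(p$regime, "geometry_dominated")

  # worn blade on the tough thin pseudoleaf (hand arithmetic)
  p2 <- predict_cutting_force(cfg, pdms_10to1(), blade_geometry(11712e-9),
                              sheet_spec(200e-6))
  expect_equal(p2$omega, 0.654, tolerance = 1e-3)
  expect_equal(p2$F_pred, 65.2e-3, tolerance = 1e-3)

  # ideally sharp limit collapses onto the lower bound exactly
  p0 <- predict_cutting_force(cfg, pdms_4to1(), blade_geometry(0),
                              sheet_spec(400e-6))
  expect_identical(p0$F_pred, p0$F_min)
  expect_identical(p0$regime, "ideally_sharp")
})

test_that("predicted force is strictly monotone in Gc, t, R, sigma_c, C", {
  base <- list(Gc = 98, sigma_c = 6e6, t = 300e-6, R = 2000e-9, C = 2)
  pred <- function(par) {
    predict_cutting_force(cut_model_config(C = par$C),
                          material_properties("m", par$Gc, par$sigma_c,
                                              4e6),
                          blade_geometry(par$R),
                          sheet_spec(par$t))$F_pred
  }
  for (field in names(base)) {
    lo <- base
    hi <- base
    hi[[field]] <- base[[field]] * 1.25
    expect_lt(pred(lo), pred(hi))
  }
})

test_that("critical radius inverts the sharpness number", {
  cfg <- cut_model_config()
  expect_equal(critical_radius(cfg, pdms_4to1(), 0.05), 408e-9,
               tolerance = 1e-2)
  expect_identical(critical_radius(cfg, pdms_4to1(), 0), 0)
  # median tropical leaf: sigma_c = 3 MPa, Gc = 400 J/m^2 -> 3.33 um
  leaf <- material_properties("median leaf", Gc = 400, sigma_c = 3e6,
                              E = 1e6)
  expect_equal(critical_radius(cfg, leaf, 0.05), 10 / 3 * 1e-6,
               tolerance = 1e-6)
  # consistency: at R = R_crit the force elevation equals the tolerance
  R <- critical_radius(cfg, pdms_10to1(), 0.07)
  expect_equal(sharpness_number(cfg, pdms_10to1(), blade_geometry(R)),
               0.07, tolerance = 1e-12)
})

test_that("material length scale matches the characterized substrates", {
  ls4 <- material_length_scale(pdms_4to1())
  expect_equal(unname(ls4[["value"]]), 16.3e-6, tolerance = 2.5e-3)
  expect_equal(unname(ls4[["sd"]]), 5.6e-6, tolerance = 1e-2)
  ls10 <- material_length_scale(pdms_10to1())
  expect_equal(unname(ls10[["value"]]), 35.8e-6, tolerance = 1e-3)
  expect_equal(unname(ls10[["sd"]]), 13.8e-6, tolerance = 1e-2)
  # infinite-strength limit: the length scale vanishes
  hard <- material_properties("hard", Gc = 98, sigma_c = 1e30, E = 1)
  expect_lt(material_length_scale(hard)[["value"]], 1e-27)
})
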