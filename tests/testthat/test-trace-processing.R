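test_that("traces read from CSV are unit-normalized and validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,force_mN", "0,0", "1,1", "2,2"), path)
  tr <- read_trace(path)
  expect_s3_class(tr, "force_trace")
  expect_equal(tr$force, c(0, 1e-3, 2e-3))
  expect_equal(tr$displacement, c(0, 1, 2) * 0.3e-3)

  writeLines(c("time_s,force_mN", "0,0", "2,1", "1,2"), path)
  expect_error(read_trace(path), "strictly increasing.*row 3")

  writeLines(c("a,b", "0,0", "1,1", "2,2"), path)
  expect_error(read_trace(path), "force column")
  tr2 <- read_trace(path, format_spec = list(a = "time_s", b = "force_mN"))
  expect_equal(tr2$force, c(0, 1e-3, 2e-3))

  # displacement column takes precedence over time * speed
  writeLines(c("displacement_mm,force_mN", "0,5", "1,5", "2,5"), path)
  tr3 <- read_trace(path)
  expect_equal(tr3$displacement, c(0, 1e-3, 2e-3))
})

test_that("written traces survive a read round trip", {
  set.seed(8)
  sim <- generate_force_trace(
    list(sample_id = "rt", edge_radius_m = 500e-9), pdms_4to1(),
    sheet_spec(200e-6), synthetic_study_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(sim$first, path)
  back <- read_trace(path, pass_id = "first")
  expect_equal(back$force, sim$first$force, tolerance = 1e-9)
  expect_equal(back$time, sim$first$time, tolerance = 1e-9)
})

test_that("steady-state detection recovers a clean plateau exactly", {
  tr <- ramp_plateau_trace(peak = 40e-3, plateau = 30e-3)
  w <- detect_steady_state(tr)
  expect_equal(w$mean_force, 30e-3, tolerance = 1e-12)
  expect_equal(w$force_sd, 0, tolerance = 1e-12)
  expect_equal(w$end_displacement - w$start_displacement, 2e-3,
               tolerance = 1 / 300 * 0.3e-3)
  # the window must start strictly after the initiation peak
  expect_gt(w$start_displacement, 0.8e-3)

  # constant trace: earliest admissible window, mean equals the constant
  wc <- detect_steady_state(constant_trace(level = 7e-3))
  expect_equal(wc$mean_force, 7e-3, tolerance = 1e-12)
  expect_equal(wc$start_displacement, 0, tolerance = 1e-12)
})

test_that("window never overlaps the initiation peak sample", {
  set.seed(21)
  for (i in 1:10) {
    tr <- ramp_plateau_trace(peak = runif(1, 35e-3, 60e-3),
                             plateau = 30e-3, peak_x = runif(1, 0.3e-3, 2e-3),
                             noise_sd = 1e-3)
    w <- detect_steady_state(tr)
    expect_gt(w$start_displacement, tr$displacement[w$peak_index])
  }
})

test_that("plateau mean under noise obeys the CLT bound", {
  set.seed(31)
  tr <- ramp_plateau_trace(plateau = 30e-3, noise_sd = 1e-3)
  w <- detect_steady_state(tr)
  expect_gt(w$n, 1500)
  expect_lt(abs(w$mean_force - 30e-3), 3 * 1e-3 / sqrt(w$n))
  expect_equal(w$force_sd, 1e-3, tolerance = 0.1)
})

test_that("short steady-state regions are rejected", {
  # peak at 4 mm of a 5 mm pass leaves < 2 mm of plateau
  tr <- ramp_plateau_trace(peak = 40e-3, plateau = 30e-3, peak_x = 4e-3)
  expect_error(detect_steady_state(tr), "insufficient steady state")
})

test_that("pass decomposition obeys Ff = Fc - Fs and flags sign cases", {
  w1 <- detect_steady_state(ramp_plateau_trace(plateau = 33e-3))
  w2 <- detect_steady_state(constant_trace(level = 4e-3),
                            start_displacement = w1$start_displacement)
  m <- decompose_passes(w1, w2)
  expect_equal(m$Ff, 29e-3, tolerance = 1e-12)
  expect_equal(m$Fc - m$Fs, m$Ff, tolerance = 1e-15)
  expect_equal(spacing_fraction(m), 4 / 33, tolerance = 1e-12)
  expect_true(is.na(m$flag))

  # zero spacing force: fracture force equals the total
  w0 <- detect_steady_state(constant_trace(level = 0),
                            start_displacement = w1$start_displacement)
  expect_equal(decompose_passes(w1, w0)$Ff, 33e-3, tolerance = 1e-12)

  # spacing force above the total: retained but flagged
  wbig <- detect_steady_state(constant_trace(level = 35e-3),
                              start_displacement = w1$start_displacement)
  expect_warning(mneg <- decompose_passes(w1, wbig), "exceeds")
  expect_equal(mneg$Ff, -2e-3, tolerance = 1e-12)
  expect_identical(mneg$flag, "negative_fracture_force")
})

test_that("thickness correction scales all forces and is invertible", {
  w1 <- detect_steady_state(ramp_plateau_trace(plateau = 50e-3))
  w2 <- detect_steady_state(constant_trace(level = 5e-3),
                            start_displacement = w1$start_displacement)
  m <- decompose_passes(w1, w2)

  mc <- thickness_correct(m, 300e-6, 317e-6)
  expect_equal(mc$Fc, 50e-3 * 317 / 300, tolerance = 1e-12)
  expect_equal(mc$Fc, mc$Ff + mc$Fs, tolerance = 1e-15)
  expect_true(mc$thickness_corrected)

  # identity correction
  expect_equal(thickness_correct(m, 300e-6, 300e-6)$Fc, m$Fc)

  # double correction is guarded; the inverse restores the original
  expect_error(thickness_correct(mc, 300e-6, 317e-6), "already")
  back <- thickness_correct(mc, 317e-6, 300e-6, allow_recorrect = TRUE)
  expect_equal(back$Fc, m$Fc, tolerance = 1e-15)
  expect_equal(back$Ff, m$Ff, tolerance = 1e-15)

  expect_error(thickness_correct(m, 0, 317e-6), "positive")
  m$Fc <- 0
  expect_error(spacing_fraction(m), "positive")
})

test_that("spacing fractions of a plant-profile batch stay in band", {
  cfg <- noiseless_config(seed = 5, zero_wear = TRUE,
                          spacing_fraction_range = c(0.09, 0.14))
  st <- run_study(cfg)
  frac <- st$per_trial$Fs_N / st$per_trial$Fc_N
  expect_true(all(frac > 0.085 & frac < 0.145))
})

test_that("plateau recovery bias at generator defaults stays below 1%", {
  cfg <- synthetic_study_config(seed = 9)
  set.seed(9)
  worker <- list(sample_id = "bias", edge_radius_m = 1000e-9)
  errs <- vapply(1:8, function(i) {
    sim <- generate_force_trace(worker, pdms_4to1(), sheet_spec(400e-6),
                                cfg, seed = 100 + i)
    m <- process_trial(sim$first, sim$second)
    m$Ff / sim$truth$Ff - 1
  }, 0)
  expect_lt(abs(mean(errs)), 0.01)
})
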