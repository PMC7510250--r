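test_that("unit conversions invert to machine precision", {
  x <- c(0.001, 1, 15, 100, 185)
  expect_equal(pa_to_mmhg(mmhg_to_pa(x)), x, tolerance = 1e-15)
  expect_equal(m3_to_ml(ml_to_m3(x)), x, tolerance = 1e-15)
})

test_that("continuity sizing reproduces the printed scale-model diameters", {
  # identity case
  expect_identical(continuity_diameter(0.5, 0.25, 0.25), 0.5)
  # d = d_ref * sqrt(v_ref / v): frozen from the closed form
  expect_equal(continuity_diameter(0.5, 0.25, 9.8), 0.0798596, tolerance = 1e-6)
  expect_equal(round(continuity_diameter(0.5, 0.25, 9.8), 2), 0.08)
  expect_equal(continuity_diameter(0.5, 0.25, 35), 0.0422577, tolerance = 1e-6)
  expect_equal(round(continuity_diameter(0.5, 0.25, 35), 2), 0.04)
  expect_error(continuity_diameter(-0.5, 0.25, 1),
               class = "venapump_invalid_parameter")
  expect_error(continuity_diameter(0.5, 0, 1),
               class = "venapump_invalid_parameter")
})

test_that("Poiseuille resistance matches the closed form and its scalings", {
  fl <- fluid_properties()
  # 8 eta l / (pi r^4) for a 30 cm, 0.5 cm tube = 6.845e7 Pa.s/m^3
  r <- poiseuille_resistance(30, 0.5, fl)
  expect_equal(r * 133.322 / 1e-6, 6.845e7, tolerance = 1e-3)
  expect_equal(r, 0.5134, tolerance = 1e-3)
  expect_equal(poiseuille_resistance(60, 0.5, fl), 2 * r, tolerance = 1e-12)
  expect_equal(poiseuille_resistance(30, 0.25, fl), 16 * r, tolerance = 1e-12)
  expect_error(poiseuille_resistance(30, 0), class = "venapump_invalid_parameter")
})

test_that("hydrostatic column pressure matches rho g h", {
  expect_identical(hydrostatic_delta(0), 0)
  expect_identical(hydrostatic_delta(130, gravity_m_s2 = 0), 0)
  expect_equal(hydrostatic_delta(130), 1060 * 9.81 * 1.3 / 133.322,
               tolerance = 1e-12)
  expect_equal(hydrostatic_delta(130), 101.4, tolerance = 1e-3)
})

test_that("porous calibration reproduces the capillary-bed drop", {
  p <- calibrate_porous_resistance(NULL, 95, 15, 0.049)
  expect_equal(p$resistance, (95 - 15) / 0.049, tolerance = 1e-12)
  expect_equal(p$resistance, 1633, tolerance = 1e-3)
  # reference flow from the venous row: area x velocity
  expect_equal(reference_tables()$q_ref_ml_s, pi * 0.25^2 * 0.25)
  expect_error(calibrate_porous_resistance(NULL, 15, 15, 0.049),
               class = "venapump_invalid_parameter")
  expect_error(
    calibrate_porous_resistance(NULL, 95, 15, 0.049, tube_loss_mmhg = 90),
    class = "venapump_calibration_infeasible")
})

test_that("the printed velocity/diameter set is continuity-consistent", {
  tab <- reference_tables()$orthostatic
  cc <- continuity_consistency(tab$diameter_cm, tab$velocity_cm_s)
  expect_lt(cc$max_rel_dev, 0.10)
})

test_that("segment and circuit invariants are enforced", {
  expect_error(vessel_segment("x", 10, 0.5, elevation_drop_cm = 11),
               class = "venapump_invalid_parameter")
  expect_error(inlet_law(10, 20), class = "venapump_invalid_parameter")
  circ <- canonical_circuit()
  expect_s3_class(circ, "circuit")
  tab <- segment_table(circ)
  expect_equal(sum(tab$length_cm), 260)
  expect_equal(nrow(tab), 5)
  # probe stations must lie within their segments
  bad <- circ$probes
  bad$offset_cm[1] <- 999
  expect_error(
    circuit(circ$fluid, unname(circ$segments), circ$porous, "artery",
            circ$inlet, probes = bad),
    class = "venapump_invalid_parameter")
})

test_that("clinostatic steady solve reproduces the resting pressure table", {
  r <- quiet_scenario("clinostatism")
  s <- r$run$series
  last <- s[s$time_s > max(s$time_s) - 1, ]
  p_ii <- mean(last$p_II_mmHg)
  p_iii <- mean(last$p_III_mmHg)
  expect_lt(abs(p_ii - 95) / 95, 0.10)
  expect_lt(abs(p_iii - 15) / 15, 0.10)
})
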