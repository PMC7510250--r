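test_that("cycle volumes integrate constant and zero-mean flows correctly", {
  t <- seq(0, 5, by = 1e-3)
  m <- cycle_volumes(t, rep(0.05, length(t)), 1, min_discard_cycles = 2)
  expect_equal(m$net_volume_ml, 0.05, tolerance = 1e-12)
  expect_equal(m$retrograde_volume_ml, 0)
  expect_equal(m$antegrade_volume_ml, 0.05, tolerance = 1e-12)

  q <- sin(2 * pi * t)
  m2 <- cycle_volumes(t, q, 1)
  expect_equal(m2$net_volume_ml, 0, tolerance = 1e-9)
  expect_equal(m2$antegrade_volume_ml, -m2$retrograde_volume_ml,
               tolerance = 1e-9)
  # net = antegrade + retrograde by construction
  expect_equal(m2$net_volume_ml,
               m2$antegrade_volume_ml + m2$retrograde_volume_ml,
               tolerance = 1e-12)
  expect_error(cycle_volumes(seq(0, 0.5, 1e-3), rep(1, 501), 1),
               class = "venapump_insufficient_data")
})

test_that("transient cycles are discarded before averaging", {
  t <- seq(0, 8, by = 1e-3)
  # settles geometrically toward a 0.2 mL/cycle plateau
  q <- 0.2 + 0.3 * exp(-t / 1.5) * (1 + 0.2 * sin(2 * pi * t))
  m <- cycle_volumes(t, q, 1, min_discard_cycles = 2, settle_tol = 0.01)
  expect_gte(m$cycles_discarded, 2)
  expect_equal(m$net_volume_ml, 0.2, tolerance = 0.05)
})

test_that("ejection fraction is the net volume over the cylinder volume", {
  # 0.2 mL over pi 0.25^2 30 = 5.9 mL -> 3.4%
  expect_equal(ejection_fraction(0.2, 0.25, 30),
               100 * 0.2 / (pi * 0.25^2 * 30), tolerance = 1e-12)
  expect_equal(ejection_fraction(0.2, 0.25, 30), 3.4, tolerance = 0.01)
  expect_equal(ejection_fraction(0), 0)
  expect_equal(ejection_fraction(pi * 0.25^2 * 30), 100)
})

test_that("scenario switches follow their definitions", {
  expect_false(scenario_definition("clinostatism")$gravity_on)
  expect_false(scenario_definition("clinostatism")$wall_motion_on)
  o <- scenario_definition("orthostatism")
  expect_true(o$gravity_on && !o$wall_motion_on)
  for (n in c("walking_healthy", "walking_severe", "walking_partial")) {
    w <- scenario_definition(n)
    expect_true(w$gravity_on && w$wall_motion_on)
    expect_equal(w$dt, "fast")
  }
  expect_equal(scenario_definition("walking_partial")$valve_grade, "partial")
})

test_that("scenario comparison reports gain, reductions and reflux", {
  res <- list(
    orthostatism = structure(list(net_volume_ml = 0.05,
                                  retrograde_volume_ml = 0),
                             class = "cycle_metrics"),
    walking_healthy = structure(list(net_volume_ml = 0.2,
                                     retrograde_volume_ml = -0.004),
                                class = "cycle_metrics"),
    walking_severe = structure(list(net_volume_ml = 0.14,
                                    retrograde_volume_ml = -0.04),
                               class = "cycle_metrics"))
  cmp <- compare_scenarios(res)
  expect_equal(cmp$pump_gain, 4)
  sev <- cmp$table[cmp$table$scenario == "walking_severe", ]
  expect_equal(sev$reduction_vs_healthy_pct, 30, tolerance = 1e-9)
  expect_equal(sev$reflux_augmentation_ml, -0.036, tolerance = 1e-12)
  expect_error(compare_scenarios(res["orthostatism"]),
               class = "venapump_comparison_error")
})
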