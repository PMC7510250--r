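# System-level invariants of the coupled circuit-valve model.

test_that("competent valves rectify a zero-mean oscillatory forcing", {
  # wall pumping alone (no pressure head, no gravity): the valve pair must
  # turn the zero-mean wall oscillation into non-negative heart-ward flow
  cfgl <- canonical_config("walking_healthy")
  cfgl$gravity_on <- FALSE
  cfgl$inlet$mean_mmhg <- 0
  cfgl$inlet$amplitude_mmhg <- 0
  r <- quiet_scenario(config = cfgl)
  expect_gte(r$knee$net_volume_ml, 0)
  expect_gt(r$knee$net_volume_ml, 0.1) # the pump actually pumps
})

test_that("net ejected volume is monotone non-increasing in the proximal gap", {
  nets <- vapply(c(0.016, 0.08, 0.2), function(g) {
    knee_net(walking_run_with_gaps(distal_gap = 0.016, proximal_gap = g,
                                   cycles = 6))
  }, 0)
  expect_true(all(diff(nets) <= 1e-9))
  expect_gt(nets[1] - nets[3], 0.01) # the effect is material, not noise
})

test_that("walking with wall motion disabled equals orthostatism exactly", {
  cfgl <- canonical_config("walking_healthy")
  cfgl$wall_motion$enabled <- FALSE
  r_walk0 <- quiet_scenario(config = cfgl)
  r_orth <- quiet_scenario("orthostatism")
  expect_equal(r_walk0$knee$net_volume_ml, r_orth$knee$net_volume_ml,
               tolerance = 0)
  expect_equal(r_walk0$ankle$net_volume_ml, r_orth$ankle$net_volume_ml,
               tolerance = 0)
})

test_that("severe incompetence refluxes in diastole, systole untouched", {
  h <- quiet_scenario("walking_healthy")
  s <- quiet_scenario("walking_severe")
  # retrograde volume at the knee grows by an order of magnitude
  expect_gt(abs(s$knee$retrograde_volume_ml),
            5 * abs(h$knee$retrograde_volume_ml))
  # systolic antegrade output is unchanged within 5%
  expect_equal(s$knee$antegrade_volume_ml, h$knee$antegrade_volume_ml,
               tolerance = 0.05)
  # and the dysfunction ordering holds
  p <- quiet_scenario("walking_partial")
  expect_gte(h$knee$net_volume_ml, p$knee$net_volume_ml - 1e-12)
  expect_gte(p$knee$net_volume_ml, s$knee$net_volume_ml)
  # distal-only incompetence is non-critical, proximal is critical
  red_partial <- 1 - p$knee$net_volume_ml / h$knee$net_volume_ml
  red_severe <- 1 - s$knee$net_volume_ml / h$knee$net_volume_ml
  expect_lt(red_partial, 0.10)
  expect_gt(red_severe, red_partial)
})

test_that("refining grid and time step leaves the walking net volume put", {
  base <- quiet_scenario("walking_healthy")
  cfgl <- canonical_config("walking_healthy")
  cfgl$solver$dx_cm <- 1.25
  cfgl$solver$dt_fast_s <- 1e-4
  fine <- quiet_scenario(config = cfgl)
  expect_equal(fine$knee$net_volume_ml, base$knee$net_volume_ml,
               tolerance = 0.02)
})

test_that("both schemes agree on the resting operating point", {
  cfg_semi <- solver_config(total_cycles = 6)
  cfg_expl <- solver_config(total_cycles = 6, scheme = "explicit",
                            dt_slow_s = 1e-4, dt_fast_s = 1e-4)
  circ <- canonical_circuit(gravity_on = TRUE)
  fs <- forcing_schedule(circ$inlet)
  valves <- canonical_valves(seal_coefficient = 135.7)
  q1 <- knee_net(run_simulation(circ, fs, valves, cfg_semi))
  q2 <- knee_net(run_simulation(circ, fs, valves, cfg_expl))
  expect_equal(q1, q2, tolerance = 1e-3)
})

test_that("all five canonical scenarios run to completion at the paper steps", {
  for (s in c("clinostatism", "orthostatism", "walking_healthy",
              "walking_severe", "walking_partial")) {
    r <- quiet_scenario(s)
    expect_true(all(is.finite(as.matrix(r$run$series[, -1]))),
                label = paste("finite series in", s))
  }
})
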