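test_that("discretization covers the arc and carries the right inertance", {
  circ <- tube_circuit(length_cm = 30)
  d <- build_discretization(circ, target_dx_cm = 1)
  plain <- d$edge_type == 0L
  expect_equal(sum(plain), 30)
  expect_equal(sum(d$edge_len[plain]) * 100, 30, tolerance = 1e-12)
  # rho l / A of a 1 cm, 0.5 cm-diameter edge = 5.40e5 Pa.s^2/m^3
  inert <- 1060 * d$edge_len[1] / d$edge_area[1]
  expect_equal(inert, 5.40e5, tolerance = 1e-3)
  expect_error(build_discretization(circ, target_dx_cm = 50),
               class = "venapump_discretization_error")
})

test_that("canonical discretization resolves probes, valves and porous edge", {
  circ <- canonical_circuit()
  d <- build_discretization(circ, valves = canonical_valves(),
                            wall_motion = wall_motion_law())
  expect_equal(sum(d$edge_type == 1L), 1) # one porous edge
  expect_equal(sum(d$edge_type == 2L), 1) # distal valve
  expect_equal(sum(d$edge_type == 3L), 1) # proximal valve
  expect_equal(d$arc_length_cm, 260, tolerance = 1e-9)
  expect_named(d$probe_nodes, c("I", "II", "III", "IV", "V", "VI"))
  # probe I is the inlet node, VI the outlet node
  expect_equal(unname(d$probe_nodes[c("I", "VI")]), c(0L, d$n_nodes - 1L))
  # elevations: inlet and outlet at 130 cm, feet at 0
  expect_equal(d$node_z[1], 1.30, tolerance = 1e-12)
  expect_equal(min(d$node_z), 0)
  # swept-source coefficients integrate to the full surface integral
  expect_equal(sum(d$node_G), 4 * pi * 0.25e-2 * 5e-5 * 0.30, tolerance = 1e-12)
})

test_that("Courant number matches v dt / dx", {
  expect_equal(cfl_number(0.2, 2e-4, 5e-4), 0.08)
  expect_equal(cfl_number(0, 123, 1), 0)
  expect_equal(cfl_number(1, 1e-3, 1e-3), 1)
  cfg <- solver_config()
  circ <- tube_circuit()
  expect_error(
    run_simulation(circ, forcing_schedule(circ$inlet), cfg = cfg, dt_s = 0.5),
    class = "venapump_stability_error")
})

test_that("steady flow in a rigid tube matches the Poiseuille closed form", {
  circ <- tube_circuit(length_cm = 30, diameter_cm = 0.5, inlet_mean = 10)
  fs <- forcing_schedule(circ$inlet)
  for (scheme in c("semi-implicit", "explicit")) {
    cfg <- solver_config(total_cycles = 10, scheme = scheme, dx_cm = 1)
    run <- run_simulation(circ, fs, cfg = cfg)
    # independent oracle: Q = dp / (8 eta l / (pi r^4) + porous)
    r_si <- 8 * 0.0035 * 0.30 / (pi * 0.0025^4) + 1e-6 * 133.322 / 1e-6
    q_oracle <- (10 * 133.322 / r_si) / 1e-6 # mL/s
    expect_equal(steady_flow(run), q_oracle, tolerance = 1e-3)
  }
})

test_that("a sealed column is exactly hydrostatic", {
  # U-bend with equal legs and zero boundary pressures: no flow develops
  # and interior pressure equals the blood-column head
  circ <- tube_circuit(length_cm = 130, inlet_mean = 0, gravity = 9.81,
                       u_bend = TRUE)
  cfg <- solver_config(total_cycles = 10, dx_cm = 1,
                       initial_velocity_cm_s = 0, initial_pressure_mmhg = 0)
  run <- run_simulation(circ, forcing_schedule(circ$inlet), cfg = cfg)
  s <- tail(run$series, 1)
  expect_lt(abs(s$Q_outlet_mL_s), 1e-6)
  p_feet_oracle <- 1060 * 9.81 * 0.65 / 133.322
  expect_equal(s$p_feet_mmHg, p_feet_oracle, tolerance = 1e-3)
  expect_equal(s$p_top_in_mmHg, 0, tolerance = 1e-9)
})

test_that("zero forcing with zero initial state is a fixed point", {
  circ <- tube_circuit(inlet_mean = 0, gravity = 0)
  cfg <- solver_config(total_cycles = 100, dx_cm = 1,
                       initial_velocity_cm_s = 0, initial_pressure_mmhg = 0)
  run <- run_simulation(circ, forcing_schedule(circ$inlet), cfg = cfg)
  expect_equal(nrow(run$series), 100 / 0.01 + 1) # 1e4 steps
  expect_true(all(abs(run$series$Q_outlet_mL_s) == 0))
  expect_true(all(abs(run$final$q_ml_s) == 0))
  expect_true(all(abs(run$final$p_mmhg) < 1e-12))
})

test_that("mass is conserved node-by-node through the walking cycle", {
  r <- quiet_scenario("walking_healthy")
  s <- r$run$series
  # outlet outflow exceeds inlet inflow by exactly the instantaneous
  # swept-volume rate of the contracting calf
  defect <- s$Q_outlet_mL_s - s$Q_inlet_mL_s - s$swept_rate_mL_s
  # volume defect per step below 1e-9 mL
  expect_lt(max(abs(defect)) * r$run$dt_s, 1e-9)
  # per-cycle volumes agree between the ankle and knee cross-sections
  expect_equal(r$ankle$net_volume_ml, r$knee$net_volume_ml, tolerance = 0.01)
})

test_that("the calf areas stay positive and pressures finite", {
  r <- quiet_scenario("walking_severe")
  s <- r$run$series
  expect_true(all(is.finite(as.matrix(s[, -1]))))
  expect_true(all(s$A_distal_cm2 > 0 & s$A_proximal_cm2 > 0))
  # valve areas bounded by leak area and full area
  a_full <- pi * 0.25^2
  expect_true(all(s$A_proximal_cm2 <= a_full + 1e-12))
  expect_true(all(s$A_proximal_cm2 >= 0.01 * a_full - 1e-12))
})

test_that("residual venous pulsation at the cardiac period survives in rest", {
  r <- quiet_scenario("clinostatism")
  s <- r$run$series
  last <- s[s$time_s > max(s$time_s) - 1, ]
  amp <- diff(range(last$Q_ankle_mL_s))
  expect_gt(amp, 0.001)               # visible modulation ...
  expect_lt(amp, mean(last$Q_ankle_mL_s)) # ... but attenuated below the mean
})

test_that("stepwise advancement matches a single longer run", {
  circ <- tube_circuit(inlet_mean = 10)
  fs <- forcing_schedule(circ$inlet)
  cfg <- solver_config(dx_cm = 1)
  one <- step_simulation(circ, fs, cfg = cfg, dt_s = 1e-2, n_steps = 50)
  a <- step_simulation(circ, fs, cfg = cfg, dt_s = 1e-2, n_steps = 25)
  b <- step_simulation(circ, fs, cfg = cfg, dt_s = 1e-2, n_steps = 25,
                       state = a$final)
  expect_equal(b$final$q_ml_s, one$final$q_ml_s, tolerance = 1e-12)
  expect_equal(b$final$p_mmhg, one$final$p_mmhg, tolerance = 1e-10)
})

test_that("numerical failure is reported as an error, not NaNs", {
  circ <- tube_circuit()
  # an absurd explicit step on a stiff edge diverges; the solver must say so
  cfg <- solver_config(total_cycles = 6, scheme = "explicit", dx_cm = 1,
                       dt_slow_s = 1e-2)
  expect_error({
    bad <- tube_circuit(diameter_cm = 0.02, inlet_mean = 100)
    run_simulation(bad, forcing_schedule(bad$inlet), cfg = cfg)
  }, regexp = "non-finite|collapsed|failure")
})
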