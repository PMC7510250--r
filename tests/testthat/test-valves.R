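test_that("effective orifice area interpolates between leak and full", {
  v <- ball_valve_spec()
  a_full <- pi * 0.25^2
  expect_equal(effective_orifice_area(v$travel_max, v), a_full)
  # competent valve seated: ~1% residual area
  expect_equal(effective_orifice_area(0, v), 0.01 * a_full)
  # incompetent (0.2 cm gap): leak fraction scales with the gap, 12.5%
  vi <- ball_valve_spec(min_gap_cm = 0.2)
  expect_equal(leak_fraction(vi), 0.125)
  expect_equal(effective_orifice_area(0, vi), 0.125 * a_full)
  # a huge gap caps at the full area
  vb <- ball_valve_spec(min_gap_cm = 3, travel_max_cm = 4)
  expect_equal(leak_fraction(vb), 1)
  # bounds over the whole travel
  xs <- seq(0, v$travel_max, length.out = 21)
  as <- vapply(xs, effective_orifice_area, 0, spec = v)
  expect_true(all(diff(as) >= 0))
  expect_true(all(as >= 0.01 * a_full - 1e-15 & as <= a_full + 1e-15))
  expect_error(effective_orifice_area(v$travel_max + 0.1, v),
               class = "venapump_state_violation")
})

test_that("ball force balance reproduces the hand-evaluated pressure force", {
  v <- ball_valve_spec()
  st <- ball_valve_state(v, position_cm = v$travel_max)
  # neutrally buoyant, no flow, equal pressures -> zero force
  expect_equal(ball_force_balance(st, v, 50, 50, 0), 0)
  # 1 mmHg forward on a 0.52 cm ball: 133.322 Pa * pi (0.0026 m)^2
  f <- ball_force_balance(st, v, 51, 50, 0)
  expect_equal(f, 133.322 * pi * 0.0026^2, tolerance = 1e-12)
  expect_equal(f, 2.83e-3, tolerance = 1e-2)
  # reverse difference with zero flow pushes toward the seat
  expect_lt(ball_force_balance(st, v, 50, 51, 0), 0)
  # a dense ball sinks toward the seat when nothing else acts
  vd <- ball_valve_spec(ball_density_kg_m3 = 2000)
  expect_lt(ball_force_balance(ball_valve_state(vd), vd, 50, 50, 0), 0)
})

test_that("ball relaxation saturates at the stops and is inert at zero force", {
  v <- ball_valve_spec()
  st <- ball_valve_state(v, position_cm = 0)
  for (i in 1:2000) st <- advance_ball(st, 1e-3, 1e-3, v)
  expect_equal(st$position, v$travel_max)
  expect_equal(st$effective_area, v$fully_open_area)
  for (i in 1:2000) st <- advance_ball(st, -1e-3, 1e-3, v)
  expect_equal(st$position, 0)
  st0 <- ball_valve_state(v, position_cm = 0.2)
  expect_equal(advance_ball(st0, 0, 1e-3, v)$position, 0.2)
})

test_that("quasi-static limit matches the sign-of-pressure oracle", {
  # as relaxation_time -> 0 the ball tracks sign(dp) instantaneously
  v <- ball_valve_spec(relaxation_time_s = 1e-9)
  st <- ball_valve_state(v, position_cm = 0)
  ts <- seq(0, 2, by = 1e-2)
  dp <- 5 * sin(2 * pi * ts) # prescribed pressure waveform, mmHg
  for (k in seq_along(ts)) {
    f <- ball_force_balance(st, v, 50 + dp[k], 50, 0, gravity_m_s2 = 0)
    st <- advance_ball(st, f, 1e-2, v)
    oracle <- if (dp[k] > 0) v$travel_max else if (dp[k] < 0) 0 else st$position
    expect_equal(st$position, oracle, tolerance = 1e-9)
  }
})

test_that("incompetence grades set the documented gap pairs", {
  base <- canonical_valves()
  h <- configure_incompetence(base, "healthy")
  expect_equal(c(h$distal$min_gap, h$proximal$min_gap), c(0.016, 0.016))
  s <- configure_incompetence(base, "severe")
  expect_equal(c(s$distal$min_gap, s$proximal$min_gap), c(0.2, 0.2))
  p <- configure_incompetence(base, "partial")
  expect_equal(c(p$distal$min_gap, p$proximal$min_gap), c(0.2, 0.016))
  expect_error(configure_incompetence(base, "bogus"))
})

test_that("valve spec invariants are enforced", {
  expect_error(ball_valve_spec(ball_diameter_cm = 0.5, seat_diameter_cm = 0.5),
               class = "venapump_invalid_parameter")
  expect_error(ball_valve_spec(min_gap_cm = 0.6, travel_max_cm = 0.5),
               class = "venapump_invalid_parameter")
  expect_error(ball_valve_spec(residual_area_fraction = 1.2),
               class = "venapump_invalid_parameter")
})
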