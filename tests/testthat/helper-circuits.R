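# Small fixture builders shared across test files. Everything is built in
# code; no stored data.

# straight rigid tube (one descending + one ascending leg when u_bend, else
# a single horizontal segment) with a negligible porous element, no valves
tube_circuit <- function(length_cm = 30, diameter_cm = 0.5,
                         inlet_mean = 10, gravity = 0, u_bend = FALSE,
                         porous_r = 1e-6) {
  if (u_bend) {
    segs <- list(
      vessel_segment("down", length_cm / 2, diameter_cm,
                     elevation_drop_cm = length_cm / 2),
      vessel_segment("up", length_cm / 2, diameter_cm,
                     elevation_drop_cm = -length_cm / 2))
    porous_after <- "down"
    probes <- data.frame(name = c("top_in", "feet", "top_out"),
                         segment = c("down", "down", "up"),
                         offset_cm = c(0, length_cm / 2, length_cm / 2),
                         stringsAsFactors = FALSE)
  } else {
    segs <- list(vessel_segment("tube", length_cm, diameter_cm))
    porous_after <- "tube"
    probes <- NULL
  }
  circuit(fluid_properties(), segs, porous_interface(porous_r),
          porous_after_segment = porous_after,
          inlet = inlet_law(inlet_mean, 0, 1),
          gravity_m_s2 = gravity, probes = probes)
}

steady_flow <- function(run) {
  s <- run$series
  tail(s$Q_outlet_mL_s, 1)
}

quiet_scenario <- function(...) {
  suppressWarnings(run_scenario(...))
}

walking_run_with_gaps <- function(distal_gap, proximal_gap, cycles = 8) {
  circ <- canonical_circuit(gravity_on = TRUE)
  wm <- wall_motion_law()
  forcing <- forcing_schedule(circ$inlet, wm)
  valves <- canonical_valves(seal_coefficient = 135.7)
  valves$distal$min_gap <- distal_gap
  valves$proximal$min_gap <- proximal_gap
  cfg <- solver_config(total_cycles = cycles)
  run_simulation(circ, forcing, valves, cfg)
}

knee_net <- function(run) {
  cycle_volumes(run$series$time_s, run$series$Q_knee_mL_s,
                run$period_s)$net_volume_ml
}
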