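#' Solver settings
#'
#' Dual time-step operation: `dt_slow_s` (default 1e-2 s) advances the slow
#' dynamics of the resting scenarios, `dt_fast_s` (default 2e-4 s) resolves
#' the calf-pump fluid dynamics. The default scheme is semi-implicit
#' (friction and the linearized orifice loss at the new time level, forcing
#' explicit), unconditionally stable at both steps; the `explicit` mode
#' (losses at the old time level on inertial edges) exists for cross-checks
#' at small steps.
#'
#' @param dt_slow_s time step for resting scenarios (s).
#' @param dt_fast_s time step for pump-active scenarios (s);
#'   `0 < dt_fast_s <= dt_slow_s`.
#' @param total_cycles number of forcing cycles to simulate (>= 2).
#' @param scheme `"semi-implicit"` or `"explicit"`.
#' @param dx_cm grid spacing target (cm).
#' @param cadence_s output sampling interval (s); defaults to the time step.
#' @param min_discard_cycles minimum transient cycles discarded before
#'   metrics.
#' @param settle_tol relative change of per-cycle net volume between
#'   consecutive cycles below which the transient is considered over.
#' @param compliance_ml_mmhg optional regularization compliance per node
#'   (mL/mmHg), 0 by default.
#' @param ball_dynamics `"relaxation"` (default) or `"inertial"`.
#' @param initial_velocity_cm_s initial uniform flow expressed as a mean
#'   velocity in the first (aortic) segment.
#' @param initial_pressure_mmhg initial uniform pressure.
#' @param seed integer seed recorded with run metadata (the solver itself
#'   is deterministic; the seed governs randomized perturbation studies).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(dt_slow_s = 1e-2, dt_fast_s = 2e-4,
                          total_cycles = 8, scheme = c("semi-implicit", "explicit"),
                          dx_cm = 2.5, cadence_s = NULL,
                          min_discard_cycles = 2, settle_tol = 0.01,
                          compliance_ml_mmhg = 0,
                          ball_dynamics = c("relaxation", "inertial"),
                          initial_velocity_cm_s = 35,
                          initial_pressure_mmhg = 100, seed = 1L) {
  scheme <- match.arg(scheme)
  ball_dynamics <- match.arg(ball_dynamics)
  check_positive(dt_slow_s = dt_slow_s, dt_fast_s = dt_fast_s, dx_cm = dx_cm)
  if (dt_fast_s > dt_slow_s) stop_invalid("dt_fast_s must be <= dt_slow_s")
  if (total_cycles < 2) stop_invalid("total_cycles must be >= 2")
  if (compliance_ml_mmhg < 0) stop_invalid("compliance must be >= 0")
  structure(list(dt_slow = dt_slow_s, dt_fast = dt_fast_s,
                 total_cycles = as.integer(total_cycles), scheme = scheme,
                 dx_cm = dx_cm, cadence = cadence_s,
                 min_discard = as.integer(min_discard_cycles),
                 settle_tol = settle_tol,
                 compliance = compliance_ml_mmhg,
                 ball_dynamics = ball_dynamics,
                 v0 = initial_velocity_cm_s, p0 = initial_pressure_mmhg,
                 seed = as.integer(seed)),
            class = "solver_config")
}

valves_to_core <- function(valves, disc, cfg, fluid) {
  if (!length(disc$valve_edges)) {
    return(list(edge = integer(0), a_full = numeric(0), a_leak = numeric(0),
                travel = numeric(0), kappa = numeric(0), tau = numeric(0),
                ball_d = numeric(0), ball_rho = numeric(0), x0 = numeric(0),
                dynamics = 0L))
  }
  vl <- list(valves$distal, valves$proximal)
  list(
    edge = as.integer(disc$valve_edges - 1L),
    a_full = vapply(vl, function(v) v$fully_open_area / 1e4, 0),
    a_leak = vapply(vl, function(v) leak_fraction(v) * v$fully_open_area / 1e4, 0),
    travel = vapply(vl, function(v) v$travel_max / 100, 0),
    # kappa in mmHg.s.cm^2/mL -> Pa.s/m (1e-4 m^2 / 1e-6 m^3 per mmHg.s)
    kappa = vapply(vl, function(v) v$seal_coefficient * .MMHG_PA * 1e-4 / 1e-6, 0),
    tau = vapply(vl, function(v) v$relaxation_time, 0),
    ball_d = vapply(vl, function(v) v$ball_diameter / 100, 0),
    ball_rho = vapply(vl, function(v) v$ball_density, 0),
    x0 = vapply(vl, function(v) v$travel_max / 100, 0),
    dynamics = if (cfg$ball_dynamics == "inertial") 1L else 0L
  )
}

#' Run the coupled circuit-valve simulation
#'
#' Advances the discretized network for `total_cycles` forcing periods with
#' the appropriate time step (`dt_fast` when wall motion is active,
#' `dt_slow` otherwise), returning probe pressure/flow time series, valve
#' trajectories and mass bookkeeping. The run refuses time steps violating
#' the Courant contract `v_ref * dt / dx <= 1` at the reference transport
#' velocity 0.35 m/s (the aortic initial velocity).
#'
#' @param circ a [circuit()].
#' @param forcing a [forcing_schedule()].
#' @param valves list (`distal`, `proximal`) of [ball_valve_spec()], or
#'   `NULL` for a valveless circuit.
#' @param cfg a [solver_config()].
#' @param dt_s optional explicit time step override (s).
#' @param n_cycles optional override of `cfg$total_cycles`.
#' @return an object of class `venapump_run` with elements `series`
#'   (data.frame of probe pressures in mmHg, flows in mL/s, valve positions
#'   in cm), `disc`, `cfg`, `dt_s`, `period_s` and final state.
#' @export
run_simulation <- function(circ, forcing, valves = NULL, cfg = solver_config(),
                           dt_s = NULL, n_cycles = NULL) {
  stopifnot(inherits(circ, "circuit"), inherits(forcing, "forcing_schedule"),
            inherits(cfg, "solver_config"))
  wm_active <- !is.null(forcing$wall_motion) && forcing$wall_motion$a > 0
  if (is.null(dt_s)) dt_s <- if (wm_active) cfg$dt_fast else cfg$dt_slow
  if (is.null(n_cycles)) n_cycles <- cfg$total_cycles

  disc <- build_discretization(circ, valves = valves,
                               wall_motion = forcing$wall_motion,
                               target_dx_cm = cfg$dx_cm)
  cfl <- cfl_number(0.35, dt_s, cfg$dx_cm / 100)
  if (cfl > 1) {
    stop(errorCondition(
      sprintf("time step violates the CFL contract (C = %.3g > 1)", cfl),
      class = c("venapump_stability_error", "venapump_error")))
  }

  period <- forcing$inlet$period
  steps_per_cycle <- as.integer(round(period / dt_s))
  if (abs(steps_per_cycle * dt_s - period) > 1e-9 * period) {
    stop_invalid("the forcing period must be an integer number of time steps")
  }
  n_steps <- steps_per_cycle * n_cycles
  cadence <- if (is.null(cfg$cadence)) dt_s else cfg$cadence
  sample_every <- max(1L, as.integer(round(cadence / dt_s)))
  if (steps_per_cycle %% sample_every != 0L) sample_every <- 1L

  core_forcing <- list(
    p_in_mean = mmhg_to_pa(forcing$inlet$mean),
    p_in_amp = mmhg_to_pa(forcing$inlet$amplitude),
    T_in = period,
    p_out = mmhg_to_pa(circ$outlet_pressure_mmhg),
    wm_on = disc$wall$on, wm_a = disc$wall$a, wm_T0 = disc$wall$T0,
    wm_rrest = disc$wall$rrest)
  core_valves <- valves_to_core(valves, disc, cfg, circ$fluid)
  q0 <- cfg$v0 / 100 * disc$edge_area[1]
  control <- list(
    dt = dt_s, n_steps = n_steps, sample_every = sample_every,
    scheme = if (cfg$scheme == "explicit") 1L else 0L,
    t0 = 0, init_q = q0, init_p = mmhg_to_pa(cfg$p0),
    gravity = circ$gravity, rho = circ$fluid$density,
    eta = circ$fluid$viscosity,
    compliance = cfg$compliance * .ML_M3 / .MMHG_PA,
    probe_nodes = as.integer(disc$probe_nodes),
    probe_edges = as.integer(c(disc$ankle_edge, disc$knee_edge) - 1L))

  res <- vp_core_run(disc, core_forcing, core_valves, control)

  series <- data.frame(time_s = res$time)
  if (length(disc$probe_nodes)) {
    pm <- pa_to_mmhg(res$p_probe)
    colnames(pm) <- paste0("p_", names(disc$probe_nodes), "_mmHg")
    series <- cbind(series, as.data.frame(pm))
  }
  series$Q_ankle_mL_s <- m3_to_ml(res$q_probe[, 1])
  series$Q_knee_mL_s <- m3_to_ml(res$q_probe[, 2])
  series$Q_inlet_mL_s <- m3_to_ml(res$q_inlet)
  series$Q_outlet_mL_s <- m3_to_ml(res$q_outlet)
  series$swept_rate_mL_s <- m3_to_ml(res$swept_rate)
  if (ncol(res$x_valve) == 2) {
    series$x_distal_cm <- res$x_valve[, 1] * 100
    series$x_proximal_cm <- res$x_valve[, 2] * 100
    series$A_distal_cm2 <- res$a_valve[, 1] * 1e4
    series$A_proximal_cm2 <- res$a_valve[, 2] * 1e4
  }

  structure(list(series = series, disc = disc, cfg = cfg, dt_s = dt_s,
                 period_s = period, n_cycles = n_cycles,
                 cfl = cfl, scheme = cfg$scheme,
                 final = list(q_ml_s = m3_to_ml(res$final_q),
                              p_mmhg = pa_to_mmhg(res$final_p),
                              x_cm = res$final_x * 100)),
            class = "venapump_run")
}

#' @export
print.venapump_run <- function(x, ...) {
  cat(sprintf("venapump run: %d cycles of %g s at dt = %g s (%s, C = %.3g)\n",
              x$n_cycles, x$period_s, x$dt_s, x$scheme, x$cfl))
  cat(sprintf("  %d samples, probes: %s\n", nrow(x$series),
              paste(setdiff(names(x$series), "time_s"), collapse = ", ")))
  invisible(x)
}

#' Advance a run by one step (or a few)
#'
#' Thin wrapper over the core stepper for state-level inspection: starts
#' from a previous run's final state and advances `n_steps` steps of
#' `dt_s`, returning the same run structure. Used for fixed-point and
#' drift checks.
#'
#' @inheritParams run_simulation
#' @param state optional list with `q_ml_s`, `p_mmhg`, `x_cm` and `t0_s`.
#' @param n_steps number of steps.
#' @return a `venapump_run`.
#' @export
step_simulation <- function(circ, forcing, valves = NULL,
                            cfg = solver_config(), dt_s = cfg$dt_fast,
                            n_steps = 1L, state = NULL) {
  disc <- build_discretization(circ, valves = valves,
                               wall_motion = forcing$wall_motion,
                               target_dx_cm = cfg$dx_cm)
  core_forcing <- list(
    p_in_mean = mmhg_to_pa(forcing$inlet$mean),
    p_in_amp = mmhg_to_pa(forcing$inlet$amplitude),
    T_in = forcing$inlet$period,
    p_out = mmhg_to_pa(circ$outlet_pressure_mmhg),
    wm_on = disc$wall$on, wm_a = disc$wall$a, wm_T0 = disc$wall$T0,
    wm_rrest = disc$wall$rrest)
  core_valves <- valves_to_core(valves, disc, cfg, circ$fluid)
  if (!is.null(state) && !is.null(state$x_cm) && length(core_valves$edge)) {
    core_valves$x0 <- state$x_cm / 100
  }
  init_q <- if (is.null(state)) cfg$v0 / 100 * disc$edge_area[1] else ml_to_m3(state$q_ml_s)
  init_p <- if (is.null(state)) mmhg_to_pa(cfg$p0) else mmhg_to_pa(state$p_mmhg)
  control <- list(
    dt = dt_s, n_steps = as.integer(n_steps), sample_every = 1L,
    scheme = if (cfg$scheme == "explicit") 1L else 0L,
    t0 = if (is.null(state$t0_s)) 0 else state$t0_s,
    init_q = init_q, init_p = init_p,
    gravity = circ$gravity, rho = circ$fluid$density,
    eta = circ$fluid$viscosity,
    compliance = cfg$compliance * .ML_M3 / .MMHG_PA,
    probe_nodes = as.integer(disc$probe_nodes),
    probe_edges = as.integer(c(disc$ankle_edge, disc$knee_edge) - 1L))
  res <- vp_core_run(disc, core_forcing, core_valves, control)
  list(final = list(q_ml_s = m3_to_ml(res$final_q),
                    p_mmhg = pa_to_mmhg(res$final_p),
                    x_cm = res$final_x * 100,
                    t0_s = (if (is.null(state$t0_s)) 0 else state$t0_s) +
                      n_steps * dt_s),
       disc = disc)
}
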