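#' Ball check-valve specification
#'
#' The closing member is a rigid sphere slightly larger than the vessel
#' lumen; it travels between a cage stop (fully open) and a seat stop. The
#' seat stop cannot reach the seat itself: a residual gap `min_gap_cm`
#' remains (0.016 cm for a competent valve, about 0.2 cm when the travel is
#' restricted to model incompetence). When seated at the healthy gap the
#' valve still leaks through about 1% of its fully open area; the leak area
#' scales linearly with the gap (capped at the full area).
#'
#' In addition to the area mapping, the seated valve carries a seat sealing
#' resistance `kappa * (1/A_eff - 1/A_full)` (mmHg.s/mL with areas in cm^2):
#' a linear viscous leak law, inversely proportional to the leak area, that
#' vanishes when fully open. `kappa` is the single calibrated constant of
#' the valve model (see the methods vignette); with the default the
#' competent valve is effectively sealed while the incompetent valve
#' refluxes enough to reproduce the dysfunction scenarios.
#'
#' @param ball_diameter_cm ball diameter (cm), larger than the seat lumen.
#' @param seat_diameter_cm vessel lumen diameter at the seat (cm).
#' @param travel_max_cm seat-stop-to-cage travel (cm).
#' @param min_gap_cm closest approach of the ball to the seat (cm).
#' @param residual_area_fraction leak fraction of the fully open area when
#'   seated at the healthy reference gap `gap_ref_cm`.
#' @param gap_ref_cm reference gap anchoring `residual_area_fraction`.
#' @param fully_open_area_cm2 effective orifice when fully open; defaults
#'   to the seat lumen area.
#' @param seal_coefficient kappa, the seat sealing coefficient
#'   (mmHg.s.cm^2/mL).
#' @param ball_density_kg_m3 ball density; neutrally buoyant by default.
#' @param relaxation_time_s first-order response time of the ball.
#' @param orientation `"distal"` (ankle side) or `"proximal"` (knee side).
#' @return an object of class `ball_valve_spec`.
#' @export
ball_valve_spec <- function(ball_diameter_cm = 0.52, seat_diameter_cm = 0.5,
                            travel_max_cm = 0.5, min_gap_cm = 0.016,
                            residual_area_fraction = 0.01,
                            gap_ref_cm = 0.016,
                            fully_open_area_cm2 = pi * (seat_diameter_cm / 2)^2,
                            seal_coefficient = 130,
                            ball_density_kg_m3 = 1060,
                            relaxation_time_s = 5e-3,
                            orientation = c("distal", "proximal")) {
  orientation <- match.arg(orientation)
  check_positive(ball_diameter_cm = ball_diameter_cm,
                 seat_diameter_cm = seat_diameter_cm,
                 travel_max_cm = travel_max_cm, min_gap_cm = min_gap_cm,
                 gap_ref_cm = gap_ref_cm,
                 fully_open_area_cm2 = fully_open_area_cm2,
                 seal_coefficient = seal_coefficient,
                 ball_density_kg_m3 = ball_density_kg_m3,
                 relaxation_time_s = relaxation_time_s)
  if (ball_diameter_cm <= seat_diameter_cm) {
    stop_invalid("ball must be larger than the seat lumen")
  }
  if (min_gap_cm >= travel_max_cm) {
    stop_invalid("'min_gap_cm' must be smaller than 'travel_max_cm'")
  }
  if (residual_area_fraction <= 0 || residual_area_fraction >= 1) {
    stop_invalid("'residual_area_fraction' must lie in (0, 1)")
  }
  structure(list(ball_diameter = ball_diameter_cm,
                 seat_diameter = seat_diameter_cm,
                 travel_max = travel_max_cm, min_gap = min_gap_cm,
                 residual_area_fraction = residual_area_fraction,
                 gap_ref = gap_ref_cm,
                 fully_open_area = fully_open_area_cm2,
                 seal_coefficient = seal_coefficient,
                 ball_density = ball_density_kg_m3,
                 relaxation_time = relaxation_time_s,
                 orientation = orientation),
            class = "ball_valve_spec")
}

#' Residual leak fraction of a valve
#'
#' Leak fraction of the fully open area when the ball sits at the seat
#' stop: `residual_area_fraction * min_gap / gap_ref`, capped at 1.
#'
#' @param spec a [ball_valve_spec()].
#' @return dimensionless leak fraction in (0, 1].
#' @export
leak_fraction <- function(spec) {
  min(1, spec$residual_area_fraction * spec$min_gap / spec$gap_ref)
}

#' Ball-valve state
#'
#' @param spec a [ball_valve_spec()].
#' @param position_cm ball position along the travel (0 = seated at the
#'   seat stop, `travel_max` = fully open).
#' @param velocity_cm_s ball velocity.
#' @return an object of class `ball_valve_state` with the effective orifice
#'   area filled in.
#' @export
ball_valve_state <- function(spec, position_cm = spec$travel_max,
                             velocity_cm_s = 0) {
  structure(list(position = position_cm, velocity = velocity_cm_s,
                 effective_area = effective_orifice_area(position_cm, spec),
                 orientation = spec$orientation),
            class = "ball_valve_state")
}

#' Effective orifice area at a ball position
#'
#' Linear interpolation between the residual leak area at the seat stop and
#' the fully open area at the cage: A_leak + (A_full - A_leak) * x / x_max.
#'
#' @param position_cm ball position within `[0, travel_max]`.
#' @param spec a [ball_valve_spec()].
#' @return effective orifice area in cm^2.
#' @export
effective_orifice_area <- function(position_cm, spec) {
  if (any(position_cm < -1e-12) || any(position_cm > spec$travel_max + 1e-12)) {
    stop(errorCondition("ball position outside travel bounds",
                        class = c("venapump_state_violation", "venapump_error")))
  }
  a_leak <- leak_fraction(spec) * spec$fully_open_area
  pmin(spec$fully_open_area,
       a_leak + (spec$fully_open_area - a_leak) *
         pmax(0, pmin(1, position_cm / spec$travel_max)))
}

#' Net axial force on the valve ball
#'
#' Pressure force (pressure difference across the ball times the ball
#' cross-section, signed toward opening for a forward difference), Stokes
#' viscous drag 3 pi eta d (u_fluid - u_ball), and the submerged weight
#' projected on the travel axis (zero for the neutrally buoyant default).
#' Both valves open against gravity (travel axis pointing up).
#'
#' @param state a [ball_valve_state()].
#' @param spec a [ball_valve_spec()].
#' @param upstream_p_mmhg,downstream_p_mmhg pressures on the upstream
#'   (ankle side) and downstream (heart side) faces, gravity-corrected to
#'   the ball position (i.e. piezometric).
#' @param local_flow_ml_s flow through the valve (mL/s, heart-ward
#'   positive).
#' @param fluid a [fluid_properties()].
#' @param gravity_m_s2 gravitational acceleration.
#' @return force in N, positive toward opening.
#' @export
ball_force_balance <- function(state, spec, upstream_p_mmhg, downstream_p_mmhg,
                               local_flow_ml_s = 0,
                               fluid = fluid_properties(),
                               gravity_m_s2 = 9.81) {
  d <- spec$ball_diameter / 100
  a_ball <- pi * (d / 2)^2
  f_p <- mmhg_to_pa(upstream_p_mmhg - downstream_p_mmhg) * a_ball
  a_eff <- state$effective_area / 1e4
  u_fluid <- ml_to_m3(local_flow_ml_s) / a_eff
  u_ball <- state$velocity / 100
  f_drag <- 3 * pi * fluid$viscosity * d * (u_fluid - u_ball)
  v_ball <- pi / 6 * d^3
  f_weight <- -(spec$ball_density - fluid$density) * v_ball * gravity_m_s2
  f_p + f_drag + f_weight
}

#' Advance the ball one time step
#'
#' Default dynamics: first-order relaxation toward the stop selected by the
#' force sign (cage for opening force, seat stop for closing force) with
#' time constant `relaxation_time`, integrated with the exact exponential
#' update (unconditionally stable). Position is clamped at the stops and
#' the velocity zeroed on contact.
#'
#' @param state a [ball_valve_state()].
#' @param force_n net force (N, positive toward opening).
#' @param dt_s time step (s), > 0.
#' @param spec a [ball_valve_spec()].
#' @return the updated [ball_valve_state()].
#' @export
advance_ball <- function(state, force_n, dt_s, spec) {
  check_positive(dt_s = dt_s)
  x_inf <- if (force_n > 0) spec$travel_max else if (force_n < 0) 0 else state$position
  x_new <- x_inf + (state$position - x_inf) * exp(-dt_s / spec$relaxation_time)
  v <- (x_new - state$position) / dt_s
  x_new <- min(max(x_new, 0), spec$travel_max)
  # snap onto a stop once the residual excursion is numerically irrelevant
  if (x_new < 1e-9) x_new <- 0
  if (spec$travel_max - x_new < 1e-9) x_new <- spec$travel_max
  if (x_new %in% c(0, spec$travel_max) && x_new == state$position) v <- 0
  ball_valve_state(spec, position_cm = x_new, velocity_cm_s = v)
}

#' Configure the valve pair for an incompetence grade
#'
#' `healthy` leaves both residual gaps at 0.016 cm; `severe` restricts both
#' balls to a ~0.2 cm gap; `partial` restricts only the distal (ankle-side)
#' valve, leaving the proximal valve competent.
#'
#' @param valves list of two [ball_valve_spec()]s named `distal`,
#'   `proximal`.
#' @param grade `"healthy"`, `"severe"` or `"partial"`.
#' @param healthy_gap_cm,incompetent_gap_cm the two gap anchors (cm).
#' @return the reconfigured list of specs.
#' @export
configure_incompetence <- function(valves = canonical_valves(),
                                   grade = c("healthy", "severe", "partial"),
                                   healthy_gap_cm = 0.016,
                                   incompetent_gap_cm = 0.2) {
  grade <- match.arg(grade)
  gaps <- switch(grade,
                 healthy = c(healthy_gap_cm, healthy_gap_cm),
                 severe = c(incompetent_gap_cm, incompetent_gap_cm),
                 partial = c(incompetent_gap_cm, healthy_gap_cm))
  set_gap <- function(spec, gap) {
    spec$min_gap <- gap
    spec
  }
  list(distal = set_gap(valves$distal, gaps[1]),
       proximal = set_gap(valves$proximal, gaps[2]))
}

#' Canonical valve pair
#'
#' Distal (ankle-side) and proximal (knee-side) ball valves with the
#' canonical geometry: 0.52 cm ball in a 0.50 cm seat, 0.5 cm travel,
#' competent 0.016 cm gaps.
#'
#' @param ... passed to [ball_valve_spec()] for both valves.
#' @return named list with elements `distal` and `proximal`.
#' @export
canonical_valves <- function(...) {
  list(distal = ball_valve_spec(orientation = "distal", ...),
       proximal = ball_valve_spec(orientation = "proximal", ...))
}
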