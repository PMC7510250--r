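#' Canonical run configuration for a scenario
#'
#' Assembles the full, unit-annotated configuration of one of the five
#' canonical scenarios: circuit geometry and calibrated friction, fluid
#' properties, boundary laws, wall-motion parameters, valve parameters and
#' solver settings. Calibrated values (segment resistances, porous
#' resistance, wall displacement amplitude, valve seal coefficient) are
#' flagged in the `calibration` section.
#'
#' @param scenario scenario name, see [scenario_definition()].
#' @return a list of class `venapump_config`.
#' @export
canonical_config <- function(scenario = c("clinostatism", "orthostatism",
                                          "walking_healthy", "walking_severe",
                                          "walking_partial")) {
  scenario <- match.arg(scenario)
  def <- scenario_definition(scenario)
  circ <- canonical_circuit(gravity_on = def$gravity_on)
  segs <- lapply(circ$segments, function(s) {
    list(name = s$name, length_cm = s$length_cm, diameter_cm = s$diameter_cm,
         elevation_drop_cm = s$elevation_drop_cm, wall = s$wall,
         resistance_mmhg_s_ml = s$resistance_mmhg_s_ml)
  })
  names(segs) <- NULL
  probes <- lapply(seq_len(nrow(circ$probes)), function(i) {
    as.list(circ$probes[i, , drop = FALSE])
  })
  cfgl <- list(
    scenario = scenario,
    fluid = list(density_kg_m3 = circ$fluid$density,
                 viscosity_pa_s = circ$fluid$viscosity),
    gravity_on = def$gravity_on,
    inlet = list(mean_mmhg = circ$inlet$mean,
                 amplitude_mmhg = circ$inlet$amplitude,
                 period_s = circ$inlet$period),
    outlet_pressure_mmhg = circ$outlet_pressure_mmhg,
    segments = segs,
    porous_interface = list(resistance_mmhg_s_ml = circ$porous$resistance),
    probes = probes,
    wall_motion = list(enabled = def$wall_motion_on,
                       displacement_amplitude_cm = 5e-3,
                       z0_cm = 10, length_cm = 30, period_s = 1),
    valves = list(grade = def$valve_grade,
                  ball_diameter_cm = 0.52, seat_diameter_cm = 0.5,
                  travel_max_cm = 0.5, healthy_gap_cm = 0.016,
                  incompetent_gap_cm = 0.2, residual_area_fraction = 0.01,
                  seal_coefficient_mmhg_s_cm2_ml = .KAPPA_CANONICAL,
                  ball_density_kg_m3 = 1060, relaxation_time_s = 5e-3),
    solver = list(dt_slow_s = 1e-2, dt_fast_s = 2e-4, total_cycles = 8L,
                  dx_cm = 2.5, scheme = "semi-implicit",
                  initial_velocity_cm_s = 35, initial_pressure_mmhg = 100),
    calibration = list(
      calibrated_fields = c("segments$resistance_mmhg_s_ml",
                            "porous_interface$resistance_mmhg_s_ml",
                            "wall_motion$displacement_amplitude_cm",
                            "valves$seal_coefficient_mmhg_s_cm2_ml"),
      reference_flow_ml_s = reference_tables()$q_ref_ml_s,
      note = paste("segment/porous resistances reproduce the resting",
                   "pressure table at the reference venous flow; the wall",
                   "displacement amplitude and the valve seal coefficient",
                   "are calibrated against the healthy and severe walking",
                   "per-cycle volumes"))
  )
  structure(cfgl, class = "venapump_config")
}

#' Build model objects from a configuration
#'
#' @param config a `venapump_config` (canonical or validated).
#' @return list with `circuit`, `forcing`, `valves`, `solver`.
#' @export
config_to_objects <- function(config) {
  stopifnot(inherits(config, "venapump_config"))
  fluid <- fluid_properties(config$fluid$density_kg_m3,
                            config$fluid$viscosity_pa_s)
  segs <- lapply(config$segments, function(s) {
    vessel_segment(s$name, s$length_cm, s$diameter_cm, s$elevation_drop_cm,
                   wall = s$wall,
                   resistance_mmhg_s_ml = s$resistance_mmhg_s_ml)
  })
  probes <- do.call(rbind, lapply(config$probes, function(p) {
    data.frame(name = p$name, segment = p$segment, offset_cm = p$offset_cm,
               stringsAsFactors = FALSE)
  }))
  # the porous interface sits at the deepest (feet-level) point of the loop:
  # after the segment where the cumulative elevation drop peaks
  drops <- vapply(config$segments, `[[`, 0, "elevation_drop_cm")
  porous_after <- config$segments[[which.max(cumsum(drops))]]$name
  circ <- circuit(fluid, segs,
                  porous_interface(config$porous_interface$resistance_mmhg_s_ml),
                  porous_after_segment = porous_after,
                  inlet = inlet_law(config$inlet$mean_mmhg,
                                    config$inlet$amplitude_mmhg,
                                    config$inlet$period_s),
                  outlet_pressure_mmhg = config$outlet_pressure_mmhg,
                  gravity_m_s2 = if (isTRUE(config$gravity_on)) 9.81 else 0,
                  probes = probes)
  wm <- NULL
  if (isTRUE(config$wall_motion$enabled)) {
    wm <- wall_motion_law(config$wall_motion$displacement_amplitude_cm,
                          config$wall_motion$z0_cm,
                          config$wall_motion$length_cm,
                          config$wall_motion$period_s)
  }
  forcing <- forcing_schedule(circ$inlet, wm)
  v <- config$valves
  base <- canonical_valves(ball_diameter_cm = v$ball_diameter_cm,
                           seat_diameter_cm = v$seat_diameter_cm,
                           travel_max_cm = v$travel_max_cm,
                           min_gap_cm = v$healthy_gap_cm,
                           residual_area_fraction = v$residual_area_fraction,
                           gap_ref_cm = v$healthy_gap_cm,
                           seal_coefficient = v$seal_coefficient_mmhg_s_cm2_ml,
                           ball_density_kg_m3 = v$ball_density_kg_m3,
                           relaxation_time_s = v$relaxation_time_s)
  valves <- configure_incompetence(base, v$grade,
                                   healthy_gap_cm = v$healthy_gap_cm,
                                   incompetent_gap_cm = v$incompetent_gap_cm)
  solver <- solver_config(dt_slow_s = config$solver$dt_slow_s,
                          dt_fast_s = config$solver$dt_fast_s,
                          total_cycles = config$solver$total_cycles,
                          scheme = config$solver$scheme,
                          dx_cm = config$solver$dx_cm,
                          initial_velocity_cm_s = config$solver$initial_velocity_cm_s,
                          initial_pressure_mmhg = config$solver$initial_pressure_mmhg)
  list(circuit = circ, forcing = forcing, valves = valves, solver = solver)
}

#' Write a configuration to YAML
#'
#' @param config a `venapump_config`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "venapump_config"))
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}

#' Generate the five canonical scenario configurations
#'
#' Writes `clinostatism.yaml`, `orthostatism.yaml`, `walking_healthy.yaml`,
#' `walking_severe.yaml` and `walking_partial.yaml` into `output_dir`.
#'
#' @param output_dir writable directory (created if missing).
#' @return character vector of the five file paths.
#' @export
generate_canonical_configs <- function(output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(errorCondition(paste0("cannot create directory: ", output_dir),
                                 class = c("venapump_io_error", "venapump_error")))
  }
  scns <- c("clinostatism", "orthostatism", "walking_healthy",
            "walking_severe", "walking_partial")
  vapply(scns, function(s) {
    p <- file.path(output_dir, paste0(s, ".yaml"))
    write_config(canonical_config(s), p)
    p
  }, "")
}

#' Validate a configuration file (or list)
#'
#' Checks the full schema and collects every violation rather than failing
#' at the first; returns the typed configuration when valid, otherwise an
#' object of class `venapump_config_violations` holding the messages.
#'
#' @param x path to a YAML configuration or an already-parsed list.
#' @return a `venapump_config` or a `venapump_config_violations` object.
#' @export
validate_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) {
      stop(errorCondition(paste0("configuration file not found: ", x),
                          class = c("venapump_io_error", "venapump_error")))
    }
    x <- tryCatch(yaml::read_yaml(x), error = function(e) {
      stop(errorCondition(paste0("configuration parse failure: ",
                                 conditionMessage(e)),
                          class = c("venapump_format_error", "venapump_error")))
    })
  }
  v <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  num_pos <- function(val, field) {
    need(is.numeric(val) && length(val) == 1 && is.finite(val) && val > 0,
         paste0("'", field, "' must be a positive number"))
  }
  need(is.list(x), "configuration must be a mapping")
  need(is.character(x$scenario) &&
         x$scenario %in% c("clinostatism", "orthostatism", "walking_healthy",
                           "walking_severe", "walking_partial"),
       "'scenario' must name one of the five canonical scenarios")
  num_pos(x$fluid$density_kg_m3, "fluid$density_kg_m3")
  num_pos(x$fluid$viscosity_pa_s, "fluid$viscosity_pa_s")
  need(is.logical(x$gravity_on), "'gravity_on' must be logical")
  num_pos(x$inlet$period_s, "inlet$period_s")
  need(is.numeric(x$inlet$mean_mmhg) && is.numeric(x$inlet$amplitude_mmhg) &&
         x$inlet$amplitude_mmhg >= 0 &&
         x$inlet$mean_mmhg - x$inlet$amplitude_mmhg >= 0,
       "inlet law requires amplitude >= 0 and mean - amplitude >= 0")
  need(identical(as.numeric(x$outlet_pressure_mmhg), 0),
       "'outlet_pressure_mmhg' must be 0 (vena cava reference)")
  need(is.list(x$segments) && length(x$segments) >= 2,
       "'segments' must list at least two segments")
  if (is.list(x$segments)) {
    for (s in x$segments) {
      lbl <- paste0("segments[", if (is.null(s$name)) "?" else s$name, "]")
      num_pos(s$length_cm, paste0(lbl, "$length_cm"))
      num_pos(s$diameter_cm, paste0(lbl, "$diameter_cm"))
      if (is.numeric(s$length_cm) && is.numeric(s$elevation_drop_cm)) {
        need(abs(s$elevation_drop_cm) <= s$length_cm + 1e-9,
             paste0(lbl, ": |elevation_drop_cm| cannot exceed length_cm"))
      }
      need(is.character(s$wall) && s$wall %in% c("rigid", "prescribed-motion"),
           paste0(lbl, "$wall must be 'rigid' or 'prescribed-motion'"))
      if (!is.null(s$resistance_mmhg_s_ml)) {
        num_pos(s$resistance_mmhg_s_ml, paste0(lbl, "$resistance_mmhg_s_ml"))
      }
    }
    n_calf <- sum(vapply(x$segments, function(s)
      identical(s$wall, "prescribed-motion"), TRUE))
    need(n_calf == 1, "exactly one prescribed-motion (calf) segment is required")
  }
  num_pos(x$porous_interface$resistance_mmhg_s_ml,
          "porous_interface$resistance_mmhg_s_ml")
  need(is.logical(x$wall_motion$enabled), "wall_motion$enabled must be logical")
  need(is.numeric(x$wall_motion$displacement_amplitude_cm) &&
         x$wall_motion$displacement_amplitude_cm >= 0,
       "wall_motion$displacement_amplitude_cm must be >= 0")
  num_pos(x$wall_motion$length_cm, "wall_motion$length_cm")
  num_pos(x$wall_motion$period_s, "wall_motion$period_s")
  vv <- x$valves
  need(is.character(vv$grade) && vv$grade %in% c("healthy", "severe", "partial"),
       "valves$grade must be healthy, severe or partial")
  num_pos(vv$ball_diameter_cm, "valves$ball_diameter_cm")
  num_pos(vv$seat_diameter_cm, "valves$seat_diameter_cm")
  if (is.numeric(vv$ball_diameter_cm) && is.numeric(vv$seat_diameter_cm)) {
    need(vv$ball_diameter_cm > vv$seat_diameter_cm,
         "valves: ball must be larger than the seat lumen")
  }
  num_pos(vv$travel_max_cm, "valves$travel_max_cm")
  num_pos(vv$healthy_gap_cm, "valves$healthy_gap_cm")
  num_pos(vv$incompetent_gap_cm, "valves$incompetent_gap_cm")
  need(is.numeric(vv$residual_area_fraction) &&
         vv$residual_area_fraction > 0 && vv$residual_area_fraction < 1,
       "valves$residual_area_fraction must lie in (0, 1)")
  num_pos(vv$seal_coefficient_mmhg_s_cm2_ml,
          "valves$seal_coefficient_mmhg_s_cm2_ml")
  num_pos(vv$relaxation_time_s, "valves$relaxation_time_s")
  sv <- x$solver
  num_pos(sv$dt_slow_s, "solver$dt_slow_s")
  num_pos(sv$dt_fast_s, "solver$dt_fast_s")
  if (is.numeric(sv$dt_slow_s) && is.numeric(sv$dt_fast_s)) {
    need(sv$dt_fast_s <= sv$dt_slow_s,
         "solver contract violated: dt_fast_s must be <= dt_slow_s")
  }
  need(is.numeric(sv$total_cycles) && sv$total_cycles >= 2,
       "solver$total_cycles must be >= 2")
  num_pos(sv$dx_cm, "solver$dx_cm")
  need(is.character(sv$scheme) && sv$scheme %in% c("semi-implicit", "explicit"),
       "solver$scheme must be 'semi-implicit' or 'explicit'")

  if (length(v)) {
    return(structure(v, class = "venapump_config_violations"))
  }
  structure(x, class = "venapump_config")
}

#' @export
print.venapump_config_violations <- function(x, ...) {
  cat("configuration violations:\n")
  for (m in x) cat("  -", m, "\n")
  invisible(x)
}

#' @export
print.venapump_config <- function(x, ...) {
  cat(sprintf("venapump configuration: scenario '%s' (%d segments, grade %s)\n",
              x$scenario, length(x$segments), x$valves$grade))
  invisible(x)
}
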