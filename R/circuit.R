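#' Blood properties
#'
#' Newtonian incompressible blood. Defaults are the standard values used for
#' large-vessel hemodynamics (density 1060 kg/m^3, dynamic viscosity
#' 0.0035 Pa.s); laminar flow is assumed throughout the circuit.
#'
#' @param density_kg_m3 fluid density in kg/m^3.
#' @param viscosity_pa_s dynamic viscosity in Pa.s.
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(density_kg_m3 = 1060, viscosity_pa_s = 0.0035) {
  check_positive(density_kg_m3 = density_kg_m3, viscosity_pa_s = viscosity_pa_s)
  structure(list(density = density_kg_m3, viscosity = viscosity_pa_s),
            class = "fluid_properties")
}

#' Vessel segment
#'
#' One straight segment of the systemic loop. `elevation_drop_cm` is the
#' signed vertical extent along the flow direction (positive when the flow
#' direction descends). Friction defaults to the Hagen-Poiseuille law for
#' the segment's lumen; `resistance_mmhg_s_ml` overrides it with a
#' calibrated lumped value (used for the scale-model arterial segments and
#' the foot-vein drainage resistance, whose printed diameters are
#' "functional to the velocity calculation" and do not carry the printed
#' pressure drops under fully developed Poiseuille friction).
#'
#' @param name segment identifier.
#' @param length_cm segment length (cm).
#' @param diameter_cm lumen diameter (cm).
#' @param elevation_drop_cm signed vertical extent along flow (cm, positive
#'   downward).
#' @param wall `"rigid"` or `"prescribed-motion"` (the calf pump segment).
#' @param resistance_mmhg_s_ml optional calibrated total resistance
#'   (mmHg.s/mL) replacing the Poiseuille value.
#' @return an object of class `vessel_segment`.
#' @export
vessel_segment <- function(name, length_cm, diameter_cm, elevation_drop_cm = 0,
                           wall = c("rigid", "prescribed-motion"),
                           resistance_mmhg_s_ml = NULL) {
  wall <- match.arg(wall)
  check_positive(length_cm = length_cm, diameter_cm = diameter_cm)
  if (!is.numeric(elevation_drop_cm) || length(elevation_drop_cm) != 1L ||
      !is.finite(elevation_drop_cm)) {
    stop_invalid("'elevation_drop_cm' must be a single finite number")
  }
  if (abs(elevation_drop_cm) > length_cm + 1e-9) {
    stop_invalid("|elevation_drop_cm| cannot exceed the segment length")
  }
  if (!is.null(resistance_mmhg_s_ml)) {
    check_positive(resistance_mmhg_s_ml = resistance_mmhg_s_ml)
  }
  structure(list(name = as.character(name), length_cm = length_cm,
                 diameter_cm = diameter_cm,
                 elevation_drop_cm = elevation_drop_cm, wall = wall,
                 resistance_mmhg_s_ml = resistance_mmhg_s_ml),
            class = "vessel_segment")
}

#' Porous capillary-bed interface
#'
#' Lumped linear (Darcy) resistance standing in for arterioles and the
#' capillary bed; it produces the artery-to-vein pressure drop at the feet.
#'
#' @param resistance_mmhg_s_ml pressure drop per unit flow (mmHg.s/mL).
#' @return an object of class `porous_interface`.
#' @export
porous_interface <- function(resistance_mmhg_s_ml) {
  check_positive(resistance_mmhg_s_ml = resistance_mmhg_s_ml)
  structure(list(resistance = resistance_mmhg_s_ml), class = "porous_interface")
}

#' Sinusoidal aortic inlet pressure law
#'
#' p(t) = mean + amplitude * sin(2 pi t / period), the pulsatile pressure
#' imposed at the aortic inlet (diastolic/systolic 80/120 mmHg with the
#' defaults).
#'
#' @param mean_mmhg mean pressure (mmHg).
#' @param amplitude_mmhg pulse amplitude (mmHg); `mean - amplitude` must be
#'   non-negative.
#' @param period_s cardiac period (s).
#' @return an object of class `inlet_law`.
#' @export
inlet_law <- function(mean_mmhg = 100, amplitude_mmhg = 20, period_s = 1) {
  check_positive(period_s = period_s)
  if (!is.numeric(mean_mmhg) || !is.numeric(amplitude_mmhg) ||
      amplitude_mmhg < 0 || mean_mmhg - amplitude_mmhg < 0) {
    stop_invalid("inlet law requires amplitude >= 0 and mean - amplitude >= 0")
  }
  structure(list(mean = mean_mmhg, amplitude = amplitude_mmhg,
                 period = period_s), class = "inlet_law")
}

#' Systemic circuit
#'
#' The ordered inlet-to-outlet chain of vessel segments with the porous
#' interface between the arterial and venous arms, boundary pressures,
#' gravity and named observation points (probes I-VI).
#'
#' @param fluid a [fluid_properties()] object.
#' @param segments ordered list of [vessel_segment()] (inlet to outlet).
#' @param porous a [porous_interface()]; inserted after
#'   `porous_after_segment`.
#' @param porous_after_segment name of the last arterial segment.
#' @param inlet an [inlet_law()].
#' @param outlet_pressure_mmhg outlet (vena cava) pressure, 0 by default.
#' @param gravity_m_s2 gravitational acceleration; 0 in clinostatism.
#' @param probes data.frame with columns `name`, `segment`, `offset_cm`
#'   (offset from segment start along flow).
#' @return an object of class `circuit`.
#' @export
circuit <- function(fluid, segments, porous, porous_after_segment, inlet,
                    outlet_pressure_mmhg = 0, gravity_m_s2 = 9.81,
                    probes = NULL) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(porous, "porous_interface"),
            inherits(inlet, "inlet_law"))
  if (!length(segments) || !all(vapply(segments, inherits, TRUE, "vessel_segment"))) {
    stop_invalid("'segments' must be a non-empty list of vessel_segment objects")
  }
  nms <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_invalid("segment names must be unique")
  if (!porous_after_segment %in% nms) {
    stop_invalid("'porous_after_segment' must name a segment")
  }
  if (gravity_m_s2 < 0) stop_invalid("'gravity_m_s2' must be >= 0")
  if (outlet_pressure_mmhg != 0) {
    # the model is built around a zero vena-cava reference
    stop_invalid("'outlet_pressure_mmhg' must be 0 (vena cava reference)")
  }
  names(segments) <- nms
  if (!is.null(probes)) {
    stopifnot(all(c("name", "segment", "offset_cm") %in% names(probes)))
    ok <- vapply(seq_len(nrow(probes)), function(i) {
      seg <- segments[[probes$segment[i]]]
      !is.null(seg) && probes$offset_cm[i] >= 0 &&
        probes$offset_cm[i] <= seg$length_cm
    }, TRUE)
    if (!all(ok)) stop_invalid("probe stations must lie within segment extents")
  }
  structure(list(fluid = fluid, segments = segments, porous = porous,
                 porous_after_segment = porous_after_segment, inlet = inlet,
                 outlet_pressure_mmhg = outlet_pressure_mmhg,
                 gravity = gravity_m_s2, probes = probes),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat("Systemic circuit:", length(x$segments), "segments, porous interface after '",
      x$porous_after_segment, "'\n", sep = "")
  cat(sprintf("  inlet %g +/- %g mmHg (T = %g s), outlet %g mmHg, g = %g m/s^2\n",
              x$inlet$mean, x$inlet$amplitude, x$inlet$period,
              x$outlet_pressure_mmhg, x$gravity))
  print(segment_table(x))
  invisible(x)
}

#' Segment table
#'
#' Geometry and friction of each segment as a data frame (exportable as CSV
#' for inspection).
#'
#' @param circ a [circuit()].
#' @return data.frame with one row per segment.
#' @export
segment_table <- function(circ) {
  segs <- circ$segments
  data.frame(
    name = vapply(segs, `[[`, "", "name"),
    length_cm = vapply(segs, `[[`, 0, "length_cm"),
    diameter_cm = vapply(segs, `[[`, 0, "diameter_cm"),
    elevation_drop_cm = vapply(segs, `[[`, 0, "elevation_drop_cm"),
    wall = vapply(segs, `[[`, "", "wall"),
    resistance_mmhg_s_ml = vapply(segs, function(s) {
      if (is.null(s$resistance_mmhg_s_ml)) {
        poiseuille_resistance(s$length_cm, s$diameter_cm, circ$fluid)
      } else s$resistance_mmhg_s_ml
    }, 0),
    row.names = NULL
  )
}

#' Diameter from the continuity equation
#'
#' Sizes a vessel so that `A * v` is conserved against a reference section:
#' returns the diameter d with (pi d^2 / 4) * target_velocity equal to the
#' reference volumetric flow.
#'
#' @param ref_diameter_cm reference diameter (cm).
#' @param ref_velocity_cm_s reference mean velocity (cm/s).
#' @param target_velocity_cm_s desired mean velocity in the sized vessel.
#' @return diameter in cm.
#' @examples
#' continuity_diameter(0.5, 0.25, 9.8)  # ~0.08, the arterial segment
#' continuity_diameter(0.5, 0.25, 35)   # ~0.04, the aorta
#' @export
continuity_diameter <- function(ref_diameter_cm, ref_velocity_cm_s,
                                target_velocity_cm_s) {
  check_positive(ref_diameter_cm = ref_diameter_cm,
                 ref_velocity_cm_s = ref_velocity_cm_s,
                 target_velocity_cm_s = target_velocity_cm_s)
  ref_diameter_cm * sqrt(ref_velocity_cm_s / target_velocity_cm_s)
}

#' Hagen-Poiseuille resistance of a segment
#'
#' 8 eta l / (pi r^4) for fully developed laminar flow, returned in the
#' clinical unit mmHg.s/mL.
#'
#' @param length_cm segment length (cm).
#' @param diameter_cm lumen diameter (cm).
#' @param fluid a [fluid_properties()].
#' @return resistance in mmHg.s/mL.
#' @export
poiseuille_resistance <- function(length_cm, diameter_cm,
                                  fluid = fluid_properties()) {
  check_positive(length_cm = length_cm, diameter_cm = diameter_cm)
  r <- diameter_cm / 2 / 100
  l <- length_cm / 100
  res_from_si(8 * fluid$viscosity * l / (pi * r^4))
}

#' Hydrostatic pressure difference of a blood column
#'
#' rho g h in mmHg; zero for any height when gravity is off (clinostatism).
#'
#' @param height_cm column height (cm).
#' @param fluid a [fluid_properties()].
#' @param gravity_m_s2 gravitational acceleration (m/s^2), >= 0.
#' @return pressure difference in mmHg.
#' @export
hydrostatic_delta <- function(height_cm, fluid = fluid_properties(),
                              gravity_m_s2 = 9.81) {
  if (gravity_m_s2 < 0) stop_invalid("'gravity_m_s2' must be >= 0")
  pa_to_mmhg(fluid$density * gravity_m_s2 * height_cm / 100)
}

#' Calibrate the porous-interface resistance
#'
#' Chooses the Darcy resistance so that, at the reference flow, the pressure
#' falls from the arterial to the venous target across the interface after
#' subtracting the viscous losses of the tube segments lying between the two
#' observation stations. With the canonical layout the porous interface sits
#' directly between the feet-level arterial and venous probes, so no tube
#' losses intervene and the calibration reduces to
#' (p_art - p_ven) / reference_flow.
#'
#' @param circ a [circuit()] (used for tube losses between the stations;
#'   may be `NULL` for the no-tube-loss case).
#' @param target_arterial_p_mmhg arterial-side pressure target (mmHg).
#' @param target_venous_p_mmhg venous-side pressure target (mmHg).
#' @param reference_flow_ml_s flow at which the targets hold (mL/s).
#' @param tube_loss_mmhg viscous losses attributable to tube segments
#'   between the two stations at the reference flow (mmHg).
#' @return a [porous_interface()].
#' @export
calibrate_porous_resistance <- function(circ = NULL,
                                        target_arterial_p_mmhg,
                                        target_venous_p_mmhg,
                                        reference_flow_ml_s,
                                        tube_loss_mmhg = 0) {
  check_positive(reference_flow_ml_s = reference_flow_ml_s)
  if (target_arterial_p_mmhg <= target_venous_p_mmhg) {
    stop_invalid("arterial target must exceed venous target")
  }
  r <- (target_arterial_p_mmhg - target_venous_p_mmhg - tube_loss_mmhg) /
    reference_flow_ml_s
  if (r <= 0) {
    stop(errorCondition(
      "calibration infeasible: tube losses exceed the target pressure drop",
      class = c("venapump_calibration_infeasible", "venapump_error")))
  }
  porous_interface(r)
}

#' Continuity self-consistency of a velocity table
#'
#' Checks that A*v computed from printed diameters and velocities agrees
#' across vessel types (relative spread about the mean volumetric flow).
#'
#' @param diameters_cm vessel diameters (cm).
#' @param velocities_cm_s matching mean velocities (cm/s).
#' @return list with per-vessel flows (mL/s) and the maximum relative
#'   deviation from their mean.
#' @export
continuity_consistency <- function(diameters_cm, velocities_cm_s) {
  stopifnot(length(diameters_cm) == length(velocities_cm_s))
  q <- pi * (diameters_cm / 2)^2 * velocities_cm_s
  list(flows_ml_s = q, max_rel_dev = max(abs(q - mean(q)) / mean(q)))
}
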