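#' Reference physiological tables of the idealized circuit
#'
#' Resting (clinostatic) velocity/pressure targets per vessel type and the
#' orthostatic per-station velocity set used to size the scale-model
#' diameters by continuity. These are the calibration surface of the
#' canonical circuit.
#'
#' @return a list with `clinostatic` and `orthostatic` data frames and the
#'   reference venous flow `q_ref_ml_s` (lumen area x venous velocity).
#' @export
reference_tables <- function() {
  clin <- data.frame(
    vessel = c("aorta", "arteries", "veins"),
    velocity_cm_s = c(45, 25, 2.65),            # mid-range of printed bands
    pressure_mmhg = c(100, 95, 15))
  orth <- data.frame(
    station = c("I", "II", "IV"),
    vessel = c("aorta", "artery", "vein"),
    diameter_cm = c(0.04, 0.08, 0.5),
    velocity_cm_s = c(35, 9.8, 0.25),
    pressure_mmhg = c(100, 185, 91))
  list(clinostatic = clin, orthostatic = orth,
       q_ref_ml_s = pi * 0.25^2 * 0.25)
}

#' Canonical lower-limb circuit
#'
#' Builds the 130 cm two-arm loop: aorta (top 10 cm of the arterial arm,
#' 0.04 cm lumen), arterial segment (remaining 120 cm, 0.08 cm), porous
#' capillary interface at the feet, foot vein (0-10 cm, 0.5 cm), the 30 cm
#' prescribed-motion calf trunk (10-40 cm) and the upper vein (40-130 cm).
#'
#' Friction is calibrated so the clinostatic steady solve reproduces the
#' resting pressure table at the reference venous flow: the arterial arm
#' carries the printed 5 mmHg aorta-to-artery drop (Poiseuille weighting
#' preserved between aorta and artery), the porous interface the 80 mmHg
#' artery-to-vein drop, and the foot vein the 15 mmHg venous drainage drop
#' (minus the Poiseuille losses of calf and upper vein, which keep their
#' analytic values so that calf friction responds to wall motion).
#'
#' @param gravity_on logical; `FALSE` reproduces clinostatism.
#' @param fluid a [fluid_properties()].
#' @param inlet an [inlet_law()].
#' @return a [circuit()].
#' @export
canonical_circuit <- function(gravity_on = TRUE, fluid = fluid_properties(),
                              inlet = inlet_law()) {
  tab <- reference_tables()
  q_ref <- tab$q_ref_ml_s
  p_aorta <- tab$clinostatic$pressure_mmhg[1]
  p_art <- tab$clinostatic$pressure_mmhg[2]
  p_vein <- tab$clinostatic$pressure_mmhg[3]

  r_aorta_pois <- poiseuille_resistance(10, 0.04, fluid)
  r_artery_pois <- poiseuille_resistance(120, 0.08, fluid)
  r_calf <- poiseuille_resistance(30, 0.5, fluid)
  r_upper <- poiseuille_resistance(90, 0.5, fluid)

  # arterial arm: total drop p_aorta -> p_art at q_ref, Poiseuille-weighted
  r_arm <- (p_aorta - p_art) / q_ref
  w <- r_aorta_pois / (r_aorta_pois + r_artery_pois)
  # venous drainage: p_vein -> 0 at q_ref across the whole venous arm
  r_foot <- p_vein / q_ref - r_calf - r_upper

  segs <- list(
    vessel_segment("aorta", 10, 0.04, elevation_drop_cm = 10,
                   resistance_mmhg_s_ml = r_arm * w),
    vessel_segment("artery", 120, 0.08, elevation_drop_cm = 120,
                   resistance_mmhg_s_ml = r_arm * (1 - w)),
    vessel_segment("foot_vein", 10, 0.5, elevation_drop_cm = -10,
                   resistance_mmhg_s_ml = r_foot),
    vessel_segment("calf", 30, 0.5, elevation_drop_cm = -30,
                   wall = "prescribed-motion"),
    vessel_segment("upper_vein", 90, 0.5, elevation_drop_cm = -90)
  )
  porous <- calibrate_porous_resistance(NULL, p_art, p_vein, q_ref)
  probes <- data.frame(
    name = c("I", "II", "III", "IV", "V", "VI"),
    segment = c("aorta", "artery", "foot_vein", "foot_vein",
                "upper_vein", "upper_vein"),
    offset_cm = c(0, 120, 0, 10, 0, 90),
    stringsAsFactors = FALSE)
  circuit(fluid, segs, porous, porous_after_segment = "artery", inlet = inlet,
          outlet_pressure_mmhg = 0,
          gravity_m_s2 = if (gravity_on) 9.81 else 0,
          probes = probes)
}
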