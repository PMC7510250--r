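#' Prescribed radial wall-motion law of the calf segment
#'
#' Muscle contraction is modelled as a radial wall velocity
#' v_r(z, t) = V_z(z) * V_t(t) on the calf trunk, with
#' V_z = a * pi * sin(pi (z - z0) / L) (half-sine axial shape, zero at the
#' segment ends) and V_t = (1/T0) * sin(2 pi t / T0). Positive v_r during
#' the first half-cycle means the wall moves inward (muscle systole);
#' during the second half-cycle the wall returns, so net displacement over
#' a full period is zero. `displacement_amplitude_cm` is the peak radial
#' displacement reached at the segment mid-point at the end of systole.
#'
#' @param displacement_amplitude_cm peak radial wall displacement a (cm).
#' @param z0_cm axial start of the deformable segment (cm above the feet).
#' @param length_cm deformable length L (cm).
#' @param period_s walking-cycle period T0 (s).
#' @return an object of class `wall_motion_law`.
#' @export
wall_motion_law <- function(displacement_amplitude_cm = 5e-3, z0_cm = 10,
                            length_cm = 30, period_s = 1) {
  check_positive(length_cm = length_cm, period_s = period_s)
  if (displacement_amplitude_cm < 0) {
    stop_invalid("'displacement_amplitude_cm' must be >= 0")
  }
  structure(list(a = displacement_amplitude_cm, z0 = z0_cm, L = length_cm,
                 T0 = period_s), class = "wall_motion_law")
}

#' Inlet pressure at time t
#'
#' Evaluates the sinusoidal aortic law mean + amplitude * sin(2 pi t / T).
#'
#' @param t_s time (s), >= 0.
#' @param law an [inlet_law()].
#' @return pressure in mmHg.
#' @export
inlet_pressure <- function(t_s, law = inlet_law()) {
  stopifnot(all(t_s >= 0))
  law$mean + law$amplitude * sin(2 * pi * t_s / law$period)
}

#' Radial wall velocity of the calf segment
#'
#' Zero outside `[z0, z0 + L]`; inside, the separable law described in
#' [wall_motion_law()]. Positive values point inward (lumen shrinking).
#'
#' @param z_cm axial position(s) above the feet (cm).
#' @param t_s time (s).
#' @param law a [wall_motion_law()].
#' @return radial velocity in cm/s.
#' @export
wall_radial_velocity <- function(z_cm, t_s, law) {
  stopifnot(inherits(law, "wall_motion_law"), all(t_s >= 0))
  vz <- ifelse(z_cm >= law$z0 & z_cm <= law$z0 + law$L,
               law$a * pi * sin(pi * (z_cm - law$z0) / law$L), 0)
  vt <- sin(2 * pi * t_s / law$T0) / law$T0
  vz * vt
}

#' Radial wall displacement of the calf segment
#'
#' Time integral of [wall_radial_velocity()]: the inward displacement
#' (a/2) sin(pi (z - z0)/L) (1 - cos(2 pi t / T0)), peaking at `a` at the
#' segment mid-point at the end of muscle systole.
#'
#' @inheritParams wall_radial_velocity
#' @return inward displacement in cm.
#' @export
wall_radial_displacement <- function(z_cm, t_s, law) {
  stopifnot(inherits(law, "wall_motion_law"))
  dz <- ifelse(z_cm >= law$z0 & z_cm <= law$z0 + law$L,
               sin(pi * (z_cm - law$z0) / law$L), 0)
  (law$a / 2) * dz * (1 - cos(2 * pi * t_s / law$T0))
}

#' Volume swept by the calf wall over one muscle systole
#'
#' Closed form of the surface integral of the wall velocity over the
#' contraction half-cycle in the thin-displacement approximation
#' (a << R): 4 * R * a * L.
#'
#' @param law a [wall_motion_law()].
#' @param radius_cm resting lumen radius of the calf trunk (cm).
#' @return swept volume in mL.
#' @export
swept_volume_half_cycle <- function(law, radius_cm = 0.25) {
  stopifnot(inherits(law, "wall_motion_law"))
  check_positive(radius_cm = radius_cm)
  4 * radius_cm * law$a * law$L
}

#' Forcing schedule
#'
#' Pairs the inlet pressure law with the (optional) calf wall motion. The
#' phase convention follows the walking cycle: t in [0, T0/2) is muscle
#' contraction (systole), [T0/2, T0) is relaxation (diastole), in phase
#' with the cardiac sinusoid.
#'
#' @param inlet an [inlet_law()].
#' @param wall_motion a [wall_motion_law()] or `NULL` (resting scenarios).
#' @return an object of class `forcing_schedule`.
#' @export
forcing_schedule <- function(inlet = inlet_law(), wall_motion = NULL) {
  stopifnot(inherits(inlet, "inlet_law"))
  if (!is.null(wall_motion)) {
    stopifnot(inherits(wall_motion, "wall_motion_law"))
    if (abs(wall_motion$T0 - inlet$period) > 1e-12) {
      # reporting cycle = walking cycle = cardiac cycle in all scenarios
      stop_invalid("wall-motion period must equal the inlet period")
    }
  }
  structure(list(inlet = inlet, wall_motion = wall_motion),
            class = "forcing_schedule")
}
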