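#' Per-cycle flow-volume metrics at a probe
#'
#' Integrates a probe flow series (trapezoidal rule) over each complete
#' forcing cycle: net volume (signed, heart-ward positive), antegrade
#' volume (positive part) and retrograde volume (negative part, reported
#' <= 0). Initial transient cycles are discarded: at least
#' `min_discard_cycles`, and further until the per-cycle net volume changes
#' by less than `settle_tol` (relative) between consecutive cycles; the
#' remaining cycles are averaged.
#'
#' @param time_s sample times (s), uniformly covering >= 1 full period.
#' @param flow_ml_s flow samples (mL/s, heart-ward positive).
#' @param period_s forcing period (s).
#' @param min_discard_cycles minimum number of discarded transient cycles
#'   (when enough cycles are available).
#' @param settle_tol relative settling tolerance for the transient rule.
#' @param probe label stored with the result.
#' @return an object of class `cycle_metrics` with fields `net_volume_ml`,
#'   `antegrade_volume_ml`, `retrograde_volume_ml`, `cycles_averaged`,
#'   `cycles_discarded` and the per-cycle table.
#' @export
cycle_volumes <- function(time_s, flow_ml_s, period_s,
                          min_discard_cycles = 2, settle_tol = 0.01,
                          probe = "probe") {
  check_positive(period_s = period_s)
  stopifnot(length(time_s) == length(flow_ml_s))
  span <- time_s[length(time_s)] - time_s[1]
  n_cyc <- floor(span / period_s + 1e-9)
  if (n_cyc < 1) {
    stop(errorCondition("flow series shorter than one full period",
                        class = c("venapump_insufficient_data", "venapump_error")))
  }
  trapz <- function(t, y) sum(diff(t) * (head(y, -1) + y[-1]) / 2)
  per <- lapply(seq_len(n_cyc), function(k) {
    lo <- time_s[1] + (k - 1) * period_s
    hi <- lo + period_s
    idx <- which(time_s >= lo - 1e-12 & time_s <= hi + 1e-12)
    t <- time_s[idx]; y <- flow_ml_s[idx]
    data.frame(cycle = k,
               net = trapz(t, y),
               antegrade = trapz(t, pmax(y, 0)),
               retrograde = trapz(t, pmin(y, 0)))
  })
  per <- do.call(rbind, per)

  discard <- min(min_discard_cycles, n_cyc - 1L)
  if (n_cyc > discard + 1L) {
    for (k in seq(discard + 1L, n_cyc - 1L)) {
      ref <- max(abs(per$net[k + 1L]), 1e-6)
      if (abs(per$net[k + 1L] - per$net[k]) < settle_tol * ref) break
      discard <- k
    }
  }
  keep <- per[(discard + 1L):n_cyc, , drop = FALSE]
  structure(list(net_volume_ml = mean(keep$net),
                 antegrade_volume_ml = mean(keep$antegrade),
                 retrograde_volume_ml = mean(keep$retrograde),
                 cycles_averaged = nrow(keep),
                 cycles_discarded = discard,
                 per_cycle = per, probe = probe),
            class = "cycle_metrics")
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat(sprintf(
    "cycle metrics (%s): net %.4g mL, antegrade %.4g mL, retrograde %.4g mL (%d cycles, %d discarded)\n",
    x$probe, x$net_volume_ml, x$antegrade_volume_ml, x$retrograde_volume_ml,
    x$cycles_averaged, x$cycles_discarded))
  invisible(x)
}

#' Calf ejection fraction
#'
#' Percentage of the resting calf trunk volume (a cylinder pi R^2 h)
#' ejected heart-ward per contraction cycle: 100 * net / (pi R^2 h).
#'
#' @param net_volume_ml net ejected volume per cycle (mL).
#' @param calf_radius_cm resting calf trunk radius (cm).
#' @param calf_length_cm calf trunk length (cm).
#' @return ejection fraction in percent.
#' @export
ejection_fraction <- function(net_volume_ml, calf_radius_cm = 0.25,
                              calf_length_cm = 30) {
  check_positive(calf_radius_cm = calf_radius_cm,
                 calf_length_cm = calf_length_cm)
  100 * net_volume_ml / (pi * calf_radius_cm^2 * calf_length_cm)
}

#' Canonical scenario definitions
#'
#' The five study conditions: lying at rest (clinostatism, gravity off),
#' standing at rest (orthostatism), and walking with healthy, severely
#' incompetent (both valves restricted) or partially incompetent (distal
#' valve only) venous valves.
#'
#' @param name scenario name.
#' @return list of switches (`gravity_on`, `wall_motion_on`,
#'   `valve_grade`, `dt`).
#' @export
scenario_definition <- function(name = c("clinostatism", "orthostatism",
                                         "walking_healthy", "walking_severe",
                                         "walking_partial")) {
  name <- match.arg(name)
  switch(name,
    clinostatism = list(name = name, gravity_on = FALSE, wall_motion_on = FALSE,
                        valve_grade = "healthy", dt = "slow"),
    orthostatism = list(name = name, gravity_on = TRUE, wall_motion_on = FALSE,
                        valve_grade = "healthy", dt = "slow"),
    walking_healthy = list(name = name, gravity_on = TRUE, wall_motion_on = TRUE,
                           valve_grade = "healthy", dt = "fast"),
    walking_severe = list(name = name, gravity_on = TRUE, wall_motion_on = TRUE,
                          valve_grade = "severe", dt = "fast"),
    walking_partial = list(name = name, gravity_on = TRUE, wall_motion_on = TRUE,
                           valve_grade = "partial", dt = "fast"))
}

#' Run one canonical scenario
#'
#' Builds the canonical circuit, forcing and valve pair for the requested
#' scenario (or uses a validated configuration object), runs the solver
#' and returns per-cycle metrics at the ankle and knee probes together
#' with the ejection fraction of the knee (reported, heart-ward) volume.
#'
#' @param name scenario name, see [scenario_definition()].
#' @param config optional validated configuration (see [validate_config()])
#'   overriding the canonical one.
#' @param cfg a [solver_config()].
#' @return an object of class `scenario_result`.
#' @export
run_scenario <- function(name = c("clinostatism", "orthostatism",
                                  "walking_healthy", "walking_severe",
                                  "walking_partial"),
                         config = NULL, cfg = solver_config()) {
  if (is.null(config)) {
    name <- match.arg(name)
    config <- canonical_config(name)
  } else {
    name <- config$scenario
  }
  objs <- config_to_objects(config)
  cfg$dx_cm <- config$solver$dx_cm
  cfg$dt_slow <- config$solver$dt_slow_s
  cfg$dt_fast <- config$solver$dt_fast_s
  run <- run_simulation(objs$circuit, objs$forcing, objs$valves, cfg)

  m_ankle <- cycle_volumes(run$series$time_s, run$series$Q_ankle_mL_s,
                           run$period_s, cfg$min_discard, cfg$settle_tol,
                           probe = "ankle")
  m_knee <- cycle_volumes(run$series$time_s, run$series$Q_knee_mL_s,
                          run$period_s, cfg$min_discard, cfg$settle_tol,
                          probe = "knee")
  calf <- objs$circuit$segments[["calf"]]
  ef <- if (!is.null(calf)) {
    ejection_fraction(m_knee$net_volume_ml, calf$diameter_cm / 2,
                      calf$length_cm)
  } else NA_real_
  structure(list(scenario = name, ankle = m_ankle, knee = m_knee,
                 ejection_fraction_pct = ef, run = run, config = config),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario '%s': net %.4g mL/cycle (knee), %.4g mL/cycle (ankle), EF %.3g%%\n",
              x$scenario, x$knee$net_volume_ml, x$ankle$net_volume_ml,
              x$ejection_fraction_pct))
  invisible(x)
}

#' Compare scenarios against the healthy-walking baseline
#'
#' Computes the calf-pump gain (walking vs orthostatism net volume), the
#' percent reduction of each dysfunction grade relative to healthy walking
#' and the reflux (retrograde volume) augmentation at the knee probe.
#'
#' @param results named list of [run_scenario()] results (or of
#'   `cycle_metrics` at the knee); must contain `walking_healthy`.
#' @return an object of class `scenario_comparison` (list with a `table`
#'   data.frame, `pump_gain` and per-grade reductions).
#' @export
compare_scenarios <- function(results) {
  if (!"walking_healthy" %in% names(results)) {
    stop(errorCondition("comparison requires the walking_healthy baseline",
                        class = c("venapump_comparison_error", "venapump_error")))
  }
  knee <- function(r) if (inherits(r, "scenario_result")) r$knee else r
  net <- vapply(results, function(r) knee(r)$net_volume_ml, 0)
  retro <- vapply(results, function(r) knee(r)$retrograde_volume_ml, 0)
  base <- net[["walking_healthy"]]
  tab <- data.frame(
    scenario = names(results),
    net_volume_ml = as.numeric(net),
    retrograde_volume_ml = as.numeric(retro),
    reduction_vs_healthy_pct = 100 * (base - as.numeric(net)) / base,
    reflux_augmentation_ml =
      as.numeric(retro) - retro[["walking_healthy"]],
    row.names = NULL)
  gain <- if ("orthostatism" %in% names(results)) {
    base / net[["orthostatism"]]
  } else NA_real_
  structure(list(table = tab, pump_gain = gain,
                 baseline_net_ml = base), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("scenario comparison (knee probe, heart-ward positive):\n")
  tab <- x$table
  tab$reduction_vs_healthy_pct <- round(tab$reduction_vs_healthy_pct)
  print(tab, row.names = FALSE)
  if (is.finite(x$pump_gain)) {
    cat(sprintf("calf-pump gain over orthostatism: %.2g x\n", x$pump_gain))
  }
  invisible(x)
}
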