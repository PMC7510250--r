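#' Courant number
#'
#' CFL diagnostic v * dt / dx for a velocity scale, time step and grid
#' spacing (SI units). Values above 1 violate the stability contract of
#' explicit transport and are refused by [run_simulation()].
#'
#' @param velocity_m_s velocity magnitude (m/s), >= 0.
#' @param dt_s time step (s).
#' @param dx_m grid spacing (m), > 0.
#' @return dimensionless Courant number.
#' @export
cfl_number <- function(velocity_m_s, dt_s, dx_m) {
  check_positive(dx_m = dx_m)
  velocity_m_s * dt_s / dx_m
}

#' Discretize a circuit into a 1-D edge chain
#'
#' Splits every segment into edges of roughly `target_dx_cm`, inserts the
#' porous edge after the last arterial segment and, when a valve pair is
#' supplied, zero-length valve edges at the boundaries of the
#' prescribed-motion calf segment (distal below, proximal above). Each edge
#' carries its inertance rho l / A and its share of the segment resistance;
#' calf edges additionally carry the axial half-sine weights used for the
#' wall-motion sources and area updates.
#'
#' @param circ a [circuit()].
#' @param valves optional list (`distal`, `proximal`) of
#'   [ball_valve_spec()].
#' @param wall_motion optional [wall_motion_law()] for the source/area
#'   precomputation.
#' @param target_dx_cm nominal grid spacing (cm); must not exceed the
#'   shortest segment.
#' @return an object of class `discretization`.
#' @export
build_discretization <- function(circ, valves = NULL, wall_motion = NULL,
                                 target_dx_cm = 2.5) {
  check_positive(target_dx_cm = target_dx_cm)
  seg_len <- vapply(circ$segments, `[[`, 0, "length_cm")
  if (target_dx_cm > min(seg_len) + 1e-9) {
    stop(errorCondition(
      "target_dx_cm exceeds the shortest segment length",
      class = c("venapump_discretization_error", "venapump_error")))
  }
  has_valves <- !is.null(valves)
  if (has_valves) {
    stopifnot(is.list(valves), all(c("distal", "proximal") %in% names(valves)))
    calf_idx <- which(vapply(circ$segments, `[[`, "", "wall") == "prescribed-motion")
    if (length(calf_idx) != 1L) {
      stop_invalid("valved circuits need exactly one prescribed-motion segment")
    }
  }

  e_len <- e_area <- e_R <- e_smid <- numeric(0)
  e_type <- e_calf <- integer(0)
  e_seg <- character(0)
  node_z <- 0 # relative; shifted so the lowest node is 0 afterwards
  v_edge <- integer(0)

  add_edge <- function(len_m, area_m2, R_si, type, calf = 0L, smid = 0,
                       dz_m = 0, seg = "") {
    e_len <<- c(e_len, len_m); e_area <<- c(e_area, area_m2)
    e_R <<- c(e_R, R_si); e_type <<- c(e_type, type)
    e_calf <<- c(e_calf, calf); e_smid <<- c(e_smid, smid)
    e_seg <<- c(e_seg, seg)
    node_z <<- c(node_z, node_z[length(node_z)] + dz_m)
  }

  for (k in seq_along(circ$segments)) {
    seg <- circ$segments[[k]]
    is_calf <- seg$wall == "prescribed-motion"
    if (has_valves && is_calf) {
      v_edge <- c(v_edge, length(e_len) + 1L) # distal valve edge (1-based)
      add_edge(0, pi * (seg$diameter_cm / 200)^2, 0, 2L, seg = ".distal_valve")
    }
    n_sub <- max(1L, as.integer(round(seg$length_cm / target_dx_cm)))
    l_e <- seg$length_cm / n_sub / 100
    a_e <- pi * (seg$diameter_cm / 200)^2
    R_tot <- if (is.null(seg$resistance_mmhg_s_ml)) {
      poiseuille_resistance(seg$length_cm, seg$diameter_cm, circ$fluid)
    } else seg$resistance_mmhg_s_ml
    R_e <- res_to_si(R_tot) / n_sub
    dz <- -seg$elevation_drop_cm / n_sub / 100 # positive drop descends
    z_here <- node_z[length(node_z)]
    for (j in seq_len(n_sub)) {
      smid <- 0
      if (is_calf && !is.null(wall_motion)) {
        # psi at edge midpoint in the wall law's height coordinate;
        # heights resolved after the z-shift, so store the fraction now
        smid <- (j - 0.5) / n_sub
      }
      add_edge(l_e, a_e, R_e, 0L, calf = as.integer(is_calf), smid = smid,
               dz_m = dz, seg = seg$name)
    }
    if (has_valves && is_calf) {
      v_edge <- c(v_edge, length(e_len) + 1L)
      add_edge(0, pi * (seg$diameter_cm / 200)^2, 0, 3L, seg = ".proximal_valve")
    }
    if (identical(seg$name, circ$porous_after_segment)) {
      add_edge(0, a_e, res_to_si(circ$porous$resistance), 1L, seg = ".porous")
    }
  }
  node_z <- node_z - min(node_z)

  # wall-motion axial weights and nodal source coefficients
  n_e_tot <- length(e_len)
  node_G <- numeric(n_e_tot + 1)
  wm <- list(on = 0L, a = 0, T0 = 1, rrest = 1)
  if (!is.null(wall_motion) && wall_motion$a > 0) {
    calf_edges <- which(e_calf == 1L)
    if (!length(calf_edges)) stop_invalid("wall motion given but no calf segment")
    calf_seg <- circ$segments[[which(vapply(circ$segments, `[[`, "", "wall") ==
                                       "prescribed-motion")]]
    rrest <- calf_seg$diameter_cm / 200
    a_m <- wall_motion$a / 100
    L_m <- wall_motion$L / 100
    z0_m <- wall_motion$z0 / 100
    for (e in calf_edges) {
      z_lo <- min(node_z[e], node_z[e + 1])
      z_hi <- max(node_z[e], node_z[e + 1])
      z_mid <- (z_lo + z_hi) / 2
      psi <- function(z) pi * pmin(pmax((z - z0_m) / L_m, 0), 1)
      e_smid[e] <- sin(psi(z_mid))
      # split the edge's swept-volume integral between its two end nodes
      gpart <- function(za, zb) {
        2 * pi * rrest * a_m * L_m * (cos(psi(za)) - cos(psi(zb)))
      }
      lo_node <- if (node_z[e] <= node_z[e + 1]) e else e + 1L
      hi_node <- if (node_z[e] <= node_z[e + 1]) e + 1L else e
      node_G[lo_node] <- node_G[lo_node] + gpart(z_lo, z_mid)
      node_G[hi_node] <- node_G[hi_node] + gpart(z_mid, z_hi)
    }
    wm <- list(on = 1L, a = a_m, T0 = wall_motion$T0, rrest = rrest)
  }

  # probe stations -> node indices (0-based for the core)
  probe_nodes <- integer(0)
  if (!is.null(circ$probes)) {
    probe_nodes <- vapply(seq_len(nrow(circ$probes)), function(i) {
      segnm <- circ$probes$segment[i]
      idx <- which(e_seg == segnm)
      seg <- circ$segments[[segnm]]
      frac <- circ$probes$offset_cm[i] / seg$length_cm
      # node at the start of the segment is idx[1]-1 (0-based: idx[1]-1)
      first_node <- idx[1] - 1L
      first_node + as.integer(round(frac * length(idx)))
    }, 0L)
    names(probe_nodes) <- circ$probes$name
  }

  ankle_edge <- if (has_valves) v_edge[1] else 1L
  knee_edge <- if (has_valves) v_edge[2] else length(e_len)

  structure(list(
    edge_len = e_len, edge_area = e_area, edge_R = e_R,
    edge_type = e_type, edge_calf = e_calf, edge_smid = e_smid,
    edge_segment = e_seg, node_z = node_z, node_G = node_G,
    valve_edges = v_edge, probe_nodes = probe_nodes,
    ankle_edge = ankle_edge, knee_edge = knee_edge,
    dx_cm = target_dx_cm, wall = wm,
    n_edges = n_e_tot, n_nodes = n_e_tot + 1L,
    arc_length_cm = sum(e_len) * 100
  ), class = "discretization")
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("1-D discretization: %d edges / %d nodes, dx = %g cm, arc %g cm\n",
              x$n_edges, x$n_nodes, x$dx_cm, x$arc_length_cm))
  if (length(x$valve_edges)) {
    cat("  valve edges:", paste(x$valve_edges, collapse = ", "), "\n")
  }
  invisible(x)
}
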