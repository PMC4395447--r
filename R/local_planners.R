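#' Social-force acceleration for one agent
#'
#' Driving force relaxing the current velocity toward the (corrected)
#' preferred velocity over `tau_H`, plus Helbing-style repulsive forces from
#' neighboring agents (exponential social repulsion, body force and sliding
#' friction on contact) and from obstacle segments.
#'
#' @param agent a [agent_state()].
#' @param v_pref preferred velocity (length-2, m/s) fed to the planner
#'   (typically the density-filtered preferred velocity).
#' @param neighbors data.frame or matrix with columns x, y, vx, vy, r of
#'   nearby agents (may be empty or NULL).
#' @param obstacles m x 4 matrix of wall segments `(x1, y1, x2, y2)`, or NULL.
#' @param params a [sf_params()].
#' @return Acceleration (length-2, m/s^2).
#' @export
sf_acceleration <- function(agent, v_pref, neighbors = NULL, obstacles = NULL,
                            params = sf_params()) {
  nb <- if (is.null(neighbors)) matrix(numeric(0), 0, 5) else
    as.matrix(as.data.frame(neighbors))
  segs <- if (is.null(obstacles)) matrix(numeric(0), 0, 4) else
    matrix(as.numeric(obstacles), ncol = 4)
  n <- nrow(nb) + 1
  pos <- rbind(agent$p, nb[, 1:2, drop = FALSE])
  vel <- rbind(agent$v_c, nb[, 3:4, drop = FALSE])
  vp <- rbind(v_pref, nb[, 3:4, drop = FALSE])  # neighbors inert: vpref = v
  rad <- c(agent$r, nb[, 5])
  mass <- rep(agent$mass, n)
  acc <- cpp_sf_accel_batch(pos, vel, vp, rad, mass, params$tau_H, params$A,
                            params$B, params$k, params$kappa,
                            params$interaction_range, segs, NaN, 0L, 0L)
  as.numeric(acc[1, ])
}

#' Advance a social-force world state by one step
#'
#' Semi-implicit Euler: velocities are updated from the accelerations, speeds
#' clamped at `max_speed`, then positions advanced with the new velocities.
#'
#' @param pos,vel n x 2 matrices of positions and current velocities.
#' @param v_pref n x 2 matrix of preferred velocities.
#' @param radius,mass per-agent radii (m) and masses (kg).
#' @param max_speed per-agent speed clamp (m/s), conventionally 1.3 x the
#'   preferred speed.
#' @param dt time step (s).
#' @param params a [sf_params()].
#' @param obstacles m x 4 matrix of wall segments or NULL.
#' @param period_x spatial period along x, or NULL.
#' @param seed,step integers seeding the deterministic tie-break direction
#'   used when two agent centers coincide exactly.
#' @return list with updated `pos` and `vel` (n x 2 matrices).
#' @export
sf_step <- function(pos, vel, v_pref, radius, mass, max_speed, dt,
                    params = sf_params(), obstacles = NULL, period_x = NULL,
                    seed = 0L, step = 0L) {
  stopifnot(dt > 0)
  segs <- if (is.null(obstacles)) matrix(numeric(0), 0, 4) else obstacles
  acc <- cpp_sf_accel_batch(pos, vel, v_pref, radius, mass, params$tau_H,
                            params$A, params$B, params$k, params$kappa,
                            params$interaction_range, segs,
                            if (is.null(period_x)) NaN else period_x,
                            as.integer(seed), as.integer(step))
  vnew <- vel + acc * dt
  spd <- sqrt(rowSums(vnew^2))
  over <- spd > max_speed & spd > 0
  if (any(over)) vnew[over, ] <- vnew[over, ] * (max_speed[over] / spd[over])
  list(pos = pos + vnew * dt, vel = vnew)
}

#' ORCA half-plane constraint induced by one neighbor
#'
#' The truncated velocity-obstacle construction shared half-half between the
#' two agents: the returned half-plane is the set of velocities for agent i
#' that are collision-free with respect to agent j for the horizon `tau_O`
#' (or that resolve an existing overlap within `dt`, when the disks already
#' intersect).
#'
#' @param agent_i,agent_j [agent_state()] objects (distinct positions).
#' @param tau_O planning horizon (s).
#' @param dt time step (s), used to resolve already-colliding disks.
#' @return list with `point` (a velocity on the boundary), `direction` (the
#'   boundary direction) and `normal` (unit outward-permitted normal): the
#'   permitted velocities v satisfy `(v - point) . normal >= 0`.
#' @export
orca_halfplane <- function(agent_i, agent_j, tau_O = 2.0, dt = 0.0625) {
  cpp_orca_pair_line(agent_i$p, agent_j$p, agent_i$v_c, agent_j$v_c,
                     agent_i$r, agent_j$r, tau_O, dt)
}

#' Closest permitted velocity to the preferred velocity
#'
#' Solves `argmin ||v - v_pref||` over the intersection of the half-planes
#' and the disk `||v|| <= max_speed` by incremental two-dimensional linear
#' programming. If the constraints are jointly infeasible, a fallback
#' linear program returns the velocity minimizing the maximum constraint
#' violation (keeping obstacle constraints hard).
#'
#' @param v_pref preferred velocity (length-2).
#' @param halfplanes list of half-planes as returned by [orca_halfplane()]
#'   (elements need `point` and `direction`), or an m x 4 matrix with columns
#'   `(px, py, dx, dy)`.
#' @param max_speed maximum speed (m/s).
#' @param n_obstacle number of leading constraints that are obstacle
#'   constraints (kept hard by the infeasibility fallback).
#' @return The new velocity (length-2).
#' @export
orca_new_velocity <- function(v_pref, halfplanes, max_speed, n_obstacle = 0L) {
  stopifnot(max_speed > 0)
  if (is.list(halfplanes) && !is.data.frame(halfplanes)) {
    m <- t(vapply(halfplanes, function(h) c(h$point, h$direction), numeric(4)))
  } else {
    m <- matrix(as.numeric(halfplanes), ncol = 4)
  }
  if (length(m) == 0) m <- matrix(numeric(0), 0, 4)
  cpp_orca_lp(as.numeric(v_pref), m, max_speed, as.integer(n_obstacle))
}

#' New velocities for all agents under ORCA
#'
#' Builds the ORCA half-plane constraints of the `max_neighbors` nearest
#' agents (plus linearized constraints for nearby obstacle segments) and
#' solves the velocity-space program for every agent.
#'
#' @inheritParams sf_step
#' @param tau_O agent-agent planning horizon (s).
#' @param neighbor_radius neighbor cutoff distance (m).
#' @param max_neighbors cap on agent constraints per agent.
#' @param tau_obst obstacle planning horizon (s); defaults to `tau_O`.
#' @param safety_margin extra clearance (m) added to the combined radius in
#'   the constraint construction only; absorbs the small violations of the
#'   infeasibility fallback so that physical disks stay disjoint in dense
#'   packs. The trajectory metrics always use the true radii.
#' @return n x 2 matrix of new velocities.
#' @export
orca_velocities <- function(pos, vel, v_pref, radius, max_speed, tau_O, dt,
                            obstacles = NULL, neighbor_radius = 5,
                            max_neighbors = 10L, tau_obst = tau_O,
                            period_x = NULL, safety_margin = 0.04) {
  segs <- if (is.null(obstacles)) matrix(numeric(0), 0, 4) else obstacles
  cpp_orca_batch(pos, vel, v_pref, radius, max_speed, tau_O, dt,
                 neighbor_radius, as.integer(max_neighbors), segs, tau_obst,
                 if (is.null(period_x)) NaN else period_x, safety_margin)
}
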