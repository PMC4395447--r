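#' Construct a validated agent state
#'
#' An agent is a two-dimensional disk with kinematic state (position, current
#' velocity, input preferred velocity) and the physiological parameters that
#' govern its density response: the stride factor `alpha` linking stride
#' length to walking speed, the personal-space stride buffer `beta`, the
#' height-normalizing constant `H` (height / 1.72 m), and the body width `w`
#' used to convert between 1D and 2D crowd densities.
#'
#' The input preferred velocity `v0` is initialized toward the goal at
#' `pref_speed`; if the goal coincides with the position the agent is flagged
#' as having reached its goal and `v0` is zero.
#'
#' @param id integer agent identifier.
#' @param p numeric length-2 position (m).
#' @param goal numeric length-2 goal position (m).
#' @param r disk radius (m).
#' @param w body width (m), used in the density-to-space mapping.
#' @param H height-normalizing constant (height / 1.72), dimensionless.
#' @param pref_speed preferred walking speed (m/s).
#' @param alpha stride factor (dimensionless).
#' @param beta stride buffer (dimensionless, >= 0).
#' @param mass body mass (kg), used by the social-force planner.
#' @param v_c current velocity (m/s); defaults to zero.
#' @return An object of class `ped_agent`: a list with the fields above plus
#'   `v0` (the initialized preferred velocity) and `at_goal`.
#' @examples
#' a <- agent_state(1, p = c(0, 0), goal = c(10, 0), pref_speed = 1.3)
#' a$v0  # (1.3, 0)
#' @export
agent_state <- function(id, p, goal, r = 0.2, w = 0.48, H = 1,
                        pref_speed = 1.34, alpha = 1.57, beta = 1.9,
                        mass = 80, v_c = c(0, 0)) {
  stopifnot(length(p) == 2, length(goal) == 2, length(v_c) == 2)
  if (!is.finite(r) || r <= 0) stop("agent radius must be positive")
  if (!is.finite(w) || w <= 0) stop("agent body width must be positive")
  if (!is.finite(H) || H <= 0) stop("height constant H must be positive")
  if (!is.finite(alpha) || alpha <= 0) stop("stride factor alpha must be positive")
  if (!is.finite(beta) || beta < 0) stop("stride buffer beta must be non-negative")
  if (!is.finite(pref_speed) || pref_speed < 0)
    stop("preferred speed must be non-negative")
  if (!is.finite(mass) || mass <= 0) stop("mass must be positive")
  dir <- goal - p
  nrm <- sqrt(sum(dir^2))
  at_goal <- nrm < 1e-12 || pref_speed == 0
  v0 <- if (at_goal) c(0, 0) else dir / nrm * pref_speed
  structure(
    list(id = as.integer(id), r = r, w = w, H = H, p = as.numeric(p),
         v_c = as.numeric(v_c), v0 = v0, pref_speed = pref_speed,
         goal = as.numeric(goal), alpha = alpha, beta = beta, mass = mass,
         at_goal = at_goal),
    class = "ped_agent")
}

#' Density-filter configuration
#'
#' Parameters of the density-dependent preferred-velocity filter. The filter
#' samples `n_samples` directions on the arc `[-theta_max, theta_max]` around
#' the input preferred velocity, probes perceived density `lookahead` meters
#' ahead along each direction, and picks the corrected velocity minimizing the
#' distance to the goal after the optimization period `tau`.
#'
#' @param sigma width (m) of the Gaussian used for per-neighbor density
#'   contributions.
#' @param lateral_scale anisotropy factor (>= 1) stretching lateral
#'   displacements so that agents ahead contribute more than agents abeam.
#' @param lookahead distance (m) from the agent to the density probe point.
#' @param theta_max half-width (rad) of the sampling arc, in (0, pi].
#' @param n_samples odd number (>= 3) of arc samples.
#' @param tau optimization period (s); must exceed the planner time step.
#' @param neighbor_radius neighbor cutoff distance (m), measured from the
#'   agent's position.
#' @param density_norm_mode `"area_normalized"` uses the unit-integral 2D
#'   Gaussian prefactor 1/(2 pi sigma^2); `"as_printed"` uses 1/(2 pi sigma).
#' @param space_mapping_mode how effective 2D density maps to the linear
#'   space `S` ahead of the agent: `"seyfried"` gives `S = 1/(w * rho)`
#'   (the width-based 1D/2D equivalence), `"eq10"` gives `S = w/rho`.
#' @return An object of class `ped_filter_config`.
#' @export
filter_config <- function(sigma = 0.7, lateral_scale = 2.5, lookahead = 1.0,
                          theta_max = pi / 2, n_samples = 13, tau = 1.0,
                          neighbor_radius = 5,
                          density_norm_mode = c("area_normalized", "as_printed"),
                          space_mapping_mode = c("seyfried", "eq10")) {
  density_norm_mode <- match.arg(density_norm_mode)
  space_mapping_mode <- match.arg(space_mapping_mode)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(lateral_scale) || lateral_scale < 1)
    stop("lateral_scale must be >= 1")
  if (!is.finite(lookahead) || lookahead <= 0) stop("lookahead must be positive")
  if (!is.finite(theta_max) || theta_max <= 0 || theta_max > pi)
    stop("theta_max must lie in (0, pi]")
  n_samples <- as.integer(n_samples)
  if (n_samples < 3 || n_samples %% 2 == 0)
    stop("n_samples must be an odd integer >= 3")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (!is.finite(neighbor_radius) || neighbor_radius <= 0)
    stop("neighbor_radius must be positive")
  structure(
    list(sigma = sigma, lateral_scale = lateral_scale, lookahead = lookahead,
         theta_max = theta_max, n_samples = n_samples, tau = tau,
         neighbor_radius = neighbor_radius,
         density_norm_mode = density_norm_mode,
         space_mapping_mode = space_mapping_mode),
    class = "ped_filter_config")
}

#' Social-force planner parameters
#'
#' Constants of the Helbing-style force model: driving-force relaxation time
#' `tau_H`, exponential repulsion strength `A` and range `B`, body-force
#' constant `k` and sliding-friction constant `kappa`, and the default agent
#' mass.
#'
#' @param tau_H relaxation time (s) of the driving force.
#' @param A repulsion strength (N).
#' @param B repulsion range (m).
#' @param k body-force constant (kg/s^2).
#' @param kappa sliding-friction constant (kg/(m s)).
#' @param mass default agent mass (kg).
#' @param interaction_range distance (m) beyond disk contact at which
#'   repulsive forces are truncated (the exponential term is negligible
#'   several `B` beyond contact).
#' @return An object of class `ped_sf_params`.
#' @export
sf_params <- function(tau_H = 0.5, A = 2000, B = 0.08, k = 1.2e5,
                      kappa = 2.4e5, mass = 80, interaction_range = 1.0) {
  vals <- c(tau_H, A, B, k, kappa, mass, interaction_range)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all social-force parameters must be positive")
  structure(
    list(tau_H = tau_H, A = A, B = B, k = k, kappa = kappa, mass = mass,
         interaction_range = interaction_range),
    class = "ped_sf_params")
}

#' Simulation configuration
#'
#' Assembles planner choice, time stepping, the density-filter configuration
#' and planner parameter blocks. Use [validate_config()] to fill defaults and
#' check cross-field invariants (notably `filter$tau > dt`).
#'
#' @param dt local-planner time step (s).
#' @param duration simulated time (s).
#' @param planner `"orca"` or `"sf"`.
#' @param filter_enabled apply the density filter to preferred velocities?
#' @param seed integer seed controlling all randomness of a run.
#' @param filter a [filter_config()].
#' @param sf a [sf_params()] block (used when `planner = "sf"`).
#' @param orca_tau ORCA planning horizon (s).
#' @param orca_max_neighbors cap on the number of nearest agents contributing
#'   ORCA constraints.
#' @param orca_safety_margin extra clearance (m) used by ORCA constraint
#'   construction (see [orca_velocities()]).
#' @param max_speed_factor ratio of an agent's maximum speed to its preferred
#'   speed (caps the ORCA solution disk and the SF speed clamp).
#' @param cell_size obstacle grid cell size c_b (m).
#' @param support_radius compact support radius (m) of the free-space kernel.
#' @param record_every record every k-th frame of the trajectory.
#' @return An object of class `ped_config`.
#' @export
simulation_config <- function(dt = 0.0625, duration = 60, planner = c("orca", "sf"),
                              filter_enabled = TRUE, seed = 1L,
                              filter = filter_config(), sf = sf_params(),
                              orca_tau = 2.0, orca_max_neighbors = 10L,
                              orca_safety_margin = 0.04,
                              max_speed_factor = 1.3, cell_size = 0.1,
                              support_radius = 1.0, record_every = 1L) {
  planner <- match.arg(planner)
  cfg <- structure(
    list(dt = dt, duration = duration, planner = planner,
         filter_enabled = isTRUE(filter_enabled), seed = as.integer(seed),
         filter = filter, sf = sf, orca_tau = orca_tau,
         orca_max_neighbors = as.integer(orca_max_neighbors),
         orca_safety_margin = orca_safety_margin,
         max_speed_factor = max_speed_factor, cell_size = cell_size,
         support_radius = support_radius,
         record_every = as.integer(record_every)),
    class = "ped_config")
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Fills missing blocks with defaults and errors if any invariant is violated,
#' naming the violated constraint. In particular the filter optimization
#' period must exceed the planner time step (the preferred velocity is
#' optimized on a longer time scale than collision avoidance).
#'
#' @param cfg a `ped_config` or a plain list with a subset of its fields.
#' @return The validated `ped_config` with defaults filled.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("cfg must be a list or ped_config")
  defaults <- list(dt = 0.0625, duration = 60, planner = "orca",
                   filter_enabled = TRUE, seed = 1L, orca_tau = 2.0,
                   orca_max_neighbors = 10L, orca_safety_margin = 0.04,
                   max_speed_factor = 1.3, cell_size = 0.1,
                   support_radius = 1.0, record_every = 1L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  # [[ ]] indexing: $ would partial-match filter_enabled
  if (is.null(cfg[["filter"]])) cfg[["filter"]] <- filter_config()
  if (!inherits(cfg[["filter"]], "ped_filter_config"))
    cfg[["filter"]] <- do.call(filter_config, cfg[["filter"]])
  if (is.null(cfg[["sf"]])) cfg[["sf"]] <- sf_params()
  if (!inherits(cfg[["sf"]], "ped_sf_params"))
    cfg[["sf"]] <- do.call(sf_params, cfg[["sf"]])
  if (!cfg$planner %in% c("orca", "sf"))
    stop("planner must be 'orca' or 'sf'")
  if (!is.finite(cfg$dt) || cfg$dt <= 0) stop("violated constraint: dt > 0")
  if (!is.finite(cfg$duration) || cfg$duration <= 0)
    stop("violated constraint: duration > 0")
  if (cfg$filter$tau <= cfg$dt)
    stop("violated constraint: filter$tau > dt (the optimization period ",
         "must exceed the planner time step)")
  if (cfg$orca_tau <= 0) stop("violated constraint: orca_tau > 0")
  if (cfg$orca_safety_margin < 0)
    stop("violated constraint: orca_safety_margin >= 0")
  if (cfg$max_speed_factor < 1)
    stop("violated constraint: max_speed_factor >= 1")
  if (cfg$cell_size <= 0) stop("violated constraint: cell_size > 0")
  if (cfg$support_radius <= 0) stop("violated constraint: support_radius > 0")
  if (cfg$record_every < 1) stop("violated constraint: record_every >= 1")
  class(cfg) <- "ped_config"
  cfg
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with R's random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards. All stochastic components of the
#' package (scenario spawning, heterogeneous preferred speeds, inflow
#' processes) draw from R's RNG, so two evaluations with the same seed are
#' bit-identical.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct a trajectory object
#'
#' A trajectory is the unit of exchange between the simulator and the
#' metrics: time-stamped positions and velocities for every agent, together
#' with the agents' static disk radii and body widths.
#'
#' @param data data.frame with columns `t`, `agent_id`, `x`, `y`, `vx`, `vy`.
#' @param agents data.frame with columns `agent_id`, `r`, `w`.
#' @param period_x spatial period along x for periodic (wrap-around)
#'   scenarios, or `NULL`.
#' @return An object of class `ped_trajectory`.
#' @export
trajectory <- function(data, agents = NULL, period_x = NULL) {
  req <- c("t", "agent_id", "x", "y", "vx", "vy")
  if (!all(req %in% names(data)))
    stop("trajectory data must have columns ", paste(req, collapse = ", "))
  data <- data[order(data$t, data$agent_id), req, drop = FALSE]
  rownames(data) <- NULL
  times <- unique(data$t)
  if (is.unsorted(times, strictly = TRUE))
    stop("frame times must be strictly increasing")
  if (anyDuplicated(data[, c("t", "agent_id")]))
    stop("duplicate (t, agent_id) rows in trajectory")
  if (is.null(agents)) {
    ids <- sort(unique(data$agent_id))
    agents <- data.frame(agent_id = ids, r = rep(0.2, length(ids)),
                         w = rep(0.48, length(ids)))
  }
  structure(list(data = data, agents = agents,
                 period_x = if (is.null(period_x)) NULL else as.numeric(period_x)),
            class = "ped_trajectory")
}

#' @export
print.ped_trajectory <- function(x, ...) {
  times <- unique(x$data$t)
  cat("<ped_trajectory> ", length(times), " frames, ",
      nrow(x$agents), " agents, t in [",
      format(min(times)), ", ", format(max(times)), "] s",
      if (!is.null(x$period_x)) paste0(", periodic x (", x$period_x, " m)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.ped_config <- function(x, ...) {
  cat("<ped_config> planner=", x$planner,
      " filter=", ifelse(x$filter_enabled, "on", "off"),
      " dt=", x$dt, "s duration=", x$duration, "s seed=", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' @export
print.ped_agent <- function(x, ...) {
  cat(sprintf("<ped_agent %d> p=(%.2f, %.2f) goal=(%.2f, %.2f) r=%.2f v0=(%.2f, %.2f)\n",
              x$id, x$p[1], x$p[2], x$goal[1], x$goal[2], x$r, x$v0[1], x$v0[2]))
  invisible(x)
}

# frame-major long data -> list of per-frame matrices keyed by agent, internal
traj_frames <- function(traj) {
  split(traj$data, traj$data$t)
}

# wide frames x agents matrices of x and y (NA where absent), internal
traj_matrices <- function(traj) {
  d <- traj$data
  ids <- traj$agents$agent_id
  times <- unique(d$t)
  ti <- match(d$t, times)
  ai <- match(d$agent_id, ids)
  X <- matrix(NA_real_, length(times), length(ids))
  Y <- X
  VX <- X
  VY <- X
  idx <- cbind(ti, ai)
  X[idx] <- d$x
  Y[idx] <- d$y
  VX[idx] <- d$vx
  VY[idx] <- d$vy
  list(t = times, x = X, y = Y, vx = VX, vy = VY, ids = ids)
}
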