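#' @title Synthetic scenario builders
#' @description Scenarios bundle obstacle polygons, spawn specifications,
#'   goal/waypoint chains, measurement regions and world bounds. They are
#'   fully synthetic: no external data is needed. The straight-to-waypoint
#'   preferred-velocity generator stands in for a global planner.
#' @name scenarios
NULL

new_scenario <- function(name, bounds, polygons, mode, agents,
                         waypoints = NULL, inflow = NULL, measurement = NULL,
                         period_x = NULL, seed = 1L,
                         defaults = scenario_defaults()) {
  segments <- do.call(rbind, c(lapply(polygons, polygon_segments),
                               list(matrix(numeric(0), 0, 4))))
  structure(
    list(name = name, bounds = as.numeric(bounds), polygons = polygons,
         segments = segments, mode = mode, agents = agents,
         waypoints = waypoints, inflow = inflow, measurement = measurement,
         period_x = period_x, seed = as.integer(seed), defaults = defaults),
    class = "ped_scenario")
}

scenario_defaults <- function(r = 0.2, w = 0.48, pref_speed_mean = 1.34,
                              pref_speed_sd = 0.05, alpha = 1.57, beta = 1.9,
                              H = 1, mass = 80) {
  list(r = r, w = w, pref_speed_mean = pref_speed_mean,
       pref_speed_sd = pref_speed_sd, alpha = alpha, beta = beta, H = H,
       mass = mass)
}

polygon_segments <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  n <- nrow(p)
  if (n < 2) return(matrix(numeric(0), 0, 4))
  nxt <- c(2:n, 1)
  cbind(p[, 1], p[, 2], p[nxt, 1], p[nxt, 2])
}

# heterogeneous preferred speeds, truncated normal (draws from the current
# RNG stream; callers wrap in with_seed)
draw_pref_speeds <- function(n, defaults) {
  if (n == 0) return(numeric(0))
  s <- rnorm(n, defaults$pref_speed_mean, defaults$pref_speed_sd)
  pmin(pmax(s, defaults$pref_speed_mean - 2.5 * defaults$pref_speed_sd),
       defaults$pref_speed_mean + 2.5 * defaults$pref_speed_sd)
}

# Jittered-grid disk placement in [xlim] x [ylim]: deterministic feasibility,
# uniform jitter inside each cell keeps disks non-overlapping by construction.
# Agents are spread over the rows as evenly as possible; the returned third
# column is the row index (used for lane-wise direction assignment).
# wrap_x: placements live on a periodic x axis of that period (no x margin).
place_grid_jitter <- function(n, xlim, ylim, r, wrap_x = NULL,
                              force_even_rows = FALSE) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  lx <- diff(xlim)
  y_lo <- ylim[1]
  y_hi <- ylim[2]
  usable_y <- y_hi - y_lo
  min_cell <- 2 * r + 0.04
  max_rows <- floor(usable_y / min_cell)
  if (max_rows < 1) stop("placement failed: corridor too narrow for agent radius")
  best <- NULL
  for (nrows in seq_len(max_rows)) {
    if (force_even_rows && nrows %% 2 == 1 && max_rows >= 2) next
    ncols <- ceiling(n / nrows)
    sx <- lx / ncols
    if (sx < min_cell) next
    sy <- usable_y / nrows
    jx <- (sx - 2 * r - 0.02) / 2
    jy <- (sy - 2 * r - 0.02) / 2
    score <- min(jx, jy)
    if (is.null(best) || score > best$score)
      best <- list(nrows = nrows, ncols = ncols, sx = sx, sy = sy,
                   jx = jx, jy = jy, score = score)
  }
  if (is.null(best))
    stop("placement failed: density too high for non-overlapping placement")
  sizes <- rep(n %/% best$nrows, best$nrows)
  extra <- n %% best$nrows
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  row <- rep(seq_len(best$nrows), sizes)
  col <- unlist(lapply(sizes, function(k) sample(best$ncols, k)))
  x <- xlim[1] + (col - 0.5) * best$sx + runif(n, -best$jx, best$jx)
  y <- y_lo + (row - 0.5) * best$sy + runif(n, -best$jy, best$jy)
  if (!is.null(wrap_x)) x <- (x - xlim[1]) %% wrap_x + xlim[1]
  cbind(x, y, row)
}

corridor_polygons <- function(width, length, margin = 3, thickness = 0.6) {
  bottom <- matrix(c(-margin, -thickness, length + margin, -thickness,
                     length + margin, 0, -margin, 0), ncol = 2, byrow = TRUE)
  top <- matrix(c(-margin, width, length + margin, width,
                  length + margin, width + thickness, -margin, width + thickness),
                ncol = 2, byrow = TRUE)
  list(bottom, top)
}

#' Build a corridor scenario
#'
#' Two straight walls a fixed width apart. In bidirectional mode the corridor
#' is periodic along its axis ("infinitely long"): both walking directions
#' are seeded in equal numbers at the requested initial density on a jittered
#' non-overlapping grid. In uni-directional mode the corridor is open-ended:
#' agents enter at the left at a controlled inflow rate and are removed at
#' the right end. A central measurement region spanning the width provides
#' fundamental-diagram samples.
#'
#' @param width corridor width (m).
#' @param length corridor length (m); the spatial period in bidirectional
#'   mode.
#' @param bidirectional logical.
#' @param initial_density initial crowd density (people/m^2) for the periodic
#'   (bidirectional) corridor; `ceiling(density * width * length)` agents are
#'   placed.
#' @param inflow_rate entry rate (people/s) for the open uni-directional
#'   corridor.
#' @param exit_width width (m) of the exit door of the open corridor. The
#'   default `NULL` leaves the exit fully open; a value below `width` narrows
#'   the outflow so that, with inflow exceeding the door capacity, the
#'   corridor congests upstream (the bottleneck construction of the
#'   uni-directional flow experiments).
#' @param direction_mode how walking directions are assigned in
#'   bidirectional mode: `"rows"` (default) alternates direction between the
#'   placement-grid rows, emulating the organized lanes of steady
#'   bidirectional pedestrian flow; `"random"` interleaves both directions
#'   uniformly (a fully mixed, pre-lane-formation state).
#' @param seed integer seed for placement jitter, direction assignment and
#'   preferred-speed draws.
#' @param defaults agent parameter defaults, see the `scenario_defaults`
#'   entries in the package vignette.
#' @return A `ped_scenario`.
#' @export
build_corridor <- function(width = 3.6, length = 20, bidirectional = TRUE,
                           initial_density = NULL, inflow_rate = NULL,
                           exit_width = NULL,
                           direction_mode = c("rows", "random"),
                           seed = 1L, defaults = scenario_defaults()) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(width > 0, length > 0)
  polys <- corridor_polygons(width, length)
  bounds <- c(-1.6, length + 1.6, -1.6, width + 1.6)
  measurement <- list(xmin = length / 2 - 1, xmax = length / 2 + 1,
                      ymin = 0, ymax = width, axis = "x")
  r <- defaults$r
  if (bidirectional || !is.null(initial_density)) {
    if (is.null(initial_density)) initial_density <- 1.0
    stopifnot(initial_density >= 0)
    n <- ceiling(initial_density * width * length)
    agents <- with_seed(seed, {
      rows_mode <- bidirectional && direction_mode == "rows"
      pos <- place_grid_jitter(n, c(0, length), c(r + 0.05, width - r - 0.05),
                               r, wrap_x = length,
                               force_even_rows = rows_mode)
      dir <- if (bidirectional && n > 0) {
        if (rows_mode) {
          ifelse(pos[, 3] %% 2 == 1, 1L, -1L)
        } else {
          sample(rep(c(1, -1), length.out = n))
        }
      } else rep(1L, max(n, 0))
      if (n == 0) data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                             dir = integer(0), pref_speed = numeric(0))
      else data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2],
                      dir = as.integer(dir),
                      pref_speed = draw_pref_speeds(n, defaults))
    })
    new_scenario(if (bidirectional) "corridor_bidirectional" else
                   "corridor_periodic_unidirectional",
                 bounds, polys, "periodic_corridor", agents,
                 measurement = measurement, period_x = length, seed = seed,
                 defaults = defaults)
  } else {
    if (is.null(inflow_rate))
      stop("uni-directional corridor needs either initial_density or inflow_rate")
    stopifnot(inflow_rate >= 0)
    door <- NULL
    if (!is.null(exit_width) && exit_width < width) {
      stopifnot(exit_width > 0)
      jamb <- (width - exit_width) / 2
      polys <- c(polys, list(
        matrix(c(length, 0, length + 0.5, 0, length + 0.5, jamb,
                 length, jamb), ncol = 2, byrow = TRUE),
        matrix(c(length, width - jamb, length + 0.5, width - jamb,
                 length + 0.5, width, length, width), ncol = 2, byrow = TRUE)))
      bounds <- c(-1.6, length + 2.6, -1.6, width + 1.6)
      door <- list(x = length + 0.25, y = width / 2, width = exit_width,
                   approach_x = length - 3)
    }
    inflow <- list(rate = inflow_rate, x0 = 0.5,
                   ymin = r + 0.1, ymax = width - r - 0.1,
                   exit_x = if (is.null(door)) length - 0.2 else length + 0.7,
                   width = width, door = door)
    agents <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                         dir = integer(0), pref_speed = numeric(0))
    new_scenario("corridor_unidirectional", bounds, polys, "open_corridor",
                 agents, inflow = inflow, measurement = measurement,
                 period_x = NULL, seed = seed, defaults = defaults)
  }
}

hourglass_polygons <- function() {
  inner_top <- matrix(c(
    -24, 3.0, -6, 3.0, -4, 2.6, -2, 1.4, -1, 0.9, 0, 0.6,
    1, 0.9, 2, 1.4, 4, 2.6, 6, 3.0, 14, 3.0), ncol = 2, byrow = TRUE)
  top <- rbind(inner_top, c(14, 6), c(-24, 6))
  bottom <- top
  bottom[, 2] <- -bottom[, 2]
  list(top, bottom)
}

#' Build the hourglass scenario
#'
#' Two mirrored concave boundaries forming a narrow central passage (1.2 m
#' wide). Agents are seeded in a staging area on the left and stream through
#' the passage toward a goal on the right, where they are removed.
#'
#' @param n_agents number of agents.
#' @param seed integer seed.
#' @param defaults agent parameter defaults.
#' @return A `ped_scenario`.
#' @export
build_hourglass <- function(n_agents = 200, seed = 1L,
                            defaults = scenario_defaults()) {
  stopifnot(n_agents > 0)
  polys <- hourglass_polygons()
  bounds <- c(-25, 15, -7, 7)
  r <- defaults$r
  agents <- with_seed(seed, {
    pos <- place_grid_jitter(n_agents, c(-23, -7), c(-2.6, 2.6), r)
    data.frame(id = seq_len(n_agents), x = pos[, 1], y = pos[, 2],
               dir = 1L, pref_speed = draw_pref_speeds(n_agents, defaults))
  })
  wps <- lapply(seq_len(n_agents), function(i) {
    list(pts = matrix(c(0, 0, 12, 0), ncol = 2, byrow = TRUE),
         dwell = c(0, 0), capture = c(1.2, 1.5), terminal = "remove")
  })
  measurement <- list(xmin = -2, xmax = 2, ymin = -1.5, ymax = 1.5, axis = "x")
  new_scenario("hourglass", bounds, polys, "waypoints", agents,
               waypoints = wps, measurement = measurement, seed = seed,
               defaults = defaults)
}

#' Build the ticket-kiosk scenario
#'
#' Agents spawn on concentric rings and walk inward to a central kiosk,
#' dwell there for `wait_time` seconds, then head outward again, creating
#' opposing flows at high density near the center.
#'
#' @param n_agents number of agents.
#' @param wait_time dwell time (s) at the kiosk.
#' @param seed integer seed.
#' @param defaults agent parameter defaults.
#' @return A `ped_scenario`.
#' @export
build_kiosk <- function(n_agents, wait_time = 10, seed = 1L,
                        defaults = scenario_defaults()) {
  stopifnot(n_agents > 0, wait_time >= 0)
  r0 <- 6
  spacing <- 1.0
  pos <- NULL
  ring <- 0
  while (is.null(pos) || nrow(pos) < n_agents) {
    radius <- r0 + ring * spacing
    k <- floor(2 * pi * radius / spacing)
    ang <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)] +
      (ring %% 2) * pi / k
    pos <- rbind(pos, cbind(radius * cos(ang), radius * sin(ang)))
    ring <- ring + 1
  }
  pos <- pos[seq_len(n_agents), , drop = FALSE]
  rmax <- r0 + ring * spacing
  agents <- with_seed(seed, {
    data.frame(id = seq_len(n_agents), x = pos[, 1], y = pos[, 2], dir = 1L,
               pref_speed = draw_pref_speeds(n_agents, defaults))
  })
  wps <- lapply(seq_len(n_agents), function(i) {
    p <- pos[i, ]
    out <- p / sqrt(sum(p^2)) * (rmax + 4)
    list(pts = matrix(c(0, 0, out), ncol = 2, byrow = TRUE),
         dwell = c(wait_time, 0), capture = c(1.5, 1.0), terminal = "remove")
  })
  bounds <- c(-rmax - 6, rmax + 6, -rmax - 6, rmax + 6)
  measurement <- list(xmin = -2, xmax = 2, ymin = -2, ymax = 2, axis = "x")
  new_scenario("kiosk", bounds, list(), "waypoints", agents, waypoints = wps,
               measurement = measurement, seed = seed, defaults = defaults)
}

#' Preferred velocity toward the current waypoint
#'
#' The straight-to-waypoint stand-in for a global planner: a unit vector
#' toward the agent's current waypoint times its preferred speed. The
#' waypoint advances when the agent is within the waypoint's capture radius
#' (default `2 * r`); with no remaining waypoint the preferred velocity is
#' zero.
#'
#' @param agent a [agent_state()]; the current waypoint index may be stored
#'   as `agent$wp_index` (default 1).
#' @param scenario a `ped_scenario` with a waypoint chain for this agent, or
#'   a plain list/matrix of waypoints.
#' @return Length-2 preferred velocity with attribute `wp_index` (the
#'   possibly advanced waypoint index).
#' @export
preferred_velocity <- function(agent, scenario) {
  wp <- if (inherits(scenario, "ped_scenario")) {
    idx <- match(agent$id, scenario$agents$id)
    if (is.na(idx) || is.null(scenario$waypoints)) NULL
    else scenario$waypoints[[idx]]
  } else if (is.matrix(scenario)) {
    list(pts = scenario, dwell = rep(0, nrow(scenario)),
         capture = rep(2 * agent$r, nrow(scenario)))
  } else {
    scenario
  }
  if (is.null(wp) || nrow(wp$pts) == 0) {
    return(structure(c(0, 0), wp_index = NA_integer_))
  }
  i <- agent$wp_index
  if (is.null(i)) i <- 1L
  capture <- wp$capture
  if (is.null(capture)) capture <- rep(2 * agent$r, nrow(wp$pts))
  while (i <= nrow(wp$pts) &&
         sqrt(sum((wp$pts[i, ] - agent$p)^2)) <= capture[i]) {
    i <- i + 1L
  }
  if (i > nrow(wp$pts)) {
    return(structure(c(0, 0), wp_index = i))
  }
  d <- wp$pts[i, ] - agent$p
  nrm <- sqrt(sum(d^2))
  structure(d / nrm * agent$pref_speed, wp_index = i)
}

#' @export
print.ped_scenario <- function(x, ...) {
  cat("<ped_scenario '", x$name, "'> ", nrow(x$agents), " initial agents, ",
      length(x$polygons), " obstacle polygons",
      if (!is.null(x$period_x)) paste0(", periodic x (", x$period_x, " m)"),
      if (!is.null(x$inflow)) paste0(", inflow ", x$inflow$rate, " /s"),
      "\n", sep = "")
  invisible(x)
}
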