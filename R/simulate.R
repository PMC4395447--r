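#' Run a crowd simulation
#'
#' Advances a scenario under the configured local planner, optionally
#' passing every agent's input preferred velocity through the
#' density-dependent filter first. The loop per step is: (1) compute input
#' preferred velocities from the waypoint/goal logic, (2) apply the density
#' filter (when enabled) to obtain corrected preferred velocities, (3) hand
#' these to the local planner (ORCA or social forces) for collision
#' avoidance, (4) integrate, wrap periodic coordinates, advance waypoints
#' and spawn/remove agents.
#'
#' All randomness (inflow arrivals, spawn jitter) derives from
#' `config$seed`; runs with identical scenario, config and seed are
#' bit-identical.
#'
#' @param scenario a `ped_scenario` from one of the builders.
#' @param config a [simulation_config()].
#' @return A [trajectory()] with attributes `scenario_name` and `config`.
#' @export
simulate_crowd <- function(scenario, config = simulation_config()) {
  cfg <- validate_config(config)
  stopifnot(inherits(scenario, "ped_scenario"))
  def <- scenario$defaults
  field <- if (length(scenario$polygons)) {
    obstacle_field(scenario$polygons, scenario$bounds, cfg$cell_size,
                   cfg$support_radius)
  } else NULL

  with_seed(cfg$seed, {
    n0 <- nrow(scenario$agents)
    state <- list(
      id = scenario$agents$id,
      x = scenario$agents$x, y = scenario$agents$y,
      vx = numeric(n0), vy = numeric(n0),
      dir = scenario$agents$dir,
      pref = scenario$agents$pref_speed,
      r = rep(def$r, n0), w = rep(def$w, n0),
      alpha = rep(def$alpha, n0), beta = rep(def$beta, n0),
      H = rep(def$H, n0), mass = rep(def$mass, n0),
      active = rep(TRUE, n0),
      wp_index = rep(1L, n0), dwell_until = rep(-Inf, n0),
      dwelling = rep(FALSE, n0))

    period <- scenario$period_x
    segs <- scenario$segments
    nsteps <- ceiling(cfg$duration / cfg$dt)
    rec_steps <- seq(0, nsteps, by = cfg$record_every)
    frames <- vector("list", length(rec_steps))
    ri <- 1L

    # precompute inflow arrival schedule (Poisson process)
    arrivals <- numeric(0)
    next_arrival <- 1L
    if (!is.null(scenario$inflow) && scenario$inflow$rate > 0) {
      gaps <- rexp(ceiling(scenario$inflow$rate * cfg$duration * 2) + 20,
                   rate = scenario$inflow$rate)
      arrivals <- cumsum(gaps)
      arrivals <- arrivals[arrivals <= cfg$duration]
    }
    next_id <- if (n0 > 0) max(state$id) + 1L else 1L
    pending_spawns <- 0L

    record <- function(t) {
      a <- state$active
      frames[[ri]] <<- data.frame(
        t = rep(t, sum(a)), agent_id = state$id[a], x = state$x[a],
        y = state$y[a], vx = state$vx[a], vy = state$vy[a])
      ri <<- ri + 1L
    }

    all_agents <- data.frame(agent_id = state$id, r = state$r, w = state$w)

    record(0)
    for (step in seq_len(nsteps)) {
      t_now <- (step - 1) * cfg$dt

      # spawn pending + newly due inflow agents
      if (length(arrivals)) {
        due <- if (next_arrival > length(arrivals)) 0L else
          sum(arrivals[next_arrival:length(arrivals)] <= t_now + cfg$dt)
        next_arrival <- next_arrival + due
        pending_spawns <- pending_spawns + due
        while (pending_spawns > 0L) {
          sp <- try_spawn(state, scenario, def)
          if (is.null(sp)) break
          state <- append_agent(state, sp, next_id, def)
          all_agents <- rbind(all_agents,
                              data.frame(agent_id = next_id, r = def$r,
                                         w = def$w))
          next_id <- next_id + 1L
          pending_spawns <- pending_spawns - 1L
        }
      }

      a <- which(state$active)
      if (length(a)) {
        gw <- goals_and_v0(state, a, scenario, t_now)
        state$wp_index[a] <- gw$wp_index
        state$dwell_until[a] <- gw$dwell_until
        state$dwelling[a] <- gw$dwelling

        pos <- cbind(state$x[a], state$y[a])
        vel <- cbind(state$vx[a], state$vy[a])
        pref_speed <- ifelse(gw$dwelling, 0, state$pref[a])
        v0 <- gw$v0
        goal <- gw$goal

        v_pref <- if (cfg$filter_enabled) {
          filter_batch(pos, v0, pref_speed, goal, state$w[a], state$alpha[a],
                       state$beta[a], state$H[a], cfg$filter, field, period)
        } else v0

        max_speed <- cfg$max_speed_factor * state$pref[a]
        if (cfg$planner == "orca") {
          vnew <- orca_velocities(pos, vel, v_pref, state$r[a], max_speed,
                                  cfg$orca_tau, cfg$dt, segs,
                                  cfg$filter$neighbor_radius,
                                  cfg$orca_max_neighbors,
                                  period_x = period,
                                  safety_margin = cfg$orca_safety_margin)
          pos <- pos + vnew * cfg$dt
        } else {
          st <- sf_step(pos, vel, v_pref, state$r[a], state$mass[a],
                        max_speed, cfg$dt, cfg$sf, segs, period,
                        seed = cfg$seed, step = step)
          pos <- st$pos
          vnew <- st$vel
        }
        if (!is.null(period)) pos[, 1] <- pos[, 1] %% period
        state$x[a] <- pos[, 1]
        state$y[a] <- pos[, 2]
        state$vx[a] <- vnew[, 1]
        state$vy[a] <- vnew[, 2]

        state <- deactivate_done(state, a, scenario)
      }

      if (step %in% rec_steps) record(step * cfg$dt)
    }

    data <- do.call(rbind, frames[!vapply(frames, is.null, logical(1))])
    traj <- trajectory(data, agents = all_agents, period_x = period)
    attr(traj, "scenario_name") <- scenario$name
    attr(traj, "config") <- cfg
    traj
  })
}

# goal positions and input preferred velocities for the active agents,
# including waypoint advancement and dwell timers
goals_and_v0 <- function(state, a, scenario, t_now) {
  n <- length(a)
  v0 <- matrix(0, n, 2)
  goal <- matrix(0, n, 2)
  wp_index <- state$wp_index[a]
  dwell_until <- state$dwell_until[a]
  dwelling <- rep(FALSE, n)
  if (scenario$mode == "periodic_corridor") {
    d <- state$dir[a]
    v0[, 1] <- d * state$pref[a]
    goal[, 1] <- state$x[a] + d * 50
    goal[, 2] <- state$y[a]
  } else if (scenario$mode == "open_corridor") {
    # aim at the far exit, keeping the current lateral position: straight +x
    v0[, 1] <- state$pref[a]
    goal[, 1] <- state$x[a] + 50
    goal[, 2] <- state$y[a]
    door <- scenario$inflow$door
    if (!is.null(door)) {
      # funnel toward the door once near the exit
      near <- state$x[a] > door$approach_x & state$x[a] < door$x
      if (any(near)) {
        dx <- door$x + 0.3 - state$x[a][near]
        dy <- door$y - state$y[a][near]
        nrm <- sqrt(dx^2 + dy^2)
        v0[near, 1] <- dx / nrm * state$pref[a][near]
        v0[near, 2] <- dy / nrm * state$pref[a][near]
        goal[near, 1] <- door$x + 0.3
        goal[near, 2] <- door$y
      }
    }
  } else {  # waypoints
    idx_all <- match(state$id[a], scenario$agents$id)
    for (k in seq_len(n)) {
      wp <- scenario$waypoints[[idx_all[k]]]
      i <- wp_index[k]
      p <- c(state$x[a[k]], state$y[a[k]])
      npts <- nrow(wp$pts)
      if (i <= npts && sqrt(sum((wp$pts[i, ] - p)^2)) <= wp$capture[i]) {
        if (wp$dwell[i] > 0 && is.infinite(dwell_until[k])) {
          dwell_until[k] <- t_now + wp$dwell[i]
        }
        if (t_now < dwell_until[k]) {
          dwelling[k] <- TRUE
          goal[k, ] <- p
          next
        }
        i <- i + 1L
        wp_index[k] <- i
        dwell_until[k] <- -Inf
      }
      if (i > npts) {
        goal[k, ] <- p
        next
      }
      d <- wp$pts[i, ] - p
      nrm <- sqrt(sum(d^2))
      if (nrm > 1e-9) v0[k, ] <- d / nrm * state$pref[a[k]]
      goal[k, ] <- wp$pts[i, ]
    }
  }
  list(v0 = v0, goal = goal, wp_index = wp_index, dwell_until = dwell_until,
       dwelling = dwelling)
}

# attempt to place one inflow agent without overlap; NULL if blocked
try_spawn <- function(state, scenario, def) {
  inf <- scenario$inflow
  act <- which(state$active)
  for (k in 1:10) {
    y <- runif(1, inf$ymin, inf$ymax)
    x <- inf$x0
    if (length(act)) {
      d2 <- (state$x[act] - x)^2 + (state$y[act] - y)^2
      if (min(d2) < (2 * def$r + 0.05)^2) next
    }
    return(c(x, y))
  }
  NULL
}

append_agent <- function(state, p, id, def) {
  state$id <- c(state$id, id)
  state$x <- c(state$x, p[1])
  state$y <- c(state$y, p[2])
  state$vx <- c(state$vx, 0)
  state$vy <- c(state$vy, 0)
  state$dir <- c(state$dir, 1L)
  state$pref <- c(state$pref, draw_pref_speeds(1, def))
  state$r <- c(state$r, def$r)
  state$w <- c(state$w, def$w)
  state$alpha <- c(state$alpha, def$alpha)
  state$beta <- c(state$beta, def$beta)
  state$H <- c(state$H, def$H)
  state$mass <- c(state$mass, def$mass)
  state$active <- c(state$active, TRUE)
  state$wp_index <- c(state$wp_index, 1L)
  state$dwell_until <- c(state$dwell_until, -Inf)
  state$dwelling <- c(state$dwelling, FALSE)
  state
}

deactivate_done <- function(state, a, scenario) {
  if (scenario$mode == "open_corridor") {
    gone <- a[state$x[a] > scenario$inflow$exit_x + 0.4]
    if (length(gone)) state$active[gone] <- FALSE
  } else if (scenario$mode == "waypoints") {
    for (k in a) {
      idx <- match(state$id[k], scenario$agents$id)
      wp <- scenario$waypoints[[idx]]
      if (state$wp_index[k] > nrow(wp$pts) &&
          identical(wp$terminal, "remove")) {
        state$active[k] <- FALSE
      }
    }
  }
  state
}
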