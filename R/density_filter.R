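#' Anisotropic personal-space displacement transform
#'
#' Humans weight space in front of them more heavily than space to the side.
#' The displacement `d` toward a neighbor is split into its component along
#' the probe direction `v_hat` (preserved) and the lateral remainder (scaled
#' by `lateral_scale`), so that after the transform a neighbor abeam appears
#' farther away than one dead ahead at the same distance.
#'
#' @param d numeric length-2 displacement (m).
#' @param v_hat unit length-2 direction vector.
#' @param lateral_scale lateral stretch factor (>= 1).
#' @return The transformed displacement d'.
#' @examples
#' transform_displacement(c(1, 1), c(1, 0), 2.5)  # (1, 2.5)
#' @export
transform_displacement <- function(d, v_hat, lateral_scale = 2.5) {
  stopifnot(length(d) == 2, length(v_hat) == 2)
  if (abs(sum(v_hat^2) - 1) > 1e-8) stop("v_hat must have unit length")
  d_forward <- sum(d * v_hat) * v_hat
  lateral_scale * (d - d_forward) + d_forward
}

#' Perceived agent density along a probe direction
#'
#' Sums anisotropic Gaussian contributions of neighboring agents. The
#' displacement to each neighbor is measured from the probing agent's
#' position (`d = p - p_j`) and passed through
#' [transform_displacement()] for the probe direction, so neighbors in front
#' contribute more than neighbors to the side.
#'
#' @param p probing agent position (length-2).
#' @param v_hat unit probe direction.
#' @param neighbors n x 2 matrix of neighbor positions (pre-filtered to the
#'   neighbor cutoff; may have zero rows).
#' @param sigma Gaussian width (m).
#' @param lateral_scale lateral stretch factor.
#' @param density_norm_mode `"area_normalized"` (unit-integral 2D Gaussian,
#'   prefactor 1/(2 pi sigma^2)) or `"as_printed"` (1/(2 pi sigma)).
#' @return Density in people/m^2.
#' @export
agent_density <- function(p, v_hat, neighbors, sigma = 0.7,
                          lateral_scale = 2.5,
                          density_norm_mode = c("area_normalized", "as_printed")) {
  density_norm_mode <- match.arg(density_norm_mode)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  neighbors <- if (is.null(neighbors)) matrix(numeric(0), 0, 2) else
    matrix(as.numeric(neighbors), ncol = 2)
  if (nrow(neighbors) == 0) return(0)
  pref <- if (density_norm_mode == "area_normalized")
    1 / (2 * pi * sigma^2) else 1 / (2 * pi * sigma)
  total <- 0
  for (j in seq_len(nrow(neighbors))) {
    d <- p - neighbors[j, ]
    dp <- transform_displacement(d, v_hat, lateral_scale)
    total <- total + pref * exp(-sum(dp^2) / (2 * sigma^2))
  }
  total
}

#' Effective density including obstacle discomfort
#'
#' Scales perceived agent density by the inverse of the contiguous free
#' space at the probe point: walls and corners reduce FS below 1 and so
#' inflate the density an agent perceives there.
#'
#' @param rho_A agent density (people/m^2).
#' @param fs contiguous free-space value in (0, 1].
#' @return Effective density (people/m^2), `rho_A / fs`.
#' @export
effective_density <- function(rho_A, fs) {
  if (!is.finite(fs) || fs <= 0) stop("fs must lie in (0, 1]")
  rho_A / fs
}

#' Natural walking speed for the available space ahead
#'
#' The biomechanical stride-length relation `L(v) = alpha * H * sqrt(v)`,
#' inflated by the personal-space stride buffer `beta`, gives the space
#' needed to walk comfortably at speed v: `S_needed = alpha H (1 + beta)
#' sqrt(v)`. Inverting and capping at the preferred speed yields the natural
#' speed for available space `S`:
#' `V(S) = min(pref_speed, (S / (alpha H (1 + beta)))^2)`.
#'
#' @param S available space ahead (m), >= 0.
#' @param pref_speed preferred walking speed (m/s).
#' @param alpha stride factor.
#' @param H height-normalizing constant.
#' @param beta stride buffer.
#' @return Natural speed (m/s), monotone nondecreasing in `S`.
#' @examples
#' natural_speed(1, pref_speed = 2, alpha = 1, H = 1, beta = 0)  # 1
#' @export
natural_speed <- function(S, pref_speed, alpha = 1.57, H = 1, beta = 1.9) {
  if (any(!is.finite(S) & !is.infinite(S)) || any(S < 0))
    stop("available space S must be non-negative")
  pmin(pref_speed, (S / (alpha * H * (1 + beta)))^2)
}

#' Map a 2D crowd density to the linear space ahead of an agent
#'
#' Single-file (1D) fundamental-diagram measurements relate to 2D crowd
#' densities through a scale factor equal to the inverse of the body width:
#' `rho_1D = w * rho_2D` (people/m), so the space per person along the
#' walking line is `S = 1/rho_1D = 1/(w * rho_2D)` (`mode = "seyfried"`, the
#' default). The alternative `mode = "eq10"` uses `S = w / rho_2D`.
#'
#' @param rho 2D density (people/m^2).
#' @param w body width (m).
#' @param mode `"seyfried"` or `"eq10"`.
#' @return Space `S` (m); `Inf` for zero density (uncongested).
#' @examples
#' space_from_density(2.08, w = 0.48, mode = "seyfried")  # ~1 m
#' @export
space_from_density <- function(rho, w = 0.48, mode = c("seyfried", "eq10")) {
  mode <- match.arg(mode)
  if (!is.finite(w) || w <= 0) stop("body width must be positive")
  if (any(rho < 0)) stop("density must be non-negative")
  S <- ifelse(rho == 0, Inf,
              if (mode == "seyfried") 1 / (w * rho) else w / rho)
  as.numeric(S)
}

#' Convert a 1D line density to the equivalent 2D crowd density
#'
#' The inverse of the width-based mapping used by [space_from_density()]:
#' `rho_2D = rho_1D / w`.
#'
#' @param rho_1d line density (people/m).
#' @param w body width (m).
#' @return 2D density (people/m^2).
#' @examples
#' density_1d_to_2d(1, w = 0.48)  # 2.083...
#' @export
density_1d_to_2d <- function(rho_1d, w = 0.48) {
  if (!is.finite(w) || w <= 0) stop("body width must be positive")
  rho_1d / w
}

#' Corrected preferred velocity for one arc sample
#'
#' Composes the density pipeline for a single probe direction: perceived
#' agent density, free-space scaling at the probe point, density-to-space
#' mapping and the natural-speed relation. The output points along the probe
#' direction with the natural-speed magnitude.
#'
#' @param theta angular offset (rad, counterclockwise) from the direction of
#'   the agent's input preferred velocity.
#' @param agent a [agent_state()].
#' @param cfg a [filter_config()].
#' @param field optional `ped_obstacle_field` (NULL in open space).
#' @param neighbors n x 2 matrix of neighbor positions.
#' @return list with `v_fd` (the corrected velocity), `q` (probe point),
#'   `rho_A`, `rho`, `fs` and `cost` (distance to goal after `cfg$tau`).
#' @export
corrected_velocity <- function(theta, agent, cfg = filter_config(),
                               field = NULL, neighbors = NULL) {
  v0n <- sqrt(sum(agent$v0^2))
  if (v0n < 1e-12 || agent$pref_speed <= 0) {
    return(list(v_fd = c(0, 0), q = agent$p, rho_A = 0, rho = 0, fs = 1,
                cost = sqrt(sum((agent$goal - agent$p)^2))))
  }
  h <- agent$v0 / v0n
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  v_hat <- as.numeric(rot %*% h)
  q <- agent$p + v_hat * cfg$lookahead
  rho_A <- agent_density(agent$p, v_hat, neighbors, cfg$sigma,
                         cfg$lateral_scale, cfg$density_norm_mode)
  fs <- if (is.null(field)) 1 else fs_at(field, q)
  rho <- effective_density(rho_A, fs)
  S <- space_from_density(rho, agent$w, cfg$space_mapping_mode)
  V <- natural_speed(S, agent$pref_speed, agent$alpha, agent$H, agent$beta)
  v_fd <- v_hat * V
  cost <- sqrt(sum((agent$goal - (agent$p + v_fd * cfg$tau))^2))
  list(v_fd = v_fd, q = q, rho_A = rho_A, rho = rho, fs = fs, cost = cost)
}

#' Optimal corrected preferred velocity over the sampling arc
#'
#' Evaluates [corrected_velocity()] at `cfg$n_samples` directions evenly
#' spaced on `[-theta_max, theta_max]` around the input preferred velocity
#' and returns the one minimizing the distance to the goal after the
#' optimization period `tau`. Ties are broken toward the smallest `|theta|`,
#' then toward the negative offset. An agent may thereby choose a longer but
#' less congested heading if it makes more progress toward the goal.
#'
#' @inheritParams corrected_velocity
#' @return The corrected preferred velocity (length-2, speed bounded by the
#'   agent's preferred speed).
#' @export
select_optimal <- function(agent, cfg = filter_config(), field = NULL,
                           neighbors = NULL) {
  if (agent$pref_speed <= 0 || sqrt(sum(agent$v0^2)) < 1e-12) return(c(0, 0))
  m <- (cfg$n_samples - 1) / 2
  dtheta <- cfg$theta_max / m
  thetas <- c(0, as.vector(rbind(-(1:m) * dtheta, (1:m) * dtheta)))
  best <- NULL
  best_cost <- Inf
  for (th in thetas) {
    s <- corrected_velocity(th, agent, cfg, field, neighbors)
    if (s$cost < best_cost) {
      best_cost <- s$cost
      best <- s$v_fd
    }
  }
  best
}

# Batch interface used by the simulator: delegates to the C++ kernel.
# Returns an n x 2 matrix of corrected preferred velocities.
filter_batch <- function(pos, v0, pref_speed, goal, w, alpha, beta, H, cfg,
                         field = NULL, period_x = NULL) {
  fsmat <- NULL
  ox <- 0; oy <- 0; cb <- 1
  if (!is.null(field)) {
    fsmat <- field$fs
    ox <- field$origin[1]; oy <- field$origin[2]; cb <- field$cell_size
  }
  cpp_filter_batch(pos, v0, pref_speed, goal, w, alpha, beta, H,
                   cfg$sigma, cfg$lateral_scale, cfg$lookahead, cfg$theta_max,
                   cfg$n_samples, cfg$tau, cfg$neighbor_radius,
                   cfg$density_norm_mode == "area_normalized",
                   cfg$space_mapping_mode == "seyfried",
                   fsmat, ox, oy, cb,
                   if (is.null(period_x)) NaN else period_x)
}
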