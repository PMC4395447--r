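#' Fundamental-diagram samples from a trajectory
#'
#' For every complete transit of an agent through the measurement region,
#' records one (density, speed) pair: the transit speed is the region's
#' length along the flow axis divided by the transit time, and the density
#' is the time average, over the transit interval, of the number of agents
#' whose centers lie in the region divided by the region area. Agents that
#' enter and turn back, or that never fully cross, produce no sample. In
#' periodic scenarios every wrap around the corridor yields a new transit.
#'
#' @param traj a [trajectory()].
#' @param region list with `xmin`, `xmax`, `ymin`, `ymax` and `axis`
#'   (currently `"x"`): the measurement rectangle and its flow axis.
#' @return data.frame with columns `agent_id`, `t_in`, `t_out`, `density`
#'   (people/m^2) and `speed` (m/s).
#' @export
fd_samples <- function(traj, region) {
  stopifnot(inherits(traj, "ped_trajectory"))
  area <- (region$xmax - region$xmin) * (region$ymax - region$ymin)
  if (area <= 0) stop("measurement region must have positive area")
  axis_len <- region$xmax - region$xmin
  M <- traj_matrices(traj)
  times <- M$t
  K <- length(times)
  if (K == 0) return(empty_fd())
  inside <- !is.na(M$x) & M$x >= region$xmin & M$x <= region$xmax &
    M$y >= region$ymin & M$y <= region$ymax
  occupancy <- rowSums(inside)

  # piecewise-constant occupancy integral of density over [t0, t1]
  dens_avg <- function(t0, t1) {
    if (t1 <= t0) return(occupancy[findInterval(t0, times)] / area)
    ks <- seq_len(K - 1)
    lo <- pmax(times[ks], t0)
    hi <- pmin(times[ks + 1], t1)
    wgt <- pmax(hi - lo, 0)
    sum(occupancy[ks] * wgt) / (t1 - t0) / area
  }

  period <- traj$period_x
  out <- list()
  for (ai in seq_along(M$ids)) {
    xs <- M$x[, ai]
    ys <- M$y[, ai]
    pres <- !is.na(xs)
    if (sum(pres) < 2) next
    # unwrap the axis coordinate for crossing interpolation
    ux <- xs
    if (!is.null(period)) {
      idx <- which(pres)
      dx <- diff(xs[idx])
      dx <- dx - period * round(dx / period)
      ux[idx] <- xs[idx[1]] + c(0, cumsum(dx))
    }
    ins <- inside[, ai]
    runs <- rle(ins)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (rr in which(runs$values)) {
      s <- starts[rr]; e <- ends[rr]
      if (s == 1 || e == K) next              # never saw entry or exit
      if (!pres[s - 1] || !pres[e + 1]) next  # absent just outside
      # wrapped offset aligning the region with the unwrapped coordinate
      off <- ux[s] - xs[s]
      lo <- region$xmin + off
      hi <- region$xmax + off
      x_before <- ux[s - 1]; x_after <- ux[e + 1]
      entered_low <- x_before < lo
      entered_high <- x_before > hi
      exited_low <- x_after < lo
      exited_high <- x_after > hi
      if (entered_low && exited_high) {
        t_in <- cross_time(times[s - 1], times[s], x_before, ux[s], lo)
        t_out <- cross_time(times[e], times[e + 1], ux[e], x_after, hi)
      } else if (entered_high && exited_low) {
        t_in <- cross_time(times[s - 1], times[s], x_before, ux[s], hi)
        t_out <- cross_time(times[e], times[e + 1], ux[e], x_after, lo)
      } else {
        next  # turned back or grazed: not a full crossing
      }
      out[[length(out) + 1]] <- data.frame(
        agent_id = M$ids[ai], t_in = t_in, t_out = t_out,
        density = dens_avg(t_in, t_out),
        speed = axis_len / (t_out - t_in))
    }
  }
  if (!length(out)) return(empty_fd())
  res <- do.call(rbind, out)
  res[order(res$t_in, res$agent_id), ]
}

empty_fd <- function() {
  data.frame(agent_id = integer(0), t_in = numeric(0), t_out = numeric(0),
             density = numeric(0), speed = numeric(0))
}

cross_time <- function(t0, t1, x0, x1, xb) {
  if (x1 == x0) return(t0)
  t0 + (xb - x0) / (x1 - x0) * (t1 - t0)
}

#' Interval penetration depth between two moving disks
#'
#' Assuming linear motion over one integration interval, returns
#' `max(0, r_i + r_j - d_min)` where `d_min` is the minimum center distance
#' over the interval (the closed-form minimum of a quadratic in time).
#'
#' @param p_i0,p_i1 agent i positions at the interval ends (length-2, m).
#' @param p_j0,p_j1 agent j positions at the interval ends.
#' @param r_i,r_j disk radii (m).
#' @return Penetration depth (m, >= 0).
#' @examples
#' interval_penetration(c(0, 0), c(0, 0), c(0.4, 0), c(0.4, 0), 0.25, 0.25)
#' @export
interval_penetration <- function(p_i0, p_i1, p_j0, p_j1, r_i, r_j) {
  rel0 <- p_j0 - p_i0
  rel1 <- p_j1 - p_i1
  dv <- rel1 - rel0
  vv <- sum(dv^2)
  s <- if (vv > 1e-12) max(0, min(1, -sum(rel0 * dv) / vv)) else 0
  dmin <- sqrt(sum((rel0 + s * dv)^2))
  max(0, r_i + r_j - dmin)
}

#' Collision score of a trajectory
#'
#' The average interval penetration depth across all frames and agents: for
#' every pair of adjacent frames the pairwise penetration depths (under
#' linear motion) are summed, and the total is normalized by the chosen
#' divisor. The default, `"per_agent_interval"`, divides by the number of
#' agent-intervals (frames-1 times agents present), giving a per-frame
#' per-agent average; `"per_pair_interval"` and `"total"` are exposed so
#' alternative normalizations can be examined.
#'
#' @param traj a [trajectory()].
#' @param normalization one of `"per_agent_interval"`,
#'   `"per_pair_interval"`, `"total"`.
#' @return An object of class `ped_collision_score`: list with `score` (m),
#'   `total`, `per_interval` (per-frame series), `n_intervals`,
#'   `agent_intervals` and `pair_intervals`. The score is zero iff no
#'   interval has any overlap.
#' @export
collision_score <- function(traj,
                            normalization = c("per_agent_interval",
                                              "per_pair_interval", "total")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(traj, "ped_trajectory"))
  M <- traj_matrices(traj)
  if (length(M$t) < 2) stop("need at least 2 frames")
  r <- traj$agents$r[match(M$ids, traj$agents$agent_id)]
  res <- cpp_collision_score(M$x, M$y, r,
                             if (is.null(traj$period_x)) NaN else traj$period_x)
  score <- switch(normalization,
                  per_agent_interval = if (res$agent_intervals > 0)
                    res$total / res$agent_intervals else 0,
                  per_pair_interval = if (res$pair_intervals > 0)
                    res$total / res$pair_intervals else 0,
                  total = res$total)
  structure(list(score = score, total = res$total,
                 per_interval = res$per_interval,
                 n_intervals = res$n_intervals,
                 agent_intervals = res$agent_intervals,
                 pair_intervals = res$pair_intervals,
                 normalization = normalization),
            class = "ped_collision_score")
}

#' @export
print.ped_collision_score <- function(x, ...) {
  cat(sprintf("<collision score> %.6g m (%s; %d intervals)\n", x$score,
              x$normalization, x$n_intervals))
  invisible(x)
}

#' Trajectory smoothness measures
#'
#' Finite-difference mean acceleration magnitude and mean unsigned
#' heading-change rate, averaged over agents and frames. Noisy, jostling
#' trajectories score high on both; straight constant-velocity motion scores
#' zero.
#'
#' @param traj a [trajectory()].
#' @param min_speed headings are only differenced between frames where both
#'   speeds exceed this floor (m/s).
#' @return list with `mean_accel` (m/s^2) and `mean_heading_rate` (rad/s).
#' @export
smoothness <- function(traj, min_speed = 0.05) {
  stopifnot(inherits(traj, "ped_trajectory"))
  M <- traj_matrices(traj)
  if (length(M$t) < 3) stop("need at least 3 frames")
  dtv <- diff(M$t)
  acc <- c()
  head_rate <- c()
  for (ai in seq_along(M$ids)) {
    pres <- which(!is.na(M$vx[, ai]))
    if (length(pres) < 3) next
    # restrict to contiguous presence
    vx <- M$vx[pres, ai]; vy <- M$vy[pres, ai]
    dts <- M$t[pres[-1]] - M$t[pres[-length(pres)]]
    ax <- diff(vx) / dts
    ay <- diff(vy) / dts
    acc <- c(acc, sqrt(ax^2 + ay^2))
    spd <- sqrt(vx^2 + vy^2)
    th <- atan2(vy, vx)
    dth <- diff(th)
    dth <- atan2(sin(dth), cos(dth))  # wrap to (-pi, pi]
    ok <- spd[-1] > min_speed & spd[-length(spd)] > min_speed
    head_rate <- c(head_rate, abs(dth[ok]) / dts[ok])
  }
  list(mean_accel = if (length(acc)) mean(acc) else 0,
       mean_heading_rate = if (length(head_rate)) mean(head_rate) else 0)
}

#' Crowd density field for one frame
#'
#' Gaussian kernel density of agent centers on a regular grid; each agent
#' contributes unit mass, so values are in people/m^2.
#'
#' @param traj a [trajectory()].
#' @param frame frame time (must match a recorded frame; the nearest frame
#'   is used with a warning if no exact match).
#' @param grid list with `xlim`, `ylim`, `cell` (m).
#' @param bandwidth kernel width (m).
#' @return Numeric matrix of densities with attributes `x`, `y` (cell-center
#'   coordinates) and `max` (the maximum cell value).
#' @export
density_field <- function(traj, frame, grid, bandwidth = 0.6) {
  stopifnot(inherits(traj, "ped_trajectory"))
  d <- traj$data
  tsel <- unique(d$t)
  if (!frame %in% tsel) {
    frame2 <- tsel[which.min(abs(tsel - frame))]
    warning("frame ", frame, " not recorded; using nearest frame ", frame2)
    frame <- frame2
  }
  pts <- d[d$t == frame, c("x", "y")]
  cx <- seq(grid$xlim[1] + grid$cell / 2, grid$xlim[2], by = grid$cell)
  cy <- seq(grid$ylim[1] + grid$cell / 2, grid$ylim[2], by = grid$cell)
  f <- matrix(0, length(cx), length(cy))
  pref <- 1 / (2 * pi * bandwidth^2)
  for (k in seq_len(nrow(pts))) {
    dx2 <- (cx - pts$x[k])^2
    dy2 <- (cy - pts$y[k])^2
    f <- f + pref * exp(-outer(dx2, dy2, "+") / (2 * bandwidth^2))
  }
  attr(f, "x") <- cx
  attr(f, "y") <- cy
  attr(f, "max") <- if (length(f)) max(f) else 0
  f
}
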