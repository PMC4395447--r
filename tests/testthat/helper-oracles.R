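# Independent brute-force oracles used to pin down expected values.

# Reachability + weight-sum free-space field, plain R (independent of the
# package's implementation): 4-connected flood fill from each free cell
# restricted to the kernel support; out-of-lattice cells count as free.
fs_field_oracle <- function(occ, kernel) {
  nx <- nrow(occ); ny <- ncol(occ)
  K <- nrow(kernel); R <- (K - 1) / 2
  fs <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (occ[i, j]) next
    visited <- matrix(FALSE, K, K)
    queue <- list(c(0, 0))
    visited[R + 1, R + 1] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        off <- cur + d
        if (any(abs(off) > R)) next
        ki <- off[1] + R + 1; kj <- off[2] + R + 1
        if (visited[ki, kj] || kernel[ki, kj] <= 0) next
        gi <- i + off[1]; gj <- j + off[2]
        occupied <- gi >= 1 && gi <= nx && gj >= 1 && gj <= ny && occ[gi, gj]
        if (occupied) next
        visited[ki, kj] <- TRUE
        queue[[length(queue) + 1]] <- off
      }
    }
    # column-major sum over the reachable stencil cells
    fs[i, j] <- sum(kernel[visited])
  }
  fs
}

# Dense velocity-space sampling oracle for the ORCA linear program, with a
# local refinement stage so the returned optimum is accurate to ~1e-4 m/s.
# lines: m x 4 (px, py, dx, dy); permitted side: det(d, p - v) <= 0.
orca_lp_oracle <- function(vpref, lines, max_speed, n1 = 1000, n2 = 201) {
  viol <- function(vx, vy) {
    worst <- rep(-Inf, length(vx))
    if (nrow(lines)) {
      for (k in seq_len(nrow(lines))) {
        v <- lines[k, 3] * (lines[k, 2] - vy) - lines[k, 4] * (lines[k, 1] - vx)
        worst <- pmax(worst, v)
      }
    }
    worst
  }
  grid_best <- function(cx, cy, half, n) {
    gx <- seq(cx - half, cx + half, length.out = n)
    gy <- seq(cy - half, cy + half, length.out = n)
    g <- expand.grid(vx = gx, vy = gy)
    keep <- g$vx^2 + g$vy^2 <= max_speed^2
    g <- g[keep, ]
    if (!nrow(g)) return(NULL)
    w <- viol(g$vx, g$vy)
    feas <- w <= 1e-9
    if (!any(feas)) return(list(feasible = FALSE, g = g, w = w))
    gf <- g[feas, ]
    d2 <- (gf$vx - vpref[1])^2 + (gf$vy - vpref[2])^2
    i <- which.min(d2)
    list(feasible = TRUE, v = c(gf$vx[i], gf$vy[i]), dist = sqrt(d2[i]))
  }
  s1 <- grid_best(0, 0, max_speed, n1)
  if (is.null(s1) || !isTRUE(s1$feasible)) return(list(feasible = FALSE))
  h1 <- 2 * max_speed / (n1 - 1)
  s2 <- grid_best(s1$v[1], s1$v[2], 3 * h1, n2)
  if (isTRUE(s2$feasible)) s2 else s1
}

# min-max-violation oracle for the infeasible case (no obstacle lines)
orca_lp3_oracle <- function(lines, max_speed, n1 = 800, n2 = 201) {
  viol <- function(vx, vy) {
    worst <- rep(-Inf, length(vx))
    for (k in seq_len(nrow(lines))) {
      v <- lines[k, 3] * (lines[k, 2] - vy) - lines[k, 4] * (lines[k, 1] - vx)
      worst <- pmax(worst, v)
    }
    worst
  }
  stage <- function(cx, cy, half, n) {
    gx <- seq(cx - half, cx + half, length.out = n)
    gy <- seq(cy - half, cy + half, length.out = n)
    g <- expand.grid(vx = gx, vy = gy)
    g <- g[g$vx^2 + g$vy^2 <= max_speed^2, ]
    w <- viol(g$vx, g$vy)
    i <- which.min(w)
    list(v = c(g$vx[i], g$vy[i]), w = w[i])
  }
  s1 <- stage(0, 0, max_speed, n1)
  h1 <- 2 * max_speed / (n1 - 1)
  s2 <- stage(s1$v[1], s1$v[2], 3 * h1, n2)
  if (s2$w <= s1$w) s2 else s1
}

# dense temporal sampling oracle for interval penetration
interval_penetration_oracle <- function(p_i0, p_i1, p_j0, p_j1, r_i, r_j,
                                        n = 1e4) {
  s <- seq(0, 1, length.out = n + 1)
  dx <- (p_j0[1] + s * (p_j1[1] - p_j0[1])) - (p_i0[1] + s * (p_i1[1] - p_i0[1]))
  dy <- (p_j0[2] + s * (p_j1[2] - p_j0[2])) - (p_i0[2] + s * (p_i1[2] - p_i0[2]))
  max(0, r_i + r_j - min(sqrt(dx^2 + dy^2)))
}

# hand-built constant-velocity trajectory data frame
make_traj <- function(specs, times, r = 0.2) {
  rows <- do.call(rbind, lapply(specs, function(s) {
    data.frame(t = times, agent_id = s$id,
               x = s$p0[1] + s$v[1] * times, y = s$p0[2] + s$v[2] * times,
               vx = s$v[1], vy = s$v[2])
  }))
  trajectory(rows, agents = data.frame(
    agent_id = vapply(specs, function(s) s$id, numeric(1)), r = r, w = 0.48))
}

# small bidirectional corridor runs used by several tests
small_corridor <- function(density = 1.0, seed = 1) {
  build_corridor(width = 3.6, length = 10, bidirectional = TRUE,
                 initial_density = density, seed = seed)
}
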