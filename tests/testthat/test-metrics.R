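test_that("FD sampling recovers the closed form for a lone constant-speed transit", {
  times <- seq(0, 10, by = 0.125)
  traj <- make_traj(list(list(id = 1, p0 = c(0, 1), v = c(1, 0))), times)
  region <- list(xmin = 4, xmax = 6, ymin = 0, ymax = 2, axis = "x")
  fd <- fd_samples(traj, region)
  expect_equal(nrow(fd), 1L)
  expect_equal(fd$speed, 1.0, tolerance = 1e-9)
  expect_equal(fd$density, 1 / 4, tolerance = 1e-9)  # one agent in 4 m^2
  expect_equal(fd$t_out - fd$t_in, 2.0, tolerance = 1e-9)

  # an agent that turns back inside the region yields no sample
  turn <- data.frame(t = times, agent_id = 1,
                     x = 5 - abs(times - 5), y = 1, vx = sign(5 - times),
                     vy = 0)
  expect_equal(nrow(fd_samples(trajectory(turn), region)), 0L)

  # empty trajectory: no samples
  empty_df <- data.frame(t = numeric(0), agent_id = integer(0),
                         x = numeric(0), y = numeric(0), vx = numeric(0),
                         vy = numeric(0))
  expect_equal(nrow(fd_samples(trajectory(empty_df), region)), 0L)
})

test_that("FD densities match the piecewise-constant occupancy integral for staggered transits", {
  times <- seq(0, 12, by = 0.25)
  traj <- make_traj(list(list(id = 1, p0 = c(0, 1), v = c(1, 0)),
                         list(id = 2, p0 = c(-2, 1), v = c(1, 0))), times)
  region <- list(xmin = 4, xmax = 6, ymin = 0, ymax = 2, axis = "x")
  fd <- fd_samples(traj, region)
  expect_equal(nrow(fd), 2L)
  f1 <- fd[fd$agent_id == 1, ]
  # agent 1 occupies [4,6] alone over t in [4, 6]; agent 2 enters at t = 6:
  # during agent 1's transit the occupancy is 1 everywhere except the final
  # instant, so its mean density is 1/area
  expect_equal(f1$density, 0.25, tolerance = 1e-6)
  # agent 2's transit [6, 8]: occupancy 1 (agent 1 leaves as it enters)
  f2 <- fd[fd$agent_id == 2, ]
  expect_equal(f2$speed, 1.0, tolerance = 1e-9)

  # overlapping transit: shift agent 2 to enter mid-transit of agent 1
  traj3 <- make_traj(list(list(id = 1, p0 = c(0, 1), v = c(1, 0)),
                          list(id = 2, p0 = c(-1, 1), v = c(1, 0))), times)
  fd3 <- fd_samples(traj3, region)
  g1 <- fd3[fd3$agent_id == 1, ]
  # hand integral: occupancy 1 on [4,5), 2 on [5,6) -> mean 1.5/area
  expect_equal(g1$density, 1.5 / 4, tolerance = 0.01)
})

test_that("interval penetration matches static geometry and a dense temporal oracle", {
  expect_equal(interval_penetration(c(0, 0), c(1, 0), c(5, 5), c(6, 5),
                                    0.25, 0.25), 0)
  expect_equal(interval_penetration(c(0, 0), c(0, 0), c(0.4, 0), c(0.4, 0),
                                    0.25, 0.25), 0.1, tolerance = 1e-12)

  # crossing pairs with mid-interval closest approach
  for (seed in 1:20) {
    ps <- with_seed(300 + seed, runif(8, -1, 1))
    pen <- interval_penetration(ps[1:2], ps[3:4], ps[5:6], ps[7:8], 0.3, 0.25)
    oracle <- interval_penetration_oracle(ps[1:2], ps[3:4], ps[5:6], ps[7:8],
                                          0.3, 0.25)
    expect_lt(abs(pen - oracle), 1e-6)
  }
})

test_that("collision score normalizes the stated way and is zero iff no overlap", {
  times <- seq(0, 5, by = 0.5)
  # ten agents far apart: collision-free
  specs <- lapply(1:10, function(k) list(id = k, p0 = c(5 * k, 0), v = c(0.5, 0)))
  cs0 <- collision_score(make_traj(specs, times, r = 0.25))
  expect_identical(cs0$score, 0)

  # one statically overlapping pair (depth 0.1) among 10 agents
  specs[[2]]$p0 <- specs[[1]]$p0 + c(0.4, 0)
  cs <- collision_score(make_traj(specs, times, r = 0.25))
  expect_equal(cs$score, 0.1 / 10, tolerance = 1e-12)
  expect_equal(collision_score(make_traj(specs, times, r = 0.25),
                               normalization = "per_pair_interval")$score,
               0.1 / 45, tolerance = 1e-12)

  # rigid motion leaves the score unchanged
  phi <- 0.9; Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  specs_rot <- lapply(specs, function(s) {
    list(id = s$id, p0 = as.numeric(Rm %*% s$p0) + c(3, -7),
         v = as.numeric(Rm %*% s$v))
  })
  expect_equal(collision_score(make_traj(specs_rot, times, r = 0.25))$score,
               cs$score, tolerance = 1e-12)

  # refining the frame rate changes the score of a smooth pass-by only mildly
  cross <- function(dt) {
    tt <- seq(0, 8, by = dt)
    make_traj(list(list(id = 1, p0 = c(-2, 0.18), v = c(0.5, 0)),
                   list(id = 2, p0 = c(2, -0.18), v = c(-0.5, 0))), tt,
              r = 0.25)
  }
  s1 <- collision_score(cross(0.03125))$score
  s2 <- collision_score(cross(0.015625))$score
  expect_lt(abs(s2 - s1) / s1, 0.05)
})

test_that("smoothness vanishes for straight motion and matches circular closed forms", {
  times <- seq(0, 5, by = 0.1)
  straight <- make_traj(list(list(id = 1, p0 = c(0, 0), v = c(1.2, 0))), times)
  sm <- smoothness(straight)
  expect_equal(sm$mean_accel, 0)
  expect_equal(sm$mean_heading_rate, 0)

  # circular path radius R at speed v: |a| = v^2/R, heading rate v/R
  R <- 3; v <- 1.2; om <- v / R
  circ <- data.frame(t = times, agent_id = 1,
                     x = R * cos(om * times), y = R * sin(om * times),
                     vx = -v * sin(om * times), vy = v * cos(om * times))
  smc <- smoothness(trajectory(circ))
  expect_equal(smc$mean_accel, v^2 / R, tolerance = 0.01)
  expect_equal(smc$mean_heading_rate, v / R, tolerance = 0.01)

  # a zig-zag path is strictly rougher than its straightened version
  zig <- data.frame(t = times, agent_id = 1, x = 1.2 * times,
                    y = 0.3 * (round(times) %% 2),
                    vx = 1.2, vy = c(diff(0.3 * (round(times) %% 2)), 0) / 0.1)
  smz <- smoothness(trajectory(zig))
  expect_gt(smz$mean_accel, sm$mean_accel)
})

test_that("density fields integrate to the crowd size and superpose", {
  times <- c(0, 1)
  traj <- make_traj(list(list(id = 1, p0 = c(5, 5), v = c(0, 0))), times)
  grid <- list(xlim = c(0, 10), ylim = c(0, 10), cell = 0.2)
  f1 <- density_field(traj, 0, grid, bandwidth = 0.5)
  expect_equal(sum(f1) * 0.2^2, 1, tolerance = 0.01)  # unit mass per agent
  expect_equal(attr(f1, "max"), max(f1))

  traj2 <- make_traj(list(list(id = 1, p0 = c(5, 5), v = c(0, 0)),
                          list(id = 2, p0 = c(5, 5), v = c(0, 0))), times)
  f2 <- density_field(traj2, 0, grid, bandwidth = 0.5)
  expect_equal(attr(f2, "max"), 2 * attr(f1, "max"), tolerance = 1e-9)

  # empty frame: zero field
  empty <- trajectory(data.frame(t = c(0, 1), agent_id = c(1, 1),
                                 x = c(50, 50), y = 0, vx = 0, vy = 0))
  f0 <- density_field(empty, 0, grid, bandwidth = 0.5)
  expect_lt(max(f0), 1e-8)  # the only agent is far outside the grid
})
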