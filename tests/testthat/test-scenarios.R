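test_that("corridor seeding places the expected number of agents without overlap", {
  sc <- build_corridor(3.6, 20, TRUE, initial_density = 0.5, seed = 1)
  expect_equal(nrow(sc$agents), 36L)  # ceiling(0.5 * 3.6 * 20)
  expect_equal(sum(sc$agents$dir == 1), sum(sc$agents$dir == -1))

  # top of the experimental density range still places cleanly
  sc2 <- build_corridor(3.6, 20, TRUE, initial_density = 2.5, seed = 2)
  expect_equal(nrow(sc2$agents), 180L)
  r <- sc2$defaults$r
  dx <- outer(sc2$agents$x, sc2$agents$x, "-")
  dx <- dx - 20 * round(dx / 20)  # periodic axis
  dy <- outer(sc2$agents$y, sc2$agents$y, "-")
  dmin <- sqrt(dx^2 + dy^2)
  diag(dmin) <- Inf
  expect_gt(min(dmin), 2 * r)
  expect_true(all(sc2$agents$y > r & sc2$agents$y < 3.6 - r))

  # empty corridor: no agents, metrics yield no samples
  sc0 <- build_corridor(3.6, 20, TRUE, initial_density = 0, seed = 1)
  expect_equal(nrow(sc0$agents), 0L)

  # absurd density cannot be placed
  expect_error(build_corridor(3.6, 20, TRUE, initial_density = 8, seed = 1),
               "placement failed")

  # builders are bit-for-bit reproducible
  expect_identical(build_corridor(seed = 5)$agents,
                   build_corridor(seed = 5)$agents)
})

test_that("periodic corridor conserves agents and the open corridor spawns at the inflow rate", {
  sc <- small_corridor(density = 1.0, seed = 3)
  traj <- simulate_crowd(sc, simulation_config(duration = 4, seed = 3))
  counts <- table(traj$data$t)
  expect_true(all(counts == nrow(sc$agents)))
  expect_true(all(traj$data$x >= 0 & traj$data$x < 10))

  scu <- build_corridor(3.6, 20, bidirectional = FALSE, inflow_rate = 2,
                        seed = 4)
  tru <- simulate_crowd(scu, simulation_config(duration = 20, seed = 4))
  n_spawned <- nrow(tru$agents)
  expect_gt(n_spawned, 20)   # ~40 expected at 2/s over 20 s
  expect_lt(n_spawned, 70)
})

test_that("hourglass agents funnel through the passage and traverse when alone", {
  sc <- build_hourglass(5, seed = 1)
  expect_equal(nrow(sc$agents), 5L)
  cfg <- simulation_config(duration = 45, seed = 1)
  traj <- simulate_crowd(sc, cfg)
  last_x <- tapply(traj$data$x, traj$data$agent_id, max)
  expect_true(all(last_x > 2))  # everyone made it past the narrow passage

  # a single agent traverses without deviating from the passage line
  sc1 <- build_hourglass(1, seed = 2)
  tr1 <- simulate_crowd(sc1, simulation_config(duration = 40, seed = 2))
  mid <- tr1$data[abs(tr1$data$x) < 1, ]
  expect_gt(nrow(mid), 0)
  expect_true(all(abs(mid$y) < 0.6))
})

test_that("kiosk agents dwell at the kiosk for the configured wait time", {
  sc <- build_kiosk(2, wait_time = 6, seed = 1)
  # opposite spawn angles give a symmetric crossing
  cfg <- simulation_config(duration = 40, seed = 1)
  traj <- simulate_crowd(sc, cfg)
  d1 <- traj$data[traj$data$agent_id == 1, ]
  near <- d1[sqrt(d1$x^2 + d1$y^2) < 1.6, ]
  expect_gte(max(near$t) - min(near$t), 6)  # dwelled at least wait_time

  # wait_time = 0 passes through without holding
  sc0 <- build_kiosk(1, wait_time = 0, seed = 1)
  tr0 <- simulate_crowd(sc0, simulation_config(duration = 30, seed = 1))
  d0 <- tr0$data[tr0$data$agent_id == 1, ]
  near0 <- d0[sqrt(d0$x^2 + d0$y^2) < 1.6, ]
  expect_lt(max(near0$t) - min(near0$t), 4)
})

test_that("waypoint preferred velocities aim, advance and expire", {
  a <- agent_state(1, c(0, 0), c(10, 0), pref_speed = 1.3)
  wps <- matrix(c(5, 0, 5, 5), ncol = 2, byrow = TRUE)
  v <- preferred_velocity(a, wps)
  expect_equal(v[1:2], c(1.3, 0), ignore_attr = TRUE)
  expect_equal(attr(v, "wp_index"), 1L)

  # within capture radius of the first waypoint: advance and turn the corner
  a2 <- agent_state(1, c(5, 0.1), c(10, 0), pref_speed = 1.3)
  a2$wp_index <- 1L
  v2 <- preferred_velocity(a2, wps)
  expect_equal(attr(v2, "wp_index"), 2L)
  expect_gt(v2[2], 1.2)  # now heading up toward (5, 5)

  # all waypoints exhausted: zero preferred velocity
  a3 <- agent_state(1, c(5, 5), c(5, 5), pref_speed = 1.3)
  a3$wp_index <- 2L
  v3 <- preferred_velocity(a3, wps)
  expect_equal(v3[1:2], c(0, 0), ignore_attr = TRUE)
})
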