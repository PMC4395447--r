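test_that("social-force driving term relaxes toward the preferred velocity", {
  a <- agent_state(1, c(0, 0), c(10, 0), pref_speed = 1.3, v_c = c(1.3, 0))
  expect_equal(sf_acceleration(a, c(1.3, 0)), c(0, 0))

  # from rest, the isolated driving-force ODE has the closed form
  # v(t) = v0 (1 - exp(-t / tau_H)); integrate the acceleration numerically
  p <- sf_params()
  ode_rhs <- function(t, y, parms) {
    ag <- agent_state(1, y[1:2], c(100, 0), pref_speed = 1.3, v_c = y[3:4])
    acc <- sf_acceleration(ag, c(1.3, 0), params = p)
    list(c(y[3:4], acc))
  }
  sol <- deSolve::ode(c(0, 0, 0, 0), seq(0, 2, by = 0.1), ode_rhs, NULL)
  expect_equal(sol[, 4], 1.3 * (1 - exp(-sol[, 1] / p$tau_H)),
               tolerance = 1e-5)

  # two agents exactly touching and at rest: the driving term vanishes and
  # the exponential repulsion magnitude equals A
  a0 <- agent_state(1, c(0, 0), c(10, 0), pref_speed = 1.3, v_c = c(0, 0))
  b <- agent_state(2, c(2 * a0$r, 0), c(10, 0), pref_speed = 1.3)
  nb <- data.frame(x = b$p[1], y = b$p[2], vx = 0, vy = 0, r = b$r)
  acc <- sf_acceleration(a0, c(0, 0), neighbors = nb, params = p)
  expect_equal(acc, c(-p$A / a0$mass, 0), tolerance = 1e-12)
})

test_that("social-force stepping integrates consistently and clamps speed", {
  # zero acceleration: uniform motion
  st <- sf_step(matrix(c(0, 0), 1, 2), matrix(c(1, 0), 1, 2),
                matrix(c(1, 0), 1, 2), 0.2, 80, 2, 0.1)
  expect_equal(st$pos, matrix(c(0.1, 0), 1, 2))
  expect_equal(st$vel, matrix(c(1, 0), 1, 2))

  # Richardson check on the smooth relaxation field: halving dt halves the
  # global error of semi-implicit Euler (first-order consistency)
  relax_run <- function(dt, t_end = 1) {
    pos <- matrix(0, 1, 2); vel <- matrix(0, 1, 2)
    for (k in seq_len(round(t_end / dt))) {
      st <- sf_step(pos, vel, matrix(c(1.3, 0), 1, 2), 0.2, 80, 10, dt)
      pos <- st$pos; vel <- st$vel
    }
    vel[1, 1]
  }
  exact <- 1.3 * (1 - exp(-1 / 0.5))
  e1 <- abs(relax_run(0.05) - exact)
  e2 <- abs(relax_run(0.025) - exact)
  e3 <- abs(relax_run(0.0125) - exact)
  expect_lt(e2 / e1, 0.65)
  expect_lt(e3 / e2, 0.65)

  # extreme repulsion engages the speed clamp
  pos <- matrix(c(0, 0, 0.1, 0), 2, 2, byrow = TRUE)
  st <- sf_step(pos, matrix(0, 2, 2), matrix(0, 2, 2), c(0.2, 0.2),
                c(80, 80), c(1.69, 1.69), 0.0625)
  expect_equal(sqrt(rowSums(st$vel^2)), c(1.69, 1.69), tolerance = 1e-12)
})

test_that("ORCA half-planes bind only threatening neighbors and mirror symmetric pairs", {
  dt <- 0.0625
  # far-away agent: preferred velocity remains permitted
  ai <- agent_state(1, c(0, 0), c(50, 0), pref_speed = 1.3, v_c = c(1.3, 0))
  aj <- agent_state(2, c(30, 0), c(-5, 0), pref_speed = 1.3, v_c = c(-1.3, 0))
  hp <- orca_halfplane(ai, aj, tau_O = 2, dt = dt)
  slack <- sum((ai$v0 - hp$point) * hp$normal)
  expect_gte(slack, 0)

  # symmetric head-on pair: the two half-planes are mirror images in x
  bi <- agent_state(1, c(0, 0), c(10, 0), pref_speed = 1.3, v_c = c(1.3, 0))
  bj <- agent_state(2, c(4, 0), c(-10, 0), pref_speed = 1.3, v_c = c(-1.3, 0))
  h1 <- orca_halfplane(bi, bj, 2, dt)
  h2 <- orca_halfplane(bj, bi, 2, dt)
  expect_equal(h1$point, -h2$point, tolerance = 1e-12)
  expect_equal(h1$normal, -h2$normal, tolerance = 1e-12)

  # identical positions are rejected
  expect_error(orca_halfplane(bi, bi), "identical")

  # overlapping disks: resolved over dt, penetration decreases next step
  ci <- agent_state(1, c(0, 0), c(10, 0), pref_speed = 1.3, v_c = c(0, 0),
                    r = 0.25)
  cj <- agent_state(2, c(0.4, 0), c(-10, 0), pref_speed = 1.3, v_c = c(0, 0),
                    r = 0.25)
  hi <- orca_halfplane(ci, cj, 2, dt)
  hj <- orca_halfplane(cj, ci, 2, dt)
  expect_lt(hi$normal[1], 0)  # push i away from j along the center line
  vi <- orca_new_velocity(ci$v0, list(hi), 2.6)
  vj <- orca_new_velocity(cj$v0, list(hj), 2.6)
  d_new <- abs((cj$p[1] + vj[1] * dt) - (ci$p[1] + vi[1] * dt))
  expect_gt(d_new, 0.4)
})

test_that("the ORCA linear program matches a dense sampling oracle", {
  # empty constraint set returns the preferred velocity
  expect_equal(orca_new_velocity(c(1, 0.3), list(), 2), c(1, 0.3))

  # a single half-plane excluding v_pref: orthogonal projection onto it
  hp <- list(point = c(0.5, 0), direction = c(0, 1))  # permits v_x <= 0.5
  v <- orca_new_velocity(c(1.2, 0.4), list(hp), 3)
  expect_equal(v, c(0.5, 0.4), tolerance = 1e-9)

  # random instances with <= 6 half-planes against the sampling oracle
  n_checked <- 0
  for (seed in 1:12) {
    lines <- with_seed(100 + seed, {
      m <- sample(1:6, 1)
      ang <- runif(m, 0, 2 * pi)
      cbind(runif(m, -0.8, 0.8), runif(m, -0.8, 0.8),
            cos(ang), sin(ang))
    })
    vp <- with_seed(200 + seed, runif(2, -1.5, 1.5))
    v_lp <- orca_new_velocity(vp, lines, 2)
    oracle <- orca_lp_oracle(vp, lines, 2)
    if (!isTRUE(oracle$feasible)) next
    n_checked <- n_checked + 1
    # feasibility of the LP solution
    viol <- max(lines[, 3] * (lines[, 2] - v_lp[2]) -
                  lines[, 4] * (lines[, 1] - v_lp[1]))
    expect_lt(viol, 1e-9)
    expect_lte(sqrt(sum(v_lp^2)), 2 + 1e-9)
    # optimality within sampling accuracy (the objective is flat along the
    # active boundary, so distances compare more sharply than positions)
    expect_lt(abs(sqrt(sum((v_lp - vp)^2)) - oracle$dist), 1e-3)
  }
  expect_gte(n_checked, 6)
})

test_that("infeasible constraint sets fall back to the min-max-violation velocity", {
  # three half-planes whose permitted sides have empty intersection
  lines <- rbind(c(0, 0.3, 1, 0),    # permits y >= 0.3 (normal (0,1))
                 c(0, -0.3, -1, 0),  # permits y <= -0.3
                 c(0.5, 0, 0, 1))    # permits x <= 0.5
  v <- orca_new_velocity(c(0, 0), lines, 1.5)
  oracle <- orca_lp3_oracle(lines, 1.5)
  viol_at <- function(vv) max(lines[, 3] * (lines[, 2] - vv[2]) -
                                lines[, 4] * (lines[, 1] - vv[1]))
  expect_lt(abs(viol_at(v) - oracle$w), 2e-3)
})

test_that("symmetric encounters stay mirror-symmetric for all time", {
  dt <- 0.0625
  pos <- matrix(c(0, 0.5, 8, -0.5), 2, 2, byrow = TRUE)
  vel <- matrix(0, 2, 2)
  pref <- rbind(c(1.3, 0), c(-1.3, 0))
  for (k in 1:160) {
    vnew <- orca_velocities(pos, vel, pref, c(0.2, 0.2), c(1.69, 1.69),
                            2, dt, safety_margin = 0)
    pos <- pos + vnew * dt
    vel <- vnew
    # agent 2 is agent 1 reflected through the midpoint (4, 0)
    expect_equal(pos[2, ], c(8, 0) - pos[1, ], tolerance = 1e-9)
  }
  # they actually passed each other without touching
  expect_gt(pos[1, 1], 6)
  d <- sqrt(sum((pos[1, ] - pos[2, ])^2))
  expect_gt(d, 0.4)
})
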