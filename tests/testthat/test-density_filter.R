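test_that("displacement transform preserves the forward component and stretches the lateral one", {
  expect_equal(transform_displacement(c(2, 0), c(1, 0), 2.5), c(2, 0))
  d <- transform_displacement(c(0, 1), c(1, 0), 2.5)
  expect_equal(sqrt(sum(d^2)), 2.5)
  expect_equal(transform_displacement(c(1, 1), c(1, 0), 2.5), c(1, 2.5))
  expect_error(transform_displacement(c(1, 1), c(1, 1), 2.5), "unit")
})

test_that("perceived density sums anisotropic Gaussian neighbor contributions", {
  expect_equal(agent_density(c(0, 0), c(1, 0), NULL), 0)
  # one neighbor at zero transformed displacement, sigma = 1
  expect_equal(agent_density(c(0, 0), c(1, 0), matrix(c(0, 0), 1, 2), sigma = 1),
               1 / (2 * pi), tolerance = 1e-12)
  # additivity
  nb <- matrix(c(0.5, 0.2, -0.3, 0.8), 2, 2, byrow = TRUE)
  single <- vapply(1:2, function(k)
    agent_density(c(0, 0), c(1, 0), nb[k, , drop = FALSE]), numeric(1))
  expect_equal(agent_density(c(0, 0), c(1, 0), nb), sum(single))
  # printed normalization differs by a factor sigma
  expect_equal(agent_density(c(0, 0), c(1, 0), nb, sigma = 0.7,
                             density_norm_mode = "as_printed"),
               0.7 * agent_density(c(0, 0), c(1, 0), nb, sigma = 0.7))
  expect_error(agent_density(c(0, 0), c(1, 0), nb, sigma = -1), "sigma")
})

test_that("free-space scaling inflates density and rejects degenerate FS", {
  expect_equal(effective_density(1, 1), 1)
  expect_equal(effective_density(1, 0.5), 2)
  expect_equal(effective_density(0, 0.3), 0)
  expect_error(effective_density(1, 0), "fs")
})

test_that("natural speed follows the stride relation and saturates at the preferred speed", {
  expect_equal(natural_speed(1, pref_speed = 2, alpha = 1, H = 1, beta = 0), 1)
  expect_equal(natural_speed(0, pref_speed = 1.3), 0)
  expect_equal(natural_speed(1e6, pref_speed = 1.3), 1.3)
  expect_equal(natural_speed(Inf, pref_speed = 1.3), 1.3)
  expect_error(natural_speed(-1, 1.3), "non-negative")
  # monotone nondecreasing, saturation threshold alpha*H*(1+beta)*sqrt(v0)
  S <- seq(0, 10, by = 0.05)
  v <- natural_speed(S, pref_speed = 1.3, alpha = 1.57, H = 1, beta = 0.9)
  expect_true(all(diff(v) >= 0))
  thr <- 1.57 * 1 * 1.9 * sqrt(1.3)
  expect_equal(natural_speed(thr, 1.3, 1.57, 1, 0.9), 1.3)
  expect_lt(natural_speed(thr - 0.01, 1.3, 1.57, 1, 0.9), 1.3)
})

test_that("the width-based density mapping reproduces the 1 people/m <-> 2.08 people/m^2 equivalence", {
  rho2d <- density_1d_to_2d(1, w = 0.48)
  expect_equal(round(rho2d, 2), 2.08)
  expect_equal(space_from_density(rho2d, 0.48, "seyfried"), 1.0,
               tolerance = 1e-12)
  expect_equal(space_from_density(1, 0.48, "eq10"), 0.48)
  expect_identical(space_from_density(0, 0.48), Inf)
  expect_equal(natural_speed(space_from_density(0, 0.48), 1.3), 1.3)
})

test_that("corrected velocity composes density, free space and stride relation", {
  cfg <- filter_config()
  a <- agent_state(1, c(0, 0), c(10, 0), pref_speed = 1.3)

  # open space, no neighbors: full preferred speed along the probe direction
  s0 <- corrected_velocity(0, a, cfg, NULL, NULL)
  expect_equal(s0$v_fd, c(1.3, 0))

  # dense wall of neighbors: near-zero speed, direction preserved
  nb <- with_seed(21, cbind(runif(80, -0.5, 0.5), runif(80, -0.5, 0.5)))
  sh <- corrected_velocity(0, a, cfg, NULL, nb)
  expect_lt(sqrt(sum(sh$v_fd^2)), 0.05)
  expect_gt(sh$v_fd[1], 0)

  # mid case equals composing the exported operations by hand
  nb2 <- matrix(c(1.2, 0.3, 0.8, -0.9, -0.5, 0.4), ncol = 2, byrow = TRUE)
  th <- 0.3
  s <- corrected_velocity(th, a, cfg, NULL, nb2)
  vh <- c(cos(th), sin(th)) * 1  # v0 along +x
  rhoA <- agent_density(a$p, vh, nb2, cfg$sigma, cfg$lateral_scale,
                        cfg$density_norm_mode)
  V <- natural_speed(space_from_density(effective_density(rhoA, 1), a$w,
                                        cfg$space_mapping_mode),
                     a$pref_speed, a$alpha, a$H, a$beta)
  expect_equal(s$v_fd, vh * V, tolerance = 1e-12)
})

test_that("arc optimization prefers the direction with best progress and breaks ties inward", {
  cfg <- filter_config()
  a <- agent_state(1, c(0, 0), c(10, 0), pref_speed = 1.3)

  # uniform zero density: straight ahead wins exactly
  expect_equal(select_optimal(a, cfg, NULL, NULL), a$v0)

  # dense cluster straight ahead, clear at positive angles: a positive-theta
  # sample wins; verify against exhaustive evaluation of the cost
  nb <- with_seed(22, cbind(runif(40, 0.2, 1.6), runif(40, -0.45, 0.05)))
  v <- select_optimal(a, cfg, NULL, nb)
  expect_gt(atan2(v[2], v[1]), 0.01)
  m <- (cfg$n_samples - 1) / 2
  thetas <- seq(-cfg$theta_max, cfg$theta_max, length.out = cfg$n_samples)
  costs <- vapply(thetas, function(th)
    corrected_velocity(th, a, cfg, NULL, nb)$cost, numeric(1))
  best <- corrected_velocity(thetas[which.min(costs)], a, cfg, NULL, nb)$v_fd
  expect_equal(v, best, tolerance = 1e-12)

  # perfectly symmetric blockage: tie resolved toward smaller |theta|, then
  # the negative offset
  nb_sym <- matrix(c(1, 0.4, 1, -0.4, 1, 0), ncol = 2, byrow = TRUE)
  vsym <- select_optimal(a, cfg, NULL, nb_sym)
  ang <- atan2(vsym[2], vsym[1])
  cost_at <- function(th) corrected_velocity(th, a, cfg, NULL, nb_sym)$cost
  dth <- cfg$theta_max / m
  if (abs(cost_at(dth) - cost_at(-dth)) < 1e-12 && cost_at(dth) < cost_at(0)) {
    expect_equal(ang, -dth, tolerance = 1e-9)
  }

  # zero preferred speed: no sampling, zero output
  still <- agent_state(2, c(0, 0), c(0, 0), pref_speed = 1.3)
  expect_equal(select_optimal(still, cfg, NULL, nb), c(0, 0))
})

test_that("filter invariants: speed bound, pass-through, frontal weighting, rotation equivariance", {
  cfg <- filter_config()
  a <- agent_state(1, c(0, 0), c(8, 3), pref_speed = 1.25)

  # speed never exceeds the preferred speed (random neighbor clouds)
  for (seed in 1:5) {
    nb <- with_seed(seed, cbind(runif(30, -2, 2), runif(30, -2, 2)))
    v <- select_optimal(a, cfg, NULL, nb)
    expect_lte(sqrt(sum(v^2)), a$pref_speed + 1e-12)
  }

  # pass-through with no neighbors and no obstacles
  expect_equal(select_optimal(a, cfg, NULL, NULL), a$v0)

  # a neighbor dead ahead contributes strictly more than one abeam
  ahead <- agent_density(c(0, 0), c(1, 0), matrix(c(1, 0), 1, 2))
  abeam <- agent_density(c(0, 0), c(1, 0), matrix(c(0, 1), 1, 2))
  expect_gt(ahead, abeam)

  # rotation equivariance of the whole configuration
  phi <- 0.7
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  nb <- with_seed(2, cbind(runif(20, -2, 2), runif(20, -2, 2)))
  v1 <- select_optimal(a, cfg, NULL, nb)
  a_rot <- agent_state(1, as.numeric(Rm %*% a$p), as.numeric(Rm %*% a$goal),
                       pref_speed = 1.25)
  v2 <- select_optimal(a_rot, cfg, NULL, t(Rm %*% t(nb)))
  expect_equal(as.numeric(Rm %*% v1), v2, tolerance = 1e-9)

  # pushing every neighbor farther out never slows the chosen velocity
  for (seed in 1:5) {
    nb <- with_seed(10 + seed, cbind(runif(25, -3, 3), runif(25, -3, 3)))
    v_near <- select_optimal(a, cfg, NULL, nb)
    v_far <- select_optimal(a, cfg, NULL, nb * 1.5)
    expect_gte(sqrt(sum(v_far^2)), sqrt(sum(v_near^2)) - 1e-12)
  }
})

test_that("the batched filter agrees with the per-agent composition", {
  cfg <- filter_config()
  sq <- matrix(c(3, 1, 5, 1, 5, 3, 3, 3), ncol = 2, byrow = TRUE)
  field <- obstacle_field(list(sq), c(-2, 10, -2, 6), 0.1, 1.0)
  n <- 12
  pos <- with_seed(4, cbind(runif(n, -1, 3), runif(n, -1, 5)))
  goal <- cbind(rep(9, n), pos[, 2])
  pref <- with_seed(5, runif(n, 1.1, 1.5))
  v0 <- (goal - pos) / sqrt(rowSums((goal - pos)^2)) * pref
  out <- pedflow:::filter_batch(pos, v0, pref, goal, rep(0.48, n),
                                rep(1.57, n), rep(1.9, n), rep(1, n),
                                cfg, field)
  for (i in seq_len(n)) {
    d2 <- rowSums((pos - matrix(pos[i, ], n, 2, byrow = TRUE))^2)
    nb <- pos[d2 > 0 & d2 < cfg$neighbor_radius^2, , drop = FALSE]
    a <- agent_state(i, pos[i, ], goal[i, ], w = 0.48, pref_speed = pref[i],
                     alpha = 1.57, beta = 1.9, H = 1)
    expect_equal(out[i, ], select_optimal(a, cfg, field, nb),
                 tolerance = 1e-10)
  }
})
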