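two_body <- function(gap_factor, r = 5e-7, group = test_groups()$HET) {
  # two spheres along x at centre distance gap_factor * 2r, high above walls
  make_particles(group, rbind(c(5e-5, 5e-5, 5e-5),
                              c(5e-5 + gap_factor * 2 * r, 5e-5, 5e-5)),
                 2 * r)
}

pair_force <- function(particles, params, groups = test_groups(),
                       domain = test_domain()) {
  nl <- build_neighbor_list(particles, domain, cutoff = 1e-5, skin = 1e-6)
  compute_forces(particles, nl, params, groups, domain)
}

test_that("Hookean contact force matches the closed form and Newton's third law", {
  prm <- ibm_force_params(Kn = 1e-3, gamma_n = 0, Ha = 0)
  # just touching: no force
  f0 <- pair_force(two_body(1), prm)
  expect_equal(max(abs(f0$F)), 0)
  # overlap 0.1 um at Kn = 1e-3: |F| = 1e-10, repulsive along x
  f1 <- pair_force(two_body(0.9), prm)
  expect_equal(f1$F[1, 1], -1e-10, tolerance = 1e-9)
  expect_equal(f1$F[2, 1], 1e-10, tolerance = 1e-9)
  expect_equal(f1$F[1, ], -f1$F[2, ])
  # virial of a repulsive pair is positive
  expect_gt(f1$virial, 0)
})

test_that("EPS adhesion matches the van der Waals closed form", {
  grp <- ibm_group("HET", 150, division_diameter = 3e-6, death_diameter = 1e-7,
                   eps = list(density = 30, yield = 0.18, shell_ratio = 1.25))
  groups <- list(HET = grp)
  prm <- ibm_force_params(Kn = 0, gamma_n = 0, Ha = 1e-20, h_floor = 1e-9)
  # R = 1 um spheres, 10 nm face separation: r_eff = 0.5 um,
  # |F| = 1e-20 * 5e-7 / (12 * 1e-16) ~ 4.1667e-10 N, attractive
  p <- make_particles(grp, rbind(c(5e-5, 5e-5, 5e-5),
                                 c(5e-5 + 2e-6 + 1e-8, 5e-5, 5e-5)), 2e-6)
  nl <- build_neighbor_list(p, test_domain(), cutoff = 1e-5, skin = 1e-6)
  f <- compute_forces(p, nl, prm, groups, test_domain())
  expect_equal(f$F[1, 1], 1e-20 * 5e-7 / (12 * 1e-16), tolerance = 1e-3)
  expect_equal(f$F[1, ], -f$F[2, ])
  # beyond the cutoff: zero
  pf <- make_particles(grp, rbind(c(2e-5, 5e-5, 5e-5),
                                  c(8e-5, 5e-5, 5e-5)), 2e-6)
  nlf <- build_neighbor_list(pf, test_domain(), cutoff = 1e-5, skin = 1e-6)
  ff <- compute_forces(pf, nlf, prm, groups, test_domain())
  expect_equal(max(abs(ff$F)), 0)
  # groups without shells feel contact only (no adhesion)
  inert <- ibm_group("ROCK", 150, division_diameter = 3e-6,
                     death_diameter = 1e-7)
  pr <- make_particles(inert, rbind(c(5e-5, 5e-5, 5e-5),
                                    c(5e-5 + 2e-6 + 1e-8, 5e-5, 5e-5)), 2e-6)
  fr <- compute_forces(pr, nl, prm, list(ROCK = inert), test_domain())
  expect_equal(max(abs(fr$F)), 0)
})

test_that("neighbour list equals the brute-force pair oracle", {
  set.seed(99)
  dom <- test_domain()
  p <- random_particles(300, dom, test_groups()$HET)
  nl <- build_neighbor_list(p, dom, cutoff = 4e-6, skin = 1e-6)
  bf <- brute_force_list(p, dom, cutoff = 4e-6, skin = 1e-6)
  expect_identical(nl$pairs, bf$pairs)
  # identical force evaluation through either list
  prm <- ibm_force_params(Kn = 1e-3, gamma_n = 1e5, Ha = 1e-20)
  f1 <- compute_forces(p, nl, prm, test_groups(), dom)
  f2 <- compute_forces(p, bf, prm, test_groups(), dom)
  expect_identical(f1$F, f2$F)
  # two far particles: empty list
  far <- make_particles(test_groups()$HET,
                        rbind(c(2e-5, 2e-5, 5e-5), c(2e-5, 2e-5, 9e-5)), 1e-6)
  expect_equal(nrow(build_neighbor_list(far, dom, cutoff = 4e-6,
                                        skin = 1e-6)$pairs), 0L)
})

test_that("periodic minimum image pairs particles across the boundary", {
  dom <- test_domain()
  p <- make_particles(test_groups()$HET,
                      rbind(c(1e-7, 5e-5, 5e-5), c(1e-4 - 1e-7, 5e-5, 5e-5)),
                      1e-6)
  nl <- build_neighbor_list(p, dom, cutoff = 2e-6, skin = 5e-7)
  expect_equal(nrow(nl$pairs), 1L)
  # and the wrapped pair overlaps, so it feels contact force
  prm <- ibm_force_params(Kn = 1e-3, Ha = 0)
  f <- compute_forces(p, nl, prm, test_groups(), dom)
  expect_gt(abs(f$F[1, 1]), 0)
  expect_equal(f$F[1, ], -f$F[2, ])
})

test_that("drag force follows the slip velocity", {
  dom <- test_domain()
  grid <- build_grid(dom, 1e-5)
  prm <- ibm_force_params()
  vel <- list(vx = array(0.01, dim = grid$n), vy = array(0, dim = grid$n),
              vz = array(0, dim = grid$n))
  p <- make_particles(test_groups()$HET, c(5e-5, 5e-5, 5e-5), 1e-6)
  # still particle in +x flow: pushed along +x
  f <- drag_force(p, vel, grid, prm)
  expect_gt(f[1, 1], 0)
  expect_equal(f[1, 2:3], c(0, 0))
  # no slip: zero drag
  p$vx <- 0.01
  expect_equal(max(abs(drag_force(p, vel, grid, prm))), 0)
  # magnitude linear in the slip for fixed beta
  p$vx <- 0.005
  f5 <- drag_force(p, vel, grid, prm)
  p$vx <- 0
  f10 <- drag_force(p, vel, grid, prm)
  expect_equal(f10[1, 1] / f5[1, 1], 2, tolerance = 1e-9)
})

test_that("velocity Verlet reproduces constant-force kinematics", {
  dom <- test_domain()
  prm <- ibm_force_params(Kn = 0, Ha = 0, viscous = 0)
  grp <- test_groups()$HET
  p <- make_particles(grp, c(5e-5, 5e-5, 5e-5), 1e-6)
  # zero force, zero velocity: nothing moves
  null_fn <- function(pp) list(F = matrix(0, nrow(pp), 3L), virial = 0)
  p0 <- verlet_step(p, null_fn, 1e-7, dom, prm)
  expect_equal(p0$x, p$x)
  # constant force: x(t) = F t^2 / (2 m) to O(dt^2)
  Fc <- 1e-12
  const_fn <- function(pp) list(F = matrix(c(Fc, 0, 0), nrow(pp), 3L,
                                           byrow = TRUE), virial = 0)
  q <- p
  q$fx <- Fc
  dt <- 1e-7; nsteps <- 200L
  for (i in seq_len(nsteps)) q <- verlet_step(q, const_fn, dt, dom, prm)
  t_tot <- nsteps * dt
  expect_equal(q$x - p$x, 0.5 * (Fc / p$mass) * t_tot^2, tolerance = 1e-6)
  # instability guard
  expect_error(verlet_step(q, const_fn, 1, dom, prm, max_disp = 1e-9),
               "instability")
})

test_that("pairwise contact conserves momentum under Verlet", {
  dom <- test_domain()
  groups <- test_groups()
  prm <- ibm_force_params(Kn = 1e-3, gamma_n = 1e5, Ha = 0, viscous = 0)
  p <- two_body(0.9)
  nl <- build_neighbor_list(p, dom)
  fn <- function(pp) compute_forces(pp, nl, prm, groups, dom)
  fe <- fn(p)
  p$fx <- fe$F[, 1]; p$fy <- fe$F[, 2]; p$fz <- fe$F[, 3]
  for (i in 1:100) p <- verlet_step(p, fn, 1e-7, dom, prm)
  m <- p$mass + p$outer_mass
  expect_equal(sum(m * p$vx), 0, tolerance = 1e-30)
  expect_equal(sum(m * p$vy), 0, tolerance = 1e-30)
})

test_that("virial pressure matches closed forms", {
  grp <- test_groups()$HET
  # single stationary particle: P = 0
  p <- make_particles(grp, c(5e-5, 5e-5, 5e-5), 1e-6)
  expect_equal(average_pressure(p, 0), 0)
  # kinetic term only: P = m v^2 / (3 V)
  p$vx <- 1e-5
  V <- pi * p$outer_diameter^3 / 6
  expect_equal(average_pressure(p, 0), p$mass * 1e-10 / (3 * V))
  # two static overlapping particles: P = r . F / (3 V) > 0
  prm <- ibm_force_params(Kn = 1e-3, gamma_n = 0, Ha = 0)
  p2 <- two_body(0.9)
  fe <- pair_force(p2, prm)
  expect_equal(average_pressure(p2, fe$virial),
               fe$virial / (3 * sum(pi * p2$outer_diameter^3 / 6)))
  expect_gt(average_pressure(p2, fe$virial), 0)
  expect_error(average_pressure(new_particles()), "empty")
})

test_that("relaxation separates overlapping spheres and then stays put", {
  dom <- test_domain()
  groups <- test_groups()
  prm <- ibm_force_params(Kn = 1e-3, gamma_n = 1e5, Ha = 0)
  # already at rest, no overlap, no adhesion: immediate exit
  p0 <- two_body(1.2)
  rx0 <- relax(p0, prm, dom, groups, dt = 1e-7)
  expect_equal(rx0$steps, 0L)
  # two overlapping spheres end at centre distance >= radius sum
  p <- two_body(0.9)
  rx <- relax(p, prm, dom, groups, dt = 1e-7, max_steps = 20000L)
  d <- sqrt(sum((as.numeric(rx$particles[1, c("x", "y", "z")]) -
                   as.numeric(rx$particles[2, c("x", "y", "z")]))^2))
  expect_gte(d, 1e-6 * (1 - 1e-3))
  # kinetic energy is damped out by the end
  expect_equal(max(abs(rx$particles$vx)), 0)
})

test_that("damped dynamics dissipates kinetic energy after the transient", {
  dom <- test_domain()
  groups <- test_groups()
  prm <- ibm_force_params(Kn = 1e-3, gamma_n = 1e6, Ha = 0, viscous = 0)
  p <- two_body(0.85)
  nl <- build_neighbor_list(p, dom)
  fn <- function(pp) compute_forces(pp, nl, prm, groups, dom)
  fe <- fn(p)
  p$fx <- fe$F[, 1]; p$fy <- fe$F[, 2]; p$fz <- fe$F[, 3]
  ke <- function(pp) sum((pp$mass + pp$outer_mass) *
                           (pp$vx^2 + pp$vy^2 + pp$vz^2)) / 2
  # elastic + damping: once in free flight KE must not grow
  kes <- numeric(300)
  for (i in seq_len(300)) { p <- verlet_step(p, fn, 1e-7, dom, prm); kes[i] <- ke(p) }
  expect_lt(kes[300], max(kes))
  expect_true(all(diff(kes[150:300]) <= 1e-25))
})
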