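test_that("mass/diameter conversions round-trip exactly", {
  d <- c(1e-6, 1.3e-6, 4e-7)
  m <- mass_from_diameter(d, 150)
  expect_equal(diameter_from_mass(m, 150), d, tolerance = 1e-12)
  # shell-free outer diameter equals the core diameter
  expect_equal(outer_diameter_from_shell(d, 0, 30), d)
  # shell mass inflates the outer diameter
  expect_true(outer_diameter_from_shell(1e-6, 1e-17, 30) > 1e-6)
})

test_that("group and particle constructors validate their invariants", {
  expect_error(ibm_group("X", 150, division_diameter = 1e-7,
                         death_diameter = 2e-7), "exceed")
  expect_error(ibm_group("X", 150, yield = 1.5), "yield")
  expect_error(ibm_group("X", -1), "positive")
  p <- make_particles(test_groups()$HET, c(1e-5, 1e-5, 5e-7), 1e-6)
  expect_s3_class(p, "ibm_particles")
  expect_equal(p$mass, 150 * pi * (1e-6)^3 / 6)
  df <- as.data.frame(p)
  df$mass <- -1
  expect_error(new_particles(df), "positive")
})

test_that("forward-Euler growth matches the one-step closed form", {
  groups <- test_groups()
  dom <- test_domain()
  p <- make_particles(groups$HET, c(1e-5, 1e-5, 5e-7), 1e-6)
  # zero growth: identity
  p$mu <- 0
  expect_equal(integrate_growth(p, groups, 900)$mass, p$mass)
  # one forward-Euler step: m (1 + mu dt)
  p$mass <- 1e-16
  p$mu <- 2.78e-5
  p2 <- integrate_growth(p, groups, 900)
  expect_equal(p2$mass, 1e-16 * (1 + 2.78e-5 * 900), tolerance = 1e-12)
  expect_equal(p2$mass, 1.02502e-16, tolerance = 1e-6)
  expect_equal(p2$diameter, diameter_from_mass(p2$mass, 150))
  # repeated decay: strictly decreasing, geometric
  p$mu <- -1e-4
  masses <- numeric(5)
  q <- p
  for (i in 1:5) { q <- integrate_growth(q, groups, 900); masses[i] <- q$mass }
  expect_true(all(diff(masses) < 0))
  expect_equal(masses[5] / masses[4], masses[2] / masses[1])
  # EPS shell accrues at (Y_EPS / Y) x gross rate
  p$mu <- 2.78e-5
  p3 <- integrate_growth(p, groups, 900)
  expect_equal(p3$outer_mass, (0.18 / 0.61) * 2.78e-5 * 1e-16 * 900)
  expect_true(p3$outer_diameter > p3$diameter)
})

test_that("division conserves mass and samples fractions in [0.4, 0.6]", {
  groups <- test_groups()
  dom <- test_domain()
  set.seed(11)
  n <- 2000L
  pos <- cbind(runif(n, 0, 1e-4), runif(n, 0, 1e-4), runif(n, 2e-6, 9e-5))
  p <- make_particles(groups$HET, pos, 1.4e-6, outer_mass = 1e-17)
  p2 <- divide_particles(p, groups, dom)
  expect_equal(nrow(p2), 2L * n)
  # exact conservation of core and shell mass
  expect_equal(sum(p2$mass), sum(p$mass), tolerance = 1e-14)
  expect_equal(sum(p2$outer_mass), sum(p$outer_mass), tolerance = 1e-14)
  # daughter-1 fraction within the stated bounds, mean near one half
  f <- p2$mass[seq_len(n)] / p$mass
  expect_true(all(f >= 0.4 & f <= 0.6))
  expect_equal(mean(f), 0.5, tolerance = 0.01)
  # daughters rest at or above the substratum
  expect_true(all(p2$z >= p2$diameter / 2 - 1e-15))
  # ids unique, new ids for daughters only
  expect_false(anyDuplicated(p2$id) > 0)
  # below the threshold nothing divides
  small <- make_particles(groups$HET, c(1e-5, 1e-5, 5e-7), 1e-6)
  expect_equal(nrow(divide_particles(small, groups, dom)), 1L)
})

test_that("daughter separation honours the distance mode", {
  groups <- test_groups()
  dom <- test_domain()
  p <- make_particles(groups$HET, c(5e-5, 5e-5, 5e-5), 1.4e-6)
  set.seed(3)
  a <- divide_particles(p, groups, dom, "radius_sum")
  d1 <- sqrt(sum((as.numeric(a[1, c("x", "y", "z")]) -
                    as.numeric(a[2, c("x", "y", "z")]))^2))
  expect_equal(d1, sum(a$diameter) / 2, tolerance = 1e-12)
  set.seed(3)
  b <- divide_particles(p, groups, dom, "diameter_sum")
  d2 <- sqrt(sum((as.numeric(b[1, c("x", "y", "z")]) -
                    as.numeric(b[2, c("x", "y", "z")]))^2))
  expect_equal(d2, sum(b$diameter), tolerance = 1e-12)
})

test_that("death classification follows the threshold and removal rules", {
  groups <- test_groups()
  grp <- groups$HET     # death at 4e-7
  mk <- function(d) make_particles(grp, c(1e-5, 1e-5, 1e-6), d)
  # at the threshold: alive (strict inequality)
  expect_equal(check_death(mk(4e-7), groups), "ALIVE")
  # just below: dead, not removed
  expect_equal(check_death(mk(2e-7), groups), "DEAD")
  # below a tenth of the threshold: removed
  expect_equal(check_death(mk(0.09 * 4e-7), groups), "REMOVE")
  # apply_death switches the group and drops removals
  p <- mk(2e-7)
  p2 <- apply_death(p, groups)
  expect_equal(p2$group, "DEAD")
  expect_equal(nrow(apply_death(mk(3e-8), groups)), 0L)
})

test_that("lysis releases dead biomass as substrate, conserving mass", {
  groups <- test_groups()
  p <- make_particles(groups$DEAD, c(1e-5, 1e-5, 1e-6), 3e-7)
  expect_equal(dead_cell_lysis_rate(p, 0), 0)
  expect_equal(dead_cell_lysis_rate(p, 1e-5), 1e-5 * p$mass)
  expect_error(dead_cell_lysis_rate(p, -1), ">= 0")
  # forward-Euler trajectory: released mass equals the biomass decrement
  dt <- 900
  released <- 0
  q <- p
  for (i in 1:50) {
    released <- released + dead_cell_lysis_rate(q, 1e-5) * dt
    q <- biofilmsim:::apply_lysis(q, groups, dt)
  }
  expect_equal(q$mass + released, p$mass, tolerance = 1e-12)
  # living particles release nothing
  h <- make_particles(groups$HET, c(1e-5, 1e-5, 1e-6), 1e-6)
  expect_equal(dead_cell_lysis_rate(h, 1e-5), 0)
})

test_that("EPS excretion is gated, bounded and mass conserving", {
  groups <- test_groups()
  dom <- test_domain()
  # below the shell-ratio threshold: no-op
  thin <- make_particles(groups$HET, c(5e-5, 5e-5, 5e-5), 1e-6,
                         outer_mass = 1e-19)
  expect_equal(nrow(eps_excrete(thin, groups, dom)), 1L)
  # thick shells excrete a U(0.4, 0.6) fraction as free EPS particles
  set.seed(21)
  n <- 2000L
  pos <- cbind(runif(n, 0, 1e-4), runif(n, 0, 1e-4), runif(n, 2e-6, 9e-5))
  shell0 <- 5e-17
  p <- make_particles(groups$HET, pos, 1e-6, outer_mass = shell0)
  expect_true(all(p$outer_diameter / p$diameter > 1.25))
  p2 <- eps_excrete(p, groups, dom)
  expect_equal(nrow(p2), 2L * n)
  eps <- p2[p2$group == "EPS", ]
  g <- eps$mass / shell0
  expect_true(all(g >= 0.4 & g <= 0.6))
  # shell mass before = EPS particle mass + residual shell
  expect_equal(sum(eps$mass) + sum(p2$outer_mass), n * shell0,
               tolerance = 1e-12)
  # EPS particles placed in contact next to their parent
  het <- p2[p2$group == "HET", ]
  expect_equal(eps$density, rep(30, n))
})
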