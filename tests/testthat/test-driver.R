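small_monod_config <- function(...) {
  base <- biofilmsim:::nitrifying_config_list()
  base$solutes <- base$solutes[c("sub", "o2")]
  base$groups <- base$groups[c("HET", "EPS", "DEAD")]
  base$groups$HET$pathways <- base$groups$HET$pathways["aerobic"]
  base$timesteps$t_end <- 3 * 900
  overrides <- list(...)
  for (k in names(overrides)) base[[k]] <- overrides[[k]]
  parse_config(base)
}

test_that("an empty process list advances time without touching state", {
  cfg <- small_monod_config(processes = list())
  groups <- biofilmsim:::config_groups(cfg)
  set.seed(1)
  p <- random_particles(5, biofilmsim:::config_domain(cfg), groups$HET)
  res <- run(cfg, list(particles = p))
  expect_equal(res$state$t, 3 * 900)
  expect_equal(res$state$particles$x, p$x)
  expect_equal(res$state$particles$mass, p$mass)
  expect_equal(nrow(res$history), 3L)
})

test_that("a single microbe in abundant nutrient doubles exponentially", {
  base <- biofilmsim:::nitrifying_config_list()
  base$solutes <- list(sub = list(diffusion = 1.6e-9, bulk = 10, influent = 10),
                       o2 = list(diffusion = 2.3e-9, bulk = 10, influent = 10,
                                 fixed_bulk = TRUE))
  base$groups <- base$groups[c("HET", "EPS", "DEAD")]
  base$groups$HET$pathways <- base$groups$HET$pathways["aerobic"]
  base$groups$HET$eps <- NULL       # core mass only, for the closed form
  base$processes <- c("growth", "division")
  base$timesteps$t_end <- 40 * 900
  cfg <- parse_config(base)
  groups <- biofilmsim:::config_groups(cfg)
  p <- make_particles(groups$HET, c(5e-5, 5e-5, 5e-7), 1e-6)
  res <- run(cfg, list(particles = p))
  h <- res$history
  # saturated Monod growth: biomass tracks (1 + mu_net dt)^k exactly
  mu_net <- 6.94e-5 - 4.63e-6
  expected <- p$mass * (1 + mu_net * 900)^seq_len(40)
  expect_equal(h$biomass_HET / expected, rep(1, 40), tolerance = 0.01)
  # particle count multiplies as the biomass doubles (~ every 3.3 h)
  expect_gte(tail(h$n_particles, 1), 6)
  expect_true(all(diff(h$n_particles) >= 0))
})

test_that("identical seed and config give bit-identical trajectories", {
  sc <- make_scenario("decay_only", seed = 5)
  r1 <- run(sc$config, sc$state)
  r2 <- run(sc$config, sc$state)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$state$particles, r2$state$particles)
})

test_that("a split-restart run equals the contiguous run step for step", {
  sc <- make_scenario("nitrifying_community", seed = 3)
  cfg <- sc$config
  full <- suppressWarnings(run(cfg, sc$state, until = 6 * 900))
  half <- suppressWarnings(run(cfg, sc$state, until = 3 * 900))
  path <- withr::local_tempfile(fileext = ".rds")
  save_restart(half$state, path)
  resumed <- suppressWarnings(run(cfg, load_restart(path), until = 6 * 900))
  expect_equal(resumed$state$particles, full$state$particles, tolerance = 1e-14)
  expect_equal(resumed$state$bulk$Sb, full$state$bulk$Sb, tolerance = 1e-14)
  expect_equal(resumed$state$fields, full$state$fields, tolerance = 1e-14)
})

test_that("stage failures name the stage and step", {
  cfg <- small_monod_config()
  groups <- biofilmsim:::config_groups(cfg)
  # a particle parked outside the domain trips validation at entry
  p <- make_particles(groups$HET, c(5e-5, 5e-5, 5e-7), 1e-6)
  p$z <- 2 * cfg$domain$lengths[[3]]
  expect_error(run(cfg, list(particles = p)), "fixed z-axis")
})

test_that("disabling a stage skips it without perturbing the others", {
  cfg_all <- small_monod_config(processes = c("growth", "division", "death"))
  cfg_nodiv <- small_monod_config(processes = c("growth", "death"))
  groups <- biofilmsim:::config_groups(cfg_all)
  p <- make_particles(groups$HET, c(5e-5, 5e-5, 6.5e-7), 1.29e-6)
  ra <- run(cfg_all, list(particles = p))
  rb <- run(cfg_nodiv, list(particles = p))
  expect_gt(nrow(ra$state$particles), 1L)   # grew past 1.3 um and divided
  expect_equal(nrow(rb$state$particles), 1L)
  # biomass identical either way: division only redistributes mass
  expect_equal(sum(ra$state$particles$mass), sum(rb$state$particles$mass),
               tolerance = 1e-12)
})

test_that("the energy model couples growth to pH speciation", {
  base <- biofilmsim:::nitrifying_config_list()
  base$domain <- list(lengths = c(4e-5, 4e-5, 4e-5), voxel = 2e-5,
                      boundary_layer = 2e-5)
  base$groups <- base$groups[c("HET", "EPS", "DEAD")]
  base$groups$HET$pathways <- NULL
  base$solutes <- list(
    sub = list(diffusion = 1.6e-9, bulk = 0.01, influent = 0.01,
               molar_mass = 0.06, acid_base = "sub"))
  base$kinetics <- "energy"
  base$energy <- list(
    HET = list(q_max = 2e-4, K = 1e-3, m_req = 1e-5, Y = 0.5,
               Cat = 1, Ana = 0.2, substrate = "sub",
               stoich = list(sub = -1)))
  base$acid_base <- list(Kw = 1e-14, temperature = 298.15,
                         nutrients = list(sub = list(charges = c(0, -1),
                                                     K = 1.8e-5)))
  base$processes <- c("mass_balance", "growth")
  base$timesteps$t_end <- 2 * 900
  cfg <- parse_config(base)
  groups <- biofilmsim:::config_groups(cfg)
  p <- make_particles(groups$HET, c(2e-5, 2e-5, 5e-7), 1e-6)
  res <- run(cfg, list(particles = p))
  # the microbe grows on the undissociated substrate fraction
  expect_gt(res$state$particles$mass, p$mass)
  # growth rate is bounded by the fully-undissociated rate
  mu_max_possible <- 0.5 * (2e-4 * 0.01 / 0.06 / 1000 /
                              (1e-3 + 0.01) - 0)  # loose upper bound
  expect_lt(res$state$particles$mu, 0.5 * 2e-4)
})
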