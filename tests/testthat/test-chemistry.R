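# 1D column grid helper: nz voxels of size H/nz, region set to biofilm so
# the bulk clamp stays out of the way.
column_grid <- function(H, nz) {
  g <- build_grid(ibm_domain(c(H / nz, H / nz, H), boundary_layer = 0), H / nz)
  g$region[] <- biofilmsim:::REGION_BIOFILM
  g
}

test_that("a uniform field at the bulk concentration is a fixed point", {
  g <- column_grid(1e-4, 16L)
  spec <- ibm_solute("s", diffusion = 2e-9, bulk = 1)
  S <- array(1, dim = g$n)
  dt <- 0.9 * diffusion_stability_dt(2e-9, g$dx)
  S2 <- diffusion_step(S, spec, g, dt)
  expect_equal(as.vector(S2), as.vector(S))
})

test_that("the FTCS step conserves interior mass away from open boundaries", {
  g <- column_grid(1e-4, 16L)
  spec <- ibm_solute("s", diffusion = 2e-9, bulk = 1)
  # blob in the interior, top layer already at the Dirichlet value: no
  # boundary flux, so total mass is conserved to machine precision
  S <- array(1, dim = g$n)
  S[1, 1, 8] <- 2
  dt <- 0.9 * diffusion_stability_dt(2e-9, g$dx)
  S2 <- diffusion_step(S, spec, g, dt)
  expect_equal(sum(S2), sum(S), tolerance = 1e-14)
})

test_that("timestep above the stability bound is rejected", {
  g <- column_grid(1e-4, 16L)
  spec <- ibm_solute("s", diffusion = 2e-9, bulk = 1)
  S <- array(1, dim = g$n)
  expect_error(diffusion_step(S, spec, g, 10), "stability")
})

test_that("negative concentrations are floored and counted", {
  g <- column_grid(1e-4, 8L)
  spec <- ibm_solute("s", diffusion = 2e-9, bulk = 0)
  S <- array(1e-9, dim = g$n)
  dt <- 0.9 * diffusion_stability_dt(2e-9, g$dx)
  S2 <- diffusion_step(S, spec, g, dt, R = -1)   # huge sink
  expect_true(all(S2 >= 0))
  expect_true(attr(S2, "n_floored") > 0)
})

test_that("first-order sink converges to the cosh profile", {
  H <- 1e-4; nz <- 32L
  g <- column_grid(H, nz)
  D <- 2e-9; k <- 0.8                    # lambda = 50 um, H / lambda = 2
  spec <- ibm_solute("s", diffusion = D, bulk = 1)
  sol <- solve_to_steady_state(list(s = array(0, dim = g$n)),
                               list(s = spec), g,
                               function(f) list(s = -k * f$s), tol = 1e-9)
  z <- voxel_centres(g, 3)
  lam <- sqrt(D / k)
  exact <- cosh(z / lam) / cosh(H / lam)
  expect_lt(max(abs(sol$fields$s[1, 1, ] - exact) / exact), 0.01)
})

test_that("constant source converges to the parabolic profile", {
  H <- 1e-4; nz <- 32L
  g <- column_grid(H, nz)
  D <- 2e-9; r0 <- 1e-4
  spec <- ibm_solute("s", diffusion = D, bulk = 1)
  sol <- solve_to_steady_state(list(s = array(1, dim = g$n)),
                               list(s = spec), g,
                               function(f) list(s = array(r0, dim = g$n)),
                               tol = 1e-9)
  z <- voxel_centres(g, 3)
  exact <- 1 + r0 * (H^2 - z^2) / (2 * D)
  expect_lt(max(abs(sol$fields$s[1, 1, ] - exact) / exact), 0.01)
})

test_that("steady state is reached from any initial field", {
  H <- 1e-4
  g <- column_grid(H, 16L)
  D <- 2e-9; k <- 0.8
  spec <- ibm_solute("s", diffusion = D, bulk = 1)
  rf <- function(f) list(s = -k * f$s)
  a <- solve_to_steady_state(list(s = array(0, dim = g$n)), list(s = spec),
                             g, rf, tol = 1e-9)
  b <- solve_to_steady_state(list(s = array(1, dim = g$n)), list(s = spec),
                             g, rf, tol = 1e-9)
  expect_equal(a$fields$s, b$fields$s, tolerance = 1e-6)
  # pure transport with a Dirichlet top converges to the uniform bulk value
  c0 <- solve_to_steady_state(list(s = array(0, dim = g$n)), list(s = spec),
                              g, NULL, tol = 1e-10)
  expect_equal(as.vector(c0$fields$s), rep(1, 16), tolerance = 1e-4)
  # iteration cap errors with the residual
  expect_error(solve_to_steady_state(list(s = array(0, dim = g$n)),
                                     list(s = spec), g, rf, tol = 1e-12,
                                     max_iters = 5L), "converge")
})

test_that("bulk voxels are clamped to the bulk concentration", {
  g <- build_grid(ibm_domain(c(2e-5, 2e-5, 1e-4), boundary_layer = 2e-5), 1e-5)
  g <- update_regions(g, new_particles())      # all bulk above the layer
  spec <- ibm_solute("s", diffusion = 2e-9, bulk = 0.5)
  S <- array(0, dim = g$n)
  dt <- 0.9 * diffusion_stability_dt(2e-9, g$dx)
  S2 <- diffusion_step(S, spec, g, dt)
  expect_true(all(S2[, , 3:10] == 0.5))
})

test_that("bulk mass balance matches the chemostat closed form", {
  grid <- build_grid(ibm_domain(c(1e-5, 1e-5, 1e-5)), 1e-5)
  # R = 0, Sb(0) = 0: Sb(t) = Sin (1 - exp(-Q t / V))
  b <- ibm_bulk(Q = 1e-8, V = 1e-4, A_f = 0, Sb = c(s = 0), Sin = c(s = 1))
  dt <- 10
  for (i in seq_len(2000)) b <- bulk_update(b, list(), grid, dt)
  exact <- 1 - exp(-1e-4 * 20000)
  expect_equal(b$Sb[["s"]], exact, tolerance = 1e-3)   # O(dt) accuracy
  # closed reactor: constant
  b2 <- ibm_bulk(Q = 0, V = 1e-4, A_f = 0, Sb = c(s = 0.3))
  expect_equal(bulk_update(b2, list(), grid, 100)$Sb[["s"]], 0.3)
  # net consumption pulls the steady state strictly below Sin
  b3 <- ibm_bulk(Q = 1e-8, V = 1e-4, A_f = 1e-2, Sb = c(s = 1), Sin = c(s = 1))
  Rneg <- list(s = array(-1e-3, dim = grid$n))
  for (i in seq_len(500)) b3 <- bulk_update(b3, Rneg, grid, 10)
  expect_lt(b3$Sb[["s"]], 1)
  # fixed solutes are skipped
  b4 <- ibm_bulk(Q = 1e-8, V = 1e-4, A_f = 0, Sb = c(s = 0.2),
                 Sin = c(s = 1), fixed = c(s = TRUE))
  expect_equal(bulk_update(b4, list(), grid, 1000)$Sb[["s"]], 0.2)
})
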