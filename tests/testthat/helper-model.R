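# Shared fixtures: a compact functional-group set and small helper builders.

test_groups <- function() {
  list(
    HET = ibm_group("HET", density = 150, division_diameter = 1.3e-6,
                    death_diameter = 4e-7, decay_rate = 4.63e-6, yield = 0.61,
                    eps = list(density = 30, yield = 0.18, shell_ratio = 1.25),
                    pathways = list(
                      aerobic = list(mumax = 6.94e-5, eta = 1,
                                     K = c(sub = 4e-3, o2 = 2e-4),
                                     stoich = c(sub = -1 / 0.61,
                                                o2 = -(1 - 0.61 - 0.18) / 0.61)))),
    EPS = ibm_group("EPS", density = 30, active = FALSE),
    DEAD = ibm_group("DEAD", density = 150, active = FALSE,
                     death_diameter = 4e-7, lysis_rate = 1e-5)
  )
}

test_domain <- function(L = 1e-4, boundary_layer = 2e-5) {
  ibm_domain(c(L, L, L), boundary_layer = boundary_layer)
}

# n random non-overlap-checked particles well inside the box
random_particles <- function(n, domain, group, d = 1e-6, zmin = 2e-6) {
  pos <- cbind(stats::runif(n, 0, domain$L[1]),
               stats::runif(n, 0, domain$L[2]),
               stats::runif(n, zmin, domain$L[3] - zmin))
  make_particles(group, pos, d)
}

# brute-force all-pairs neighbour list (the O(N^2) oracle)
brute_force_list <- function(particles, domain, cutoff, skin) {
  n <- nrow(particles)
  pairs <- t(utils::combn(n, 2L))
  d <- biofilmsim:::pair_deltas(particles, pairs, domain)
  keep <- rowSums(d^2) < (cutoff + skin)^2
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(pairs = pairs, cutoff = cutoff, skin = skin,
                 pos = cbind(particles$x, particles$y, particles$z)),
            class = "ibm_neighbor_list")
}
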