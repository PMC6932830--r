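# Instantaneous biological events: growth integration, division, death and
# removal, dead-cell lysis, EPS shell accumulation and excretion.

# Uniform random unit vectors (n x 3) via normalised Gaussian triples.
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  v / nrm
}

#' Integrate growth/decay of every agent over one biological step
#'
#' Biomass follows `dm/dt = mu m` integrated by one forward-Euler step,
#' `m <- m (1 + mu dt)`; `mu` may be negative (decay). Core diameters are
#' recomputed from mass. For groups with an EPS shell the shell mass grows at
#' `(Y_EPS / Y)` times the gross (pathway-sum, decay excluded) growth rate.
#' An update that would drive the mass non-positive floors it just below the
#' removal threshold so death processing picks the agent up.
#'
#' @param particles an `ibm_particles` table with `mu` set to the net growth
#'   rate (s^-1) of each agent.
#' @param groups named list of [ibm_group()] definitions.
#' @param dt_bio biological timestep (s), > 0.
#' @param mu_gross optional vector of gross growth rates (pathway sum before
#'   decay, s^-1) driving EPS shell accumulation; defaults to `pmax(mu, 0)`.
#' @return the updated particle table.
#' @export
integrate_growth <- function(particles, groups, dt_bio, mu_gross = NULL) {
  if (dt_bio <= 0) stop("dt_bio must be positive")
  if (nrow(particles) == 0L) return(particles)
  if (is.null(mu_gross)) mu_gross <- pmax(particles$mu, 0)
  active <- group_field(particles, groups, "active", default = 0) > 0
  m <- particles$mass
  m_new <- ifelse(active, m * (1 + particles$mu * dt_bio), m)
  # floor below the removal threshold (death/10) so the agent gets removed
  death_d <- group_field(particles, groups, "death_diameter", default = 0)
  m_floor <- mass_from_diameter(death_d / 10, particles$density) / 2
  m_new <- pmax(m_new, pmax(m_floor, .Machine$double.xmin))
  particles$mass <- m_new
  particles$diameter <- diameter_from_mass(m_new, particles$density)
  # EPS shell accumulation for shell-bearing groups
  has_eps <- !vapply(groups, function(g) is.null(g$eps), logical(1))
  if (any(has_eps)) {
    shell_rate <- vapply(groups, function(g) {
      if (is.null(g$eps)) 0 else g$eps$yield / g$yield
    }, numeric(1))
    sr <- unname(shell_rate[match(particles$group, names(shell_rate))])
    sr[is.na(sr)] <- 0
    particles$outer_mass <- particles$outer_mass +
      sr * pmax(mu_gross, 0) * m * dt_bio * active
  }
  particles <- refresh_outer_diameter(particles, groups)
  particles
}

# Recompute outer diameters from core diameter + shell mass.
refresh_outer_diameter <- function(particles, groups) {
  eps_rho <- vapply(groups, function(g) {
    if (!is.null(g$eps)) g$eps$density else g$density
  }, numeric(1))
  rho <- unname(eps_rho[match(particles$group, names(eps_rho))])
  rho[is.na(rho)] <- particles$density[is.na(rho)]
  particles$outer_diameter <- outer_diameter_from_shell(particles$diameter,
                                                        particles$outer_mass,
                                                        rho)
  particles
}

#' Divide every agent whose core diameter reached its division threshold
#'
#' Division is instantaneous. The parent mass is conserved exactly: daughter 1
#' keeps the parent position and receives a uniformly random fraction
#' `f ~ U(0.4, 0.6)` of the parent mass, daughter 2 gets the rest plus a new
#' unique id. The EPS shell splits with the same fraction. Daughter 2 is
#' placed along a uniformly random 3D direction at a centre distance of the
#' daughters' radius sum (touching spheres) or diameter sum, per
#' `distance_mode`; a placement below the substratum is reflected so
#' `z >= radius`. Velocities are inherited.
#'
#' @param particles an `ibm_particles` table.
#' @param groups named list of [ibm_group()].
#' @param domain an [ibm_domain()] (for periodic wrapping and the substratum).
#' @param distance_mode `"radius_sum"` (touching, default) or
#'   `"diameter_sum"` for the daughter centre separation.
#' @return the particle table after all due divisions.
#' @export
divide_particles <- function(particles, groups, domain,
                             distance_mode = c("radius_sum", "diameter_sum")) {
  distance_mode <- match.arg(distance_mode)
  if (nrow(particles) == 0L) return(particles)
  div_d <- group_field(particles, groups, "division_diameter", default = Inf)
  active <- group_field(particles, groups, "active", default = 0) > 0
  idx <- which(active & particles$diameter >= div_d)
  if (!length(idx)) return(particles)
  n <- length(idx)
  f <- stats::runif(n, 0.4, 0.6)
  m_parent <- particles$mass[idx]
  shell_parent <- particles$outer_mass[idx]
  rho <- particles$density[idx]

  m1 <- f * m_parent
  m2 <- m_parent - m1         # exact conservation
  d1 <- diameter_from_mass(m1, rho)
  d2 <- diameter_from_mass(m2, rho)
  sep <- switch(distance_mode,
                radius_sum = (d1 + d2) / 2,
                diameter_sum = d1 + d2)
  dir <- random_unit_vectors(n)

  daughters <- as.data.frame(particles)[idx, , drop = FALSE]
  daughters$id <- take_ids(particles, n)
  daughters$mass <- m2
  daughters$diameter <- d2
  daughters$outer_mass <- (1 - f) * shell_parent
  daughters$x <- particles$x[idx] + sep * dir[, 1]
  daughters$y <- particles$y[idx] + sep * dir[, 2]
  daughters$z <- particles$z[idx] + sep * dir[, 3]
  # reflect below-substratum placements so z >= radius
  rmin2 <- d2 / 2
  low <- daughters$z < rmin2
  daughters$z[low] <- pmax(2 * rmin2[low] - daughters$z[low], rmin2[low])
  ztop <- domain$L[3]
  daughters$z <- pmin(daughters$z, ztop - rmin2)
  for (ax in 1:2) {
    col <- c("x", "y")[ax]
    if (domain$periodic[ax]) {
      daughters[[col]] <- daughters[[col]] %% domain$L[ax]
    } else {
      daughters[[col]] <- pmin(pmax(daughters[[col]], rmin2),
                               domain$L[ax] - rmin2)
    }
  }

  particles$mass[idx] <- m1
  particles$diameter[idx] <- d1
  particles$outer_mass[idx] <- f * shell_parent

  particles <- append_particles(particles, daughters)
  refresh_outer_diameter(particles, groups)
}

#' Classify each agent as alive, dead, or due for removal
#'
#' An agent whose core diameter shrinks strictly below its group's death
#' threshold is dead (its type switches to `DEAD`; dead cells keep their
#' mechanics but perform no biological activity). Once the diameter falls
#' below a tenth of the death threshold the agent is removed outright.
#'
#' @param particles an `ibm_particles` table.
#' @param groups named list of [ibm_group()].
#' @return character vector, one of `"ALIVE"`, `"DEAD"`, `"REMOVE"` per agent.
#' @export
check_death <- function(particles, groups) {
  death_d <- group_field(particles, groups, "death_diameter", default = 0)
  status <- rep("ALIVE", nrow(particles))
  status[particles$diameter < death_d] <- "DEAD"
  status[particles$diameter < death_d / 10] <- "REMOVE"
  # already-dead agents stay dead until removal
  dead_grp <- particles$group == "DEAD"
  status[dead_grp & status == "ALIVE"] <- "DEAD"
  status
}

#' Apply death and removal events
#'
#' Agents classified `DEAD` switch group to `"DEAD"` (a `DEAD` group must be
#' present in `groups` when this happens); agents classified `REMOVE` are
#' dropped from the table.
#'
#' @inheritParams check_death
#' @return the updated particle table.
#' @export
apply_death <- function(particles, groups) {
  status <- check_death(particles, groups)
  newly_dead <- status == "DEAD" & particles$group != "DEAD"
  if (any(newly_dead)) {
    if (is.null(groups[["DEAD"]]))
      stop("a DEAD functional group must be configured for death events")
    particles$group[newly_dead] <- "DEAD"
    particles$mu[newly_dead] <- 0
  }
  keep <- status != "REMOVE"
  if (!all(keep)) {
    nid <- attr(particles, "next_id")
    particles <- particles[keep, , drop = FALSE]
    attr(particles, "next_id") <- nid
    class(particles) <- c("ibm_particles", "data.frame")
  }
  particles
}

#' Substrate source from lysis of dead biomass
#'
#' Dead cells convert their biomass linearly (first order, rate `k_lys`) into
#' soluble substrate available to other microbes. Returns the per-agent mass
#' release rate; the caller credits it to the host voxel's substrate reaction
#' term and decrements the mass consistently.
#'
#' @param particles an `ibm_particles` table.
#' @param lysis_rate first-order lysis rate (s^-1), >= 0.
#' @return numeric vector, kg s^-1 per agent (0 for living agents).
#' @export
dead_cell_lysis_rate <- function(particles, lysis_rate) {
  if (lysis_rate < 0) stop("lysis_rate must be >= 0")
  ifelse(particles$group == "DEAD", lysis_rate * particles$mass, 0)
}

# Forward-Euler mass decrement matching the lysis source over dt.
apply_lysis <- function(particles, groups, dt) {
  dead <- particles$group == "DEAD"
  if (!any(dead)) return(particles)
  k <- if (!is.null(groups[["DEAD"]])) groups[["DEAD"]]$lysis_rate else 0
  if (k <= 0) return(particles)
  m <- particles$mass[dead]
  particles$mass[dead] <- pmax(m * (1 - k * dt), .Machine$double.xmin)
  particles$diameter[dead] <- diameter_from_mass(particles$mass[dead],
                                                 particles$density[dead])
  refresh_outer_diameter(particles, groups)
}

#' Excrete EPS particles from heterotrophs with thick shells
#'
#' When the relative shell thickness (outer diameter over core diameter) of a
#' shell-bearing agent exceeds its group's `shell_ratio` threshold, a
#' uniformly random fraction `g ~ U(0.4, 0.6)` of the shell mass leaves as a
#' new free EPS particle (group `"EPS"`, EPS density), placed in contact next
#' to the parent: centre distance = parent outer radius + EPS radius along a
#' uniformly random direction (reflected off the substratum). EPS mass is
#' conserved exactly. Agents below the threshold are untouched.
#'
#' @param particles an `ibm_particles` table.
#' @param groups named list of [ibm_group()]; must contain an `"EPS"` group
#'   when excretion triggers.
#' @param domain an [ibm_domain()].
#' @return the particle table with shells reduced and EPS particles appended.
#' @export
eps_excrete <- function(particles, groups, domain) {
  if (nrow(particles) == 0L) return(particles)
  ratio_thr <- vapply(groups, function(g) {
    if (is.null(g$eps)) Inf else g$eps$shell_ratio
  }, numeric(1))
  thr <- unname(ratio_thr[match(particles$group, names(ratio_thr))])
  thr[is.na(thr)] <- Inf
  idx <- which(particles$outer_diameter / particles$diameter > thr &
                 particles$outer_mass > 0)
  if (!length(idx)) return(particles)
  eps_grp <- groups[["EPS"]]
  if (is.null(eps_grp)) stop("an EPS functional group must be configured for excretion")
  n <- length(idx)
  g <- stats::runif(n, 0.4, 0.6)
  m_eps <- g * particles$outer_mass[idx]
  d_eps <- diameter_from_mass(m_eps, eps_grp$density)
  particles$outer_mass[idx] <- particles$outer_mass[idx] - m_eps
  particles <- refresh_outer_diameter(particles, groups)

  dir <- random_unit_vectors(n)
  dist <- particles$outer_diameter[idx] / 2 + d_eps / 2
  pos <- cbind(particles$x[idx] + dist * dir[, 1],
               particles$y[idx] + dist * dir[, 2],
               particles$z[idx] + dist * dir[, 3])
  r_eps <- d_eps / 2
  zz <- pos[, 3]
  low <- zz < r_eps
  zz[low] <- pmax(2 * r_eps[low] - zz[low], r_eps[low])
  pos[, 3] <- pmin(zz, domain$L[3] - r_eps)
  new_eps <- make_particles(eps_grp, pos, d_eps,
                            id = take_ids(particles, n))
  # free EPS particles: all mass in the core sphere at EPS density
  particles <- append_particles(particles, as.data.frame(new_eps))
  # wrap periodic axes
  for (ax in 1:2) {
    col <- c("x", "y")[ax]
    if (domain$periodic[ax]) particles[[col]] <- particles[[col]] %% domain$L[ax]
  }
  particles
}
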