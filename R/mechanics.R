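# Soft-sphere discrete element mechanics: neighbour lists, Hookean contact,
# van der Waals EPS adhesion, fluid drag against a prescribed velocity field,
# velocity-Verlet integration and relaxation to mechanical equilibrium.

#' Force-field parameters for the DEM sub-model
#'
#' @param Kn elastic constant for normal contact (N m^-1).
#' @param gamma_n viscoelastic damping constant for normal contact (s^-1);
#'   the damping force on a contacting pair is `m_ij gamma_n v_ij`.
#' @param Ha Hamaker coefficient of the EPS adhesion force (J).
#' @param h_floor minimum-separation floor (m) regularising the `1/h^2`
#'   adhesion singularity.
#' @param adhesion_cutoff adhesion range as a multiple of the pair's outer
#'   radius sum.
#' @param mu_fluid dynamic viscosity of the ambient fluid (Pa s), used by the
#'   Stokes-form drag correction `beta = 18 mu_f eps_f / d_p^2`.
#' @param viscous optional background viscous damping: `NA` (default) derives
#'   a near-critical per-particle coefficient `sqrt(Kn m)` during relaxation,
#'   a number is used as-is (N s m^-1), 0 disables it.
#' @param z_top behaviour of particles crossing the fixed top face:
#'   `"reflect"` or `"remove"`.
#' @param pressure_floor pressure scale (Pa) below which the community is
#'   considered force-free.
#' @return an object of class `ibm_force_params`.
#' @export
ibm_force_params <- function(Kn = 1e-3, gamma_n = 0, Ha = 1e-20,
                             h_floor = 1e-9, adhesion_cutoff = 1.5,
                             mu_fluid = 1e-3, viscous = NA,
                             z_top = c("reflect", "remove"),
                             pressure_floor = 1e-12) {
  if (Kn < 0 || gamma_n < 0 || Ha < 0 || h_floor < 0)
    stop("Kn, gamma_n, Ha and h_floor must be >= 0")
  structure(list(Kn = Kn, gamma_n = gamma_n, Ha = Ha, h_floor = h_floor,
                 adhesion_cutoff = adhesion_cutoff, mu_fluid = mu_fluid,
                 viscous = viscous, z_top = match.arg(z_top),
                 pressure_floor = pressure_floor),
            class = "ibm_force_params")
}

# Minimum-image separation vectors x_i - x_j for a pair index matrix.
pair_deltas <- function(particles, pairs, domain) {
  d <- cbind(particles$x[pairs[, 1]] - particles$x[pairs[, 2]],
             particles$y[pairs[, 1]] - particles$y[pairs[, 2]],
             particles$z[pairs[, 1]] - particles$z[pairs[, 2]])
  for (ax in 1:3) {
    if (domain$periodic[ax]) {
      L <- domain$L[ax]
      d[, ax] <- d[, ax] - L * round(d[, ax] / L)
    }
  }
  d
}

#' Build a neighbour list by cell binning
#'
#' Returns exactly the particle pairs whose minimum-image centre distance is
#' below `cutoff + skin`. The skin lets the list survive small displacements;
#' it must be rebuilt before any particle moves farther than `skin / 2`
#' (see [neighbor_list_stale()]).
#'
#' @param particles an `ibm_particles` table.
#' @param domain an [ibm_domain()].
#' @param cutoff interaction cutoff (m); default 1.5 x the largest outer
#'   diameter (the adhesion range of the largest pair).
#' @param skin skin distance (m); default a quarter of the cutoff.
#' @return an object of class `ibm_neighbor_list` with the pair index matrix
#'   (`i < j`), the build positions, `cutoff` and `skin`.
#' @export
build_neighbor_list <- function(particles, domain, cutoff = NULL,
                                skin = NULL) {
  n <- nrow(particles)
  if (is.null(cutoff)) {
    cutoff <- if (n) 1.5 * max(particles$outer_diameter) else 1e-6
  }
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(skin)) skin <- 0.25 * cutoff
  rc <- cutoff + skin
  pos <- cbind(particles$x, particles$y, particles$z)
  empty <- matrix(integer(), ncol = 2L)
  if (n < 2L) {
    return(structure(list(pairs = empty, cutoff = cutoff, skin = skin,
                          pos = pos), class = "ibm_neighbor_list"))
  }
  L <- domain$L
  ncell <- pmax(1L, as.integer(floor(L / rc)))
  if (all(ncell < 3L)) {
    cand <- t(utils::combn(n, 2L))            # few cells: all pairs
  } else {
    cs <- L / ncell
    ci <- matrix(0L, n, 3L)
    for (ax in 1:3) {
      w <- wrap_positions(pos, domain)
      ci[, ax] <- pmin(ncell[ax] - 1L,
                       pmax(0L, as.integer(floor(w[, ax] / cs[ax]))))
    }
    lin <- ci[, 1] + ncell[1] * (ci[, 2] + ncell[2] * ci[, 3])
    members <- split(seq_len(n), lin)
    coords <- t(vapply(strtoi(names(members)), function(l) {
      k <- l %/% (ncell[1] * ncell[2])
      r <- l %% (ncell[1] * ncell[2])
      c(r %% ncell[1], r %/% ncell[1], k)
    }, integer(3)))
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    half <- off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
                  (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
    out <- vector("list", 64L); nout <- 0L
    add_pairs <- function(p) { nout <<- nout + 1L; out[[nout]] <<- p }
    # same-cell pairs
    for (m in members) {
      if (length(m) > 1L) add_pairs(t(utils::combn(m, 2L)))
    }
    # cross-cell pairs over the 13 half-space offsets
    key <- function(cc) cc[, 1] + ncell[1] * (cc[, 2] + ncell[2] * cc[, 3])
    lin_names <- names(members)
    for (r in seq_len(nrow(half))) {
      nb <- sweep(coords, 2L, half[r, ], "+")
      ok <- rep(TRUE, nrow(nb))
      for (ax in 1:3) {
        if (domain$periodic[ax]) nb[, ax] <- nb[, ax] %% ncell[ax]
        else ok <- ok & nb[, ax] >= 0L & nb[, ax] < ncell[ax]
      }
      nb_lin <- key(nb)
      for (ii in which(ok)) {
        tgt <- members[[as.character(nb_lin[ii])]]
        if (is.null(tgt)) next
        src <- members[[lin_names[ii]]]
        g <- expand.grid(i = src, j = tgt)
        g <- g[g$i != g$j, , drop = FALSE]
        if (nrow(g)) add_pairs(cbind(pmin(g$i, g$j), pmax(g$i, g$j)))
      }
    }
    cand <- if (nout) do.call(rbind, out[seq_len(nout)]) else empty
    if (nrow(cand)) cand <- unique(cand)
  }
  if (nrow(cand)) {
    d <- pair_deltas(particles, cand, domain)
    keep <- rowSums(d^2) < rc^2
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  }
  structure(list(pairs = cand, cutoff = cutoff, skin = skin, pos = pos),
            class = "ibm_neighbor_list")
}

#' Has any particle outrun the neighbour-list skin?
#'
#' @param nl an `ibm_neighbor_list`.
#' @param particles the current particle table (same ordering as at build).
#' @return `TRUE` when the list must be rebuilt.
#' @export
neighbor_list_stale <- function(nl, particles) {
  if (nrow(particles) != nrow(nl$pos)) return(TRUE)
  disp2 <- (particles$x - nl$pos[, 1])^2 + (particles$y - nl$pos[, 2])^2 +
    (particles$z - nl$pos[, 3])^2
  max(disp2) > (nl$skin / 2)^2
}

#' Pairwise and body forces on every particle
#'
#' Evaluates, over the neighbour-list pairs: the Hookean contact force
#' `F_c = Kn delta n_ij - m_ij gamma_n v_ij` on core-sphere overlaps
#' (`n_ij` the unit vector from j to i, `m_ij` the effective mass), and the
#' attractive van der Waals EPS adhesion `F_a = Ha r_ij / (12 h_min^2)`
#' between EPS-bearing particles within the adhesion cutoff (`r_ij` the
#' effective outer radius, `h_min` the separation floored at `h_floor`).
#' Body forces: Hookean repulsion from the substratum wall, optional fluid
#' drag against a prescribed velocity field, and optional background viscous
#' damping. Newton's third law holds exactly for every pair.
#'
#' @param particles an `ibm_particles` table.
#' @param nl an `ibm_neighbor_list` for the current positions.
#' @param params an [ibm_force_params()].
#' @param groups named list of [ibm_group()] (for the adhesive flags).
#' @param domain an [ibm_domain()].
#' @param velocity optional prescribed fluid velocity field (list of arrays
#'   `vx, vy, vz` on grid voxels) for the drag force.
#' @param grid the `ibm_grid` carrying the velocity field (required with
#'   `velocity`).
#' @return list with `F` (n x 3 matrix, N), `virial` (the pair term
#'   `sum r_ij . F_ij` of the pressure), and `max_overlap` (m).
#' @export
compute_forces <- function(particles, nl, params, groups, domain,
                           velocity = NULL, grid = NULL) {
  n <- nrow(particles)
  F <- matrix(0, n, 3L)
  virial <- 0
  max_overlap <- 0
  m_dyn <- particles$mass + particles$outer_mass
  pairs <- nl$pairs
  if (nrow(pairs)) {
    d <- pair_deltas(particles, pairs, domain)
    dist <- sqrt(rowSums(d^2))
    coincident <- dist < 1e-30
    if (any(coincident)) {
      warning("coincident particle centres; using +z fallback direction")
      d[coincident, ] <- matrix(c(0, 0, 1), sum(coincident), 3L, byrow = TRUE)
      dist[coincident] <- 1e-30
    }
    nvec <- d / dist
    i <- pairs[, 1]; j <- pairs[, 2]
    ri <- particles$diameter[i] / 2; rj <- particles$diameter[j] / 2
    Fp <- matrix(0, nrow(pairs), 3L)
    # Hookean contact with viscoelastic damping on core overlaps
    delta <- ri + rj - dist
    ct <- delta > 0
    if (any(ct)) {
      max_overlap <- max(delta[ct])
      meff <- m_dyn[i] * m_dyn[j] / (m_dyn[i] + m_dyn[j])
      vrel <- cbind(particles$vx[i] - particles$vx[j],
                    particles$vy[i] - particles$vy[j],
                    particles$vz[i] - particles$vz[j])
      Fp[ct, ] <- params$Kn * delta[ct] * nvec[ct, , drop = FALSE] -
        params$gamma_n * meff[ct] * vrel[ct, , drop = FALSE]
    }
    # EPS adhesion between EPS-bearing particles
    if (params$Ha > 0) {
      adh_flag <- group_field(particles, groups, "adhesive", default = 0) > 0
      Ri <- particles$outer_diameter[i] / 2
      Rj <- particles$outer_diameter[j] / 2
      ad <- adh_flag[i] & adh_flag[j] &
        dist < params$adhesion_cutoff * (Ri + Rj)
      if (any(ad)) {
        h <- pmax(dist[ad] - (Ri[ad] + Rj[ad]), params$h_floor)
        reff <- Ri[ad] * Rj[ad] / (Ri[ad] + Rj[ad])
        mag <- params$Ha * reff / (12 * h^2)
        Fp[ad, ] <- Fp[ad, , drop = FALSE] - mag * nvec[ad, , drop = FALSE]
      }
    }
    nz <- rowSums(Fp^2) > 0
    if (any(nz)) {
      acc <- rowsum(rbind(Fp[nz, , drop = FALSE], -Fp[nz, , drop = FALSE]),
                    c(i[nz], j[nz]))
      who <- as.integer(rownames(acc))
      F[who, ] <- F[who, ] + acc
      virial <- sum(d[nz, , drop = FALSE] * Fp[nz, , drop = FALSE])
    }
  }
  # substratum wall: Hookean repulsion (damped) on core contact with z = 0
  r_core <- particles$diameter / 2
  wall <- particles$z < r_core
  if (any(wall)) {
    dw <- r_core[wall] - particles$z[wall]
    F[wall, 3L] <- F[wall, 3L] + params$Kn * dw -
      params$gamma_n * m_dyn[wall] * particles$vz[wall]
    max_overlap <- max(max_overlap, dw)
  }
  # drag against the prescribed fluid velocity field
  if (!is.null(velocity)) {
    if (is.null(grid)) stop("drag needs the grid carrying the velocity field")
    F <- F + drag_force(particles, velocity, grid, params)
  }
  # background viscous damping (relaxation aid)
  cv <- params$viscous
  if (!is.null(cv) && !anyNA(cv) && any(cv > 0)) {
    F <- F - cv * cbind(particles$vx, particles$vy, particles$vz)
  }
  list(F = F, virial = virial, max_overlap = max_overlap)
}

#' Fluid drag force from a prescribed velocity field
#'
#' `F_d = -(V_p eps_s beta / eps_f) (u_p - U_f)`: a particle slower than the
#' fluid is pushed along the flow. `eps_s` is the particle volume fraction of
#' the host voxel, `eps_f = 1 - eps_s`, and the drag correction defaults to
#' the Stokes form `beta = 18 mu_f eps_f / d_p^2`.
#'
#' @inheritParams compute_forces
#' @param velocity list of arrays `vx, vy, vz` (m s^-1) on grid voxels.
#' @return n x 3 matrix of drag forces (N).
#' @export
drag_force <- function(particles, velocity, grid, params) {
  n <- nrow(particles)
  if (n == 0L) return(matrix(0, 0L, 3L))
  lin <- voxel_linear_index(grid, locate_voxel(grid,
                                               cbind(particles$x, particles$y,
                                                     particles$z)))
  Vvox <- grid$dx^3
  Vp <- particle_volumes(particles)
  eps_s_vox <- rep(0, prod(grid$n))
  agg <- rowsum(Vp, lin)
  eps_s_vox[as.integer(rownames(agg))] <- agg[, 1] / Vvox
  eps_s <- eps_s_vox[lin]
  if (any(eps_s >= 1)) stop("over-packed voxel: particle volume fraction >= 1")
  eps_f <- 1 - eps_s
  beta <- 18 * params$mu_fluid * eps_f / particles$diameter^2
  Uf <- cbind(velocity$vx[lin], velocity$vy[lin], velocity$vz[lin])
  up <- cbind(particles$vx, particles$vy, particles$vz)
  -(Vp * eps_s * beta / eps_f) * (up - Uf)
}

#' One velocity-Verlet step
#'
#' Standard velocity Verlet on translations: half kick from the stored
#' forces, drift, force re-evaluation at the new positions, half kick.
#' Positions wrap on periodic faces; a particle reaching the fixed top face
#' is reflected or removed per the force parameters (the substratum is
#' handled by the wall force, with a reflective backstop at z = 0).
#'
#' @param particles an `ibm_particles` table whose `fx, fy, fz` hold the
#'   forces at the current positions.
#' @param force_fn function `(particles) -> list(F = n x 3, ...)` evaluating
#'   forces at given positions (typically a [compute_forces()] closure).
#' @param dt mechanical timestep (s), of order 1e-7 s.
#' @param domain an [ibm_domain()].
#' @param params an [ibm_force_params()] (top-face behaviour).
#' @param max_disp displacement bound (m) per step; exceeding it raises an
#'   instability error. Default unbounded.
#' @return the particle table with updated positions, velocities and forces;
#'   the force evaluation's extra fields are attached as attribute `"force"`.
#' @export
verlet_step <- function(particles, force_fn, dt, domain, params,
                        max_disp = Inf) {
  m <- particles$mass + particles$outer_mass
  half <- dt / (2 * m)
  particles$vx <- particles$vx + particles$fx * half
  particles$vy <- particles$vy + particles$fy * half
  particles$vz <- particles$vz + particles$fz * half
  if (is.finite(max_disp)) {
    disp <- sqrt(particles$vx^2 + particles$vy^2 + particles$vz^2) * dt
    if (any(disp > max_disp))
      stop(sprintf("instability: particle displacement %.3g m exceeds %.3g m in one step",
                   max(disp), max_disp))
  }
  particles$x <- particles$x + particles$vx * dt
  particles$y <- particles$y + particles$vy * dt
  particles$z <- particles$z + particles$vz * dt
  for (ax in 1:2) {
    col <- c("x", "y")[ax]
    if (domain$periodic[ax]) particles[[col]] <- particles[[col]] %% domain$L[ax]
  }
  # substratum backstop and top-face handling
  below <- particles$z < 0
  if (any(below)) {
    particles$z[below] <- -particles$z[below]
    particles$vz[below] <- -particles$vz[below]
  }
  ztop <- domain$L[3]
  above <- particles$z > ztop
  if (any(above)) {
    if (params$z_top == "remove") {
      nid <- attr(particles, "next_id")
      particles <- particles[!above, , drop = FALSE]
      attr(particles, "next_id") <- nid
      class(particles) <- c("ibm_particles", "data.frame")
      m <- particles$mass + particles$outer_mass
    } else {
      particles$z[above] <- 2 * ztop - particles$z[above]
      particles$vz[above] <- -particles$vz[above]
    }
  }
  fe <- force_fn(particles)
  half <- dt / (2 * m)
  particles$vx <- particles$vx + fe$F[, 1] * half
  particles$vy <- particles$vy + fe$F[, 2] * half
  particles$vz <- particles$vz + fe$F[, 3] * half
  particles$fx <- fe$F[, 1]; particles$fy <- fe$F[, 2]; particles$fz <- fe$F[, 3]
  attr(particles, "force") <- fe
  particles
}

#' Virial pressure of the particle system
#'
#' `P = (1 / 3V) (sum_i m_i v_i . v_i + sum_{i<j} r_ij . F_ij)` with `V` the
#' summed (outer-sphere) particle volume: the kinetic term plus the pair
#' interaction term.
#'
#' @param particles an `ibm_particles` table (non-empty).
#' @param virial the pair term `sum r_ij . F_ij` (from [compute_forces()]).
#' @return pressure (Pa).
#' @export
average_pressure <- function(particles, virial = 0) {
  if (nrow(particles) == 0L) stop("average pressure of an empty system is undefined")
  V <- sum(particle_volumes(particles))
  m <- particles$mass + particles$outer_mass
  kin <- sum(m * (particles$vx^2 + particles$vy^2 + particles$vz^2))
  (kin + virial) / (3 * V)
}

#' Relax the community to mechanical equilibrium
#'
#' Runs damped velocity-Verlet dynamics until the average (virial) pressure
#' stabilises: convergence when the relative pressure change over a sliding
#' window of `window` steps drops below `pressure_tol`, with an immediate
#' exit when the system starts force-free and at rest. The neighbour list is
#' rebuilt whenever a particle outruns half the skin.
#'
#' @param particles an `ibm_particles` table.
#' @param params an [ibm_force_params()]. With `viscous = NA` a
#'   near-critical per-particle damping `sqrt(Kn m)` is applied during
#'   relaxation only.
#' @param domain an [ibm_domain()].
#' @param groups named list of [ibm_group()].
#' @param dt mechanical timestep (s).
#' @param pressure_tol relative pressure-change tolerance (default 1e-3 over
#'   a 100-step window).
#' @param max_steps step budget; exceeded -> warning, state returned.
#' @param window sliding-window length (steps).
#' @param velocity,grid optional prescribed flow field for drag.
#' @param max_disp per-step displacement bound forwarded to [verlet_step()].
#' @return list with `particles` (velocities zeroed on exit), `steps`,
#'   `pressure` (at exit) and `converged`.
#' @export
relax <- function(particles, params, domain, groups, dt = 1e-7,
                  pressure_tol = 1e-3, max_steps = 5000L, window = 100L,
                  velocity = NULL, grid = NULL, max_disp = Inf) {
  n <- nrow(particles)
  if (n == 0L)
    return(list(particles = particles, steps = 0L, pressure = 0,
                converged = TRUE))
  if (anyNA(params$viscous))
    params$viscous <- sqrt(params$Kn * (particles$mass + particles$outer_mass))
  nl <- build_neighbor_list(particles, domain)
  force_fn <- function(p) {
    if (nrow(p) != nrow(nl$pos)) {        # e.g. removal at the top face
      nl <<- build_neighbor_list(p, domain)
      if (length(params$viscous) > 1L)
        params$viscous <<- sqrt(params$Kn * (p$mass + p$outer_mass))
    }
    compute_forces(p, nl, params, groups, domain,
                   velocity = velocity, grid = grid)
  }
  fe <- force_fn(particles)
  particles$fx <- fe$F[, 1]; particles$fy <- fe$F[, 2]; particles$fz <- fe$F[, 3]
  P <- average_pressure(particles, fe$virial)
  kin0 <- sum((particles$mass + particles$outer_mass) *
                (particles$vx^2 + particles$vy^2 + particles$vz^2))
  if (abs(P) < params$pressure_floor && kin0 == 0 && fe$max_overlap == 0)
    return(list(particles = particles, steps = 0L, pressure = P,
                converged = TRUE))
  hist <- rep(NA_real_, window)
  steps <- 0L
  converged <- FALSE
  while (steps < max_steps) {
    steps <- steps + 1L
    if (neighbor_list_stale(nl, particles))
      nl <- build_neighbor_list(particles, domain)
    particles <- verlet_step(particles, force_fn, dt, domain, params,
                             max_disp = max_disp)
    fe <- attr(particles, "force")
    P <- average_pressure(particles, fe$virial)
    P_old <- hist[(steps - 1L) %% window + 1L]
    hist[(steps - 1L) %% window + 1L] <- P
    if (steps >= window && !is.na(P_old)) {
      rel <- abs(P - P_old) / max(abs(P), params$pressure_floor)
      if (rel < pressure_tol) { converged <- TRUE; break }
    }
    if (abs(P) < params$pressure_floor) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("mechanical relaxation hit the %d-step budget (P = %.3g Pa)",
                    max_steps, P))
  particles$vx <- 0; particles$vy <- 0; particles$vz <- 0
  attr(particles, "force") <- NULL
  list(particles = particles, steps = steps, pressure = P,
       converged = converged)
}
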