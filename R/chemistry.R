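# Solute transport: explicit (FTCS) diffusion-advection-reaction on the
# voxel grid, pseudo-steady-state iteration, and the bulk-liquid chemostat
# mass balance.

#' Describe one soluble species
#'
#' @param name solute name.
#' @param diffusion molecular diffusion coefficient D (m^2 s^-1), > 0.
#' @param bulk bulk-liquid concentration S_b (kg m^-3); also the Dirichlet
#'   value at the top face and the clamp value of bulk-region voxels.
#' @param influent influent concentration S_in (kg m^-3) for the bulk balance.
#' @param fixed_bulk logical; `TRUE` keeps S_b constant (e.g. oxygen held by
#'   aeration), skipping the bulk mass balance for this solute.
#' @param molar_mass optional molar mass (kg mol^-1) for pH unit conversion.
#' @param acid_base optional name of the acid-base system this solute feeds.
#' @param gas optional gas-phase partner: list with `KLa` (s^-1), `KH`
#'   (Henry constant, dimensionless liquid/gas ratio) and `Sgas` (head-space
#'   concentration).
#' @return an object of class `ibm_solute`.
#' @export
ibm_solute <- function(name, diffusion, bulk = 0, influent = 0,
                       fixed_bulk = FALSE, molar_mass = NULL,
                       acid_base = NULL, gas = NULL) {
  if (!is.finite(diffusion) || diffusion <= 0) stop("diffusion coefficient must be > 0")
  if (bulk < 0 || influent < 0) stop("concentrations must be >= 0")
  if (!is.null(gas)) {
    if (is.null(gas$KLa) || gas$KLa <= 0 || is.null(gas$KH) || gas$KH <= 0)
      stop("gas partner needs positive KLa and KH")
  }
  structure(list(name = name, diffusion = diffusion, bulk = bulk,
                 influent = influent, fixed_bulk = isTRUE(fixed_bulk),
                 molar_mass = molar_mass, acid_base = acid_base, gas = gas),
            class = "ibm_solute")
}

#' Stability bound of the explicit 3D diffusion step
#'
#' Forward-Euler with the 7-point Laplacian is stable for
#' `dt <= dx^2 / (6 D)`.
#'
#' @param D diffusion coefficient (m^2 s^-1).
#' @param dx voxel size (m).
#' @return maximum stable timestep (s).
#' @export
diffusion_stability_dt <- function(D, dx) {
  dx^2 / (6 * D)
}

# Shift an array one voxel along an axis, filling the exposed face per the
# boundary treatment: periodic sides, Dirichlet (ghost = 2 Sb - S) at the top
# face, zero-flux Neumann (ghost = boundary voxel) at the substratum and on
# fixed lateral faces.
shift_with_bc <- function(S, axis, dir, Sb, periodic) {
  n <- dim(S)[axis]
  idx <- if (axis != 3L && periodic[axis]) {
    (seq_len(n) + dir - 1L) %% n + 1L
  } else {
    pmin(pmax(seq_len(n) + dir, 1L), n)   # clamped index = zero-flux ghost
  }
  if (axis == 1L) {
    S[idx, , , drop = FALSE]
  } else if (axis == 2L) {
    S[, idx, , drop = FALSE]
  } else {
    out <- S[, , idx, drop = FALSE]
    if (dir > 0L) out[, , n] <- 2 * Sb - S[, , n]   # top Dirichlet ghost
    out
  }
}

#' One explicit diffusion-advection-reaction step for a solute field
#'
#' Advances `dS/dt = D lap(S) - div(v S) + R` by one forward-Euler step with
#' the 7-point central Laplacian and central-difference advection on voxel
#' centres. Boundary handling: Dirichlet `S_b` at the top face, zero-flux
#' Neumann at the substratum, periodic on periodic side faces (zero-flux on
#' fixed side faces). Bulk-region voxels are clamped to `S_b` after the step
#' (the bulk is perfectly mixed). Negative concentrations are floored at zero
#' and counted in the attribute `"n_floored"`.
#'
#' @param S 3D concentration array (kg m^-3).
#' @param spec the solute's [ibm_solute()] (supplies D and S_b).
#' @param grid an `ibm_grid`.
#' @param dt timestep (s); must respect [diffusion_stability_dt()] and, with
#'   advection, an advective CFL of at most 1.
#' @param R reaction-rate array (kg m^-3 s^-1) or scalar 0.
#' @param velocity optional list of arrays `vx, vy, vz` (m s^-1) on voxel
#'   centres (a prescribed, static fluid velocity field).
#' @param Sb override for the Dirichlet/bulk clamp value (defaults to
#'   `spec$bulk`).
#' @return the updated array.
#' @export
diffusion_step <- function(S, spec, grid, dt, R = 0, velocity = NULL,
                           Sb = spec$bulk) {
  D <- spec$diffusion
  dx <- grid$dx
  dt_max <- diffusion_stability_dt(D, dx)
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("diffusion timestep %g exceeds the stability bound %g", dt, dt_max))
  per <- grid$domain$periodic
  xp <- shift_with_bc(S, 1L, +1L, Sb, per); xm <- shift_with_bc(S, 1L, -1L, Sb, per)
  yp <- shift_with_bc(S, 2L, +1L, Sb, per); ym <- shift_with_bc(S, 2L, -1L, Sb, per)
  zp <- shift_with_bc(S, 3L, +1L, Sb, per); zm <- shift_with_bc(S, 3L, -1L, Sb, per)
  lap <- (xp + xm + yp + ym + zp + zm - 6 * S) / dx^2
  adv <- 0
  if (!is.null(velocity)) {
    cfl <- max(abs(velocity$vx), abs(velocity$vy), abs(velocity$vz)) * dt / dx
    if (cfl > 1) stop(sprintf("advective CFL %g exceeds 1", cfl))
    fx <- velocity$vx * S; fy <- velocity$vy * S; fz <- velocity$vz * S
    adv <- (shift_with_bc(fx, 1L, +1L, Sb * mean(velocity$vx), per) -
              shift_with_bc(fx, 1L, -1L, Sb * mean(velocity$vx), per)) / (2 * dx) +
           (shift_with_bc(fy, 2L, +1L, Sb * mean(velocity$vy), per) -
              shift_with_bc(fy, 2L, -1L, Sb * mean(velocity$vy), per)) / (2 * dx) +
           (shift_with_bc(fz, 3L, +1L, Sb * mean(velocity$vz), per) -
              shift_with_bc(fz, 3L, -1L, Sb * mean(velocity$vz), per)) / (2 * dx)
  }
  S_new <- S + dt * (D * lap - adv + R)
  n_floor <- sum(S_new < 0)
  if (n_floor > 0) S_new[S_new < 0] <- 0
  # perfectly mixed bulk region
  S_new[grid$region == REGION_BULK] <- Sb
  attr(S_new, "n_floored") <- n_floor
  S_new
}

#' Iterate solute fields to pseudo-steady state
#'
#' Repeats [diffusion_step()] for every solute, re-evaluating the reaction
#' term each sweep, until the largest relative per-step change across voxels
#' and solutes falls below `tol` (the frozen-state approximation: the
#' converged field is held constant over the enclosing biological step).
#'
#' @param fields named list of concentration arrays.
#' @param specs named list of [ibm_solute()].
#' @param grid an `ibm_grid`.
#' @param reaction_fn function `(fields) -> named list of R arrays`; may be
#'   `NULL` for pure transport.
#' @param dt timestep (s); default 0.9 x the tightest stability bound.
#' @param tol relative per-sweep change tolerance (default 1e-6).
#' @param max_iters sweep limit; exceeding it is an error reporting the
#'   residual.
#' @param velocity optional prescribed velocity field (see
#'   [diffusion_step()]).
#' @param Sb optional named vector of bulk concentrations overriding the
#'   specs (used by the driver after bulk updates).
#' @return list with `fields` (converged), `iterations`, and `residual`.
#' @export
solve_to_steady_state <- function(fields, specs, grid, reaction_fn = NULL,
                                  dt = NULL, tol = 1e-6, max_iters = 200000L,
                                  velocity = NULL, Sb = NULL) {
  if (tol <= 0) stop("tol must be > 0")
  Dmax <- max(vapply(specs, function(s) s$diffusion, numeric(1)))
  if (is.null(dt)) dt <- 0.9 * diffusion_stability_dt(Dmax, grid$dx)
  it <- 0L
  repeat {
    it <- it + 1L
    R <- if (is.null(reaction_fn)) NULL else reaction_fn(fields)
    delta <- 0
    for (s in names(fields)) {
      Sb_s <- if (!is.null(Sb) && s %in% names(Sb)) Sb[[s]] else specs[[s]]$bulk
      Rs <- if (is.null(R) || is.null(R[[s]])) 0 else R[[s]]
      S_new <- diffusion_step(fields[[s]], specs[[s]], grid, dt, Rs,
                              velocity = velocity, Sb = Sb_s)
      scale <- max(abs(S_new), Sb_s, 1e-300)
      delta <- max(delta, max(abs(S_new - fields[[s]])) / scale)
      fields[[s]] <- S_new
    }
    if (delta < tol) break
    if (it >= max_iters)
      stop(sprintf("steady-state solve did not converge in %d sweeps (residual %.3g)",
                   it, delta))
  }
  list(fields = fields, iterations = it, residual = delta)
}

#' Bulk-liquid state of the macro-scale reactor
#'
#' @param Q volumetric flow rate (m^3 s^-1).
#' @param V reactor volume (m^3).
#' @param A_f biofilm surface area in the reactor (m^2).
#' @param Sb named vector of bulk concentrations (kg m^-3).
#' @param Sin named vector of influent concentrations (kg m^-3).
#' @param fixed named logical vector; `TRUE` entries are not updated.
#' @return an object of class `ibm_bulk`.
#' @export
ibm_bulk <- function(Q, V, A_f, Sb, Sin = Sb, fixed = NULL) {
  if (Q < 0 || V < 0 || A_f < 0) stop("Q, V and A_f must be >= 0")
  if (is.null(fixed)) fixed <- stats::setNames(rep(FALSE, length(Sb)), names(Sb))
  structure(list(Q = Q, V = V, A_f = A_f, Sb = Sb, Sin = Sin, fixed = fixed),
            class = "ibm_bulk")
}

#' Update the bulk concentrations by the chemostat mass balance
#'
#' Integrates, by one forward-Euler step over the biological timestep,
#' `dS_b/dt = (Q/V)(S_in - S_b) + (A_f / (V Lx Ly)) * Int R dV`,
#' the volume integral running over all voxels. Concentrations are floored at
#' zero; solutes flagged fixed (e.g. aerated oxygen) are skipped.
#'
#' @param bulk an [ibm_bulk()].
#' @param R_fields named list of reaction-rate arrays (kg m^-3 s^-1).
#' @param grid an `ibm_grid`.
#' @param dt_bio biological timestep (s), > 0.
#' @return the updated `ibm_bulk`.
#' @export
bulk_update <- function(bulk, R_fields, grid, dt_bio) {
  if (dt_bio <= 0) stop("dt_bio must be positive")
  Vvox <- grid$dx^3
  LxLy <- grid$domain$L[1] * grid$domain$L[2]
  for (s in names(bulk$Sb)) {
    if (isTRUE(bulk$fixed[[s]])) next
    integral <- if (!is.null(R_fields[[s]])) sum(R_fields[[s]]) * Vvox else 0
    dSb <- (bulk$Q / bulk$V) * (bulk$Sin[[s]] - bulk$Sb[[s]]) +
      bulk$A_f / (bulk$V * LxLy) * integral
    bulk$Sb[[s]] <- max(0, bulk$Sb[[s]] + dt_bio * dSb)
  }
  bulk
}
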