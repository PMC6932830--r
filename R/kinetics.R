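# Growth kinetics: per-microbe specific growth rates (Monod or energy based)
# and the mapping of growth onto per-voxel solute reaction rates.

#' Monod growth rate of one functional group at local concentrations
#'
#' Each growth pathway p of the group contributes
#' `mu_p = mumax * eta_p * prod_s S_s / (K_{p,s} + S_s)` over its limiting
#' solutes (`eta = 1` for aerobic pathways, `eta = etaHET` for anoxic
#' denitrification by heterotrophs), optionally multiplied by inhibition
#' factors `K_I / (K_I + S)` (e.g. oxygen switching off denitrification).
#' The net specific growth rate is the pathway sum minus the first-order
#' decay rate b. Zero concentrations are handled natively (the Monod factor
#' is simply 0).
#'
#' @param group an [ibm_group()] with `pathways`.
#' @param local_conc named numeric vector of solute concentrations (kg m^-3)
#'   in the agent's voxel; must cover every solute the pathways reference.
#' @return list with `mu` (net rate, s^-1) and `pathway_mu` (named vector of
#'   per-pathway gross rates, the weights for the reaction-rate split).
#' @export
monod_growth_rate <- function(group, local_conc) {
  if (any(local_conc < 0)) stop("concentrations must be >= 0")
  if (!length(group$pathways))
    return(list(mu = -group$decay_rate, pathway_mu = numeric()))
  mu_p <- vapply(group$pathways, function(pw) {
    eta <- if (is.null(pw$eta)) 1 else pw$eta
    rate <- pw$mumax * eta
    for (s in names(pw$K)) {
      if (!s %in% names(local_conc))
        stop(sprintf("pathway of group %s needs solute '%s' which is not configured",
                     group$name, s))
      S <- local_conc[[s]]
      rate <- rate * S / (pw$K[[s]] + S)
    }
    for (s in names(pw$inhibition)) {
      if (!s %in% names(local_conc))
        stop(sprintf("pathway of group %s needs solute '%s' which is not configured",
                     group$name, s))
      KI <- pw$inhibition[[s]]
      rate <- rate * KI / (KI + local_conc[[s]])
    }
    rate
  }, numeric(1))
  list(mu = sum(mu_p) - group$decay_rate, pathway_mu = mu_p)
}

#' Energy-limited growth rate
#'
#' In the energy-based model a microbe grows only with the energy left after
#' maintenance: `mu = Y (q_met - m_req)`. The rate is negative (decay) when
#' the harvested metabolic rate does not meet the maintenance requirement.
#'
#' @param Y growth yield from the energy dissipation method (config-supplied).
#' @param q_met metabolic rate (s^-1 equivalent), >= 0.
#' @param m_req maintenance requirement on the same scale, >= 0.
#' @return specific growth rate mu (s^-1).
#' @export
energy_growth_rate <- function(Y, q_met, m_req) {
  if (q_met < 0) stop("q_met must be >= 0")
  if (m_req < 0) stop("m_req must be >= 0")
  Y * (q_met - m_req)
}

#' Metabolic rate with Monod saturation on the active substrate form
#'
#' The energy model's metabolic rate saturates on the concentration of the
#' non-charged (undissociated) substrate form supplied by the pH speciation:
#' `q_met = q_max * S_active / (K + S_active)`.
#'
#' @param q_max maximum metabolic rate.
#' @param S_active concentration of the active (non-charged) form (kg m^-3).
#' @param K half-saturation constant (kg m^-3).
#' @return metabolic rate, same units as `q_max`.
#' @export
q_met_monod <- function(q_max, S_active, K) {
  if (S_active < 0) stop("S_active must be >= 0")
  q_max * S_active / (K + S_active)
}

#' Energy-model reaction rate of a soluble species
#'
#' The consumption/formation rate driven by one microbe's growth is
#' `R = mu (Cat / Y + Ana) X`, with `Cat` the catabolic free energy supplied
#' and `Ana` the anabolic free energy required (per unit biomass, config
#' units) and `X` the biomass density; the overall-reaction stoichiometry
#' distributes it over the solute species.
#'
#' @param mu specific growth rate (s^-1).
#' @param Y growth yield.
#' @param Cat catabolic free energy coefficient.
#' @param Ana anabolic free energy coefficient.
#' @param X biomass density (kg m^-3), >= 0.
#' @return reaction rate (kg m^-3 s^-1 scale).
#' @export
energy_reaction_rate <- function(mu, Y, Cat, Ana, X) {
  if (X < 0) stop("biomass density must be >= 0")
  mu * (Cat / Y + Ana) * X
}

# Per-voxel pathway rate arrays for one group: a named list of 3D arrays
# mu_p[voxel] evaluated from the solute fields. `fields` is a named list of
# concentration arrays.
pathway_rate_fields <- function(group, fields, dims) {
  lapply(group$pathways, function(pw) {
    eta <- if (is.null(pw$eta)) 1 else pw$eta
    rate <- array(pw$mumax * eta, dim = dims)
    for (s in names(pw$K)) {
      S <- fields[[s]]
      if (is.null(S))
        stop(sprintf("pathway of group %s needs solute '%s' which is not configured",
                     group$name, s))
      rate <- rate * S / (pw$K[[s]] + S)
    }
    for (s in names(pw$inhibition)) {
      S <- fields[[s]]
      if (is.null(S))
        stop(sprintf("pathway of group %s needs solute '%s' which is not configured",
                     group$name, s))
      rate <- rate * pw$inhibition[[s]] / (pw$inhibition[[s]] + S)
    }
    rate
  })
}

# Per-voxel biomass (kg) of each group: matrix [n_voxel, n_group].
voxel_group_mass <- function(particles, grid, groups) {
  nvox <- prod(grid$n)
  M <- matrix(0, nrow = nvox, ncol = length(groups),
              dimnames = list(NULL, names(groups)))
  if (nrow(particles) == 0L) return(M)
  lin <- voxel_linear_index(grid, locate_voxel(grid,
                                               cbind(particles$x, particles$y,
                                                     particles$z)))
  for (g in names(groups)) {
    sel <- particles$group == g
    if (any(sel)) {
      agg <- rowsum(particles$mass[sel], lin[sel])
      M[as.integer(rownames(agg)), g] <- agg[, 1]
    }
  }
  M
}

# Precompute what the reaction evaluation needs from the frozen community:
# per-voxel biomass arrays (kg per voxel volume) of the pathway-bearing
# groups and the lysis source field. Rebuilt once per biological step.
reaction_context <- function(particles, grid, groups, lysis_solute = "sub") {
  dims <- grid$n
  Vvox <- grid$dx^3
  M <- voxel_group_mass(particles, grid, groups)
  Mg <- list()
  for (g in names(groups)) {
    grp <- groups[[g]]
    if (!isTRUE(grp$active) || !length(grp$pathways)) next
    if (any(M[, g] > 0)) Mg[[g]] <- array(M[, g] / Vvox, dim = dims)
  }
  lysis <- NULL
  dead_grp <- groups[["DEAD"]]
  if (!is.null(lysis_solute) && !is.null(dead_grp) &&
      dead_grp$lysis_rate > 0 && "DEAD" %in% colnames(M) &&
      any(M[, "DEAD"] > 0)) {
    lysis <- array(dead_grp$lysis_rate * M[, "DEAD"] / Vvox, dim = dims)
  }
  list(Mg = Mg, lysis = lysis, lysis_solute = lysis_solute, dims = dims)
}

# Reaction rates against the (changing) fields for a frozen context.
accumulate_from_context <- function(ctx, fields, groups) {
  R <- lapply(fields, function(f) array(0, dim = ctx$dims))
  for (g in names(ctx$Mg)) {
    grp <- groups[[g]]
    mu_fields <- pathway_rate_fields(grp, fields, ctx$dims)
    for (pw_name in names(grp$pathways)) {
      pw <- grp$pathways[[pw_name]]
      if (is.null(pw$stoich)) next
      mu_m <- mu_fields[[pw_name]] * ctx$Mg[[g]]
      for (s in names(pw$stoich)) {
        if (!is.null(R[[s]])) R[[s]] <- R[[s]] + pw$stoich[[s]] * mu_m
      }
    }
  }
  if (!is.null(ctx$lysis) && !is.null(R[[ctx$lysis_solute]]))
    R[[ctx$lysis_solute]] <- R[[ctx$lysis_solute]] + ctx$lysis
  R
}

#' Accumulate per-voxel solute reaction rates from the growing community
#'
#' For every voxel v and solute s,
#' `R[v, s] = sum_{i in v} sum_p nu[g_i, p, s] mu_{p,i} m_i / V_voxel`
#' (consumption negative, production positive), evaluated against the frozen
#' solute fields of the current biological step. Lysis of `DEAD` biomass adds
#' a first-order source to the configured substrate solute.
#'
#' @param particles an `ibm_particles` table.
#' @param grid an `ibm_grid`.
#' @param fields named list of solute concentration arrays (kg m^-3).
#' @param groups named list of [ibm_group()].
#' @param lysis_solute solute name credited with lysed dead biomass
#'   (default `"sub"`); ignored when no DEAD group or zero lysis rate.
#' @return named list of reaction-rate arrays (kg m^-3 s^-1), one per solute
#'   present in `fields`.
#' @export
accumulate_voxel_reactions <- function(particles, grid, fields, groups,
                                       lysis_solute = "sub") {
  ctx <- reaction_context(particles, grid, groups, lysis_solute)
  accumulate_from_context(ctx, fields, groups)
}

#' Net growth rate of every agent against frozen solute fields
#'
#' Evaluates the Monod pathway rates of each agent at its host voxel and
#' returns net (`pathway sum - decay`) and gross (pathway sum) rates.
#' Inactive groups (EPS, DEAD) get zero.
#'
#' @inheritParams accumulate_voxel_reactions
#' @return list with numeric vectors `mu` and `mu_gross` (s^-1, per agent).
#' @export
particle_growth_rates <- function(particles, grid, fields, groups) {
  n <- nrow(particles)
  mu <- numeric(n)
  mu_gross <- numeric(n)
  if (n == 0L) return(list(mu = mu, mu_gross = mu_gross))
  lin <- voxel_linear_index(grid, locate_voxel(grid,
                                               cbind(particles$x, particles$y,
                                                     particles$z)))
  dims <- grid$n
  for (g in names(groups)) {
    grp <- groups[[g]]
    sel <- particles$group == g
    if (!any(sel) || !isTRUE(grp$active)) next
    gross <- numeric(sum(sel))
    if (length(grp$pathways)) {
      mu_fields <- pathway_rate_fields(grp, fields, dims)
      for (mf in mu_fields) gross <- gross + mf[lin[sel]]
    }
    mu_gross[sel] <- gross
    mu[sel] <- gross - grp$decay_rate
  }
  list(mu = mu, mu_gross = mu_gross)
}
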