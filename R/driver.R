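# The multi-timescale simulation loop: per biological step the solute fields
# are driven to pseudo-steady state against frozen biology, the bulk liquid
# is updated, agents grow and divide/die/excrete, and the community is
# mechanically relaxed against frozen biology and chemistry.

#' Run a simulation
#'
#' Executes the individual-based simulation loop. Per biological step, in
#' order: (1) the prescribed velocity field is applied (drag inputs), (2) the
#' solute fields are solved to pseudo-steady state with reaction rates
#' re-evaluated from the frozen community (with per-voxel pH and gas-liquid
#' transfer when the energy model is enabled), (3) the bulk liquid is updated
#' by the chemostat mass balance, (4) growth is integrated, (5) division,
#' death/removal, lysis and EPS excretion fire, (6) the community relaxes to
#' mechanical equilibrium, and (7) the region labelling and neighbour
#' bookkeeping are refreshed. Any stage error aborts with the stage name and
#' step index. Enabled stages come from the configuration's `processes`
#' list; a disabled stage is skipped without perturbing the others.
#'
#' @param config an `ibm_config` (see [parse_config()]).
#' @param state optional initial state: list with `particles`
#'   (an `ibm_particles` table), and optionally `fields`, `bulk`, `t`,
#'   `rng` (from a restart) and `velocity` (prescribed fluid velocity arrays
#'   `vx, vy, vz` on the grid). Missing pieces are initialised from the
#'   config (uniform fields at bulk concentrations, t = 0).
#' @param until optional end time (s), overriding `timesteps$t_end`.
#' @param progress print a per-step summary line.
#' @return an object of class `ibm_run`: list with `state` (final state,
#'   including the RNG state for restarts), `history` (per-step data frame:
#'   time, particle count, per-group biomass, solver iterations, relaxation
#'   pressure, morphology summaries, bulk concentrations) and `config`.
#' @export
run <- function(config, state = NULL, until = NULL, progress = FALSE) {
  stopifnot(inherits(config, "ibm_config"))
  domain <- config_domain(config)
  grid <- config_grid(config)
  groups <- config_groups(config)
  specs <- config_solutes(config)
  params <- config_force_params(config)
  proc <- config$processes
  dt_bio <- config$timesteps$bio
  t_end <- if (!is.null(until)) until else config$timesteps$t_end

  if (is.null(state)) state <- list()
  particles <- state$particles
  if (is.null(particles)) particles <- new_particles()
  if (nrow(particles)) {
    pos <- cbind(particles$x, particles$y, particles$z)
    wrap_positions(pos, domain)   # errors if outside fixed faces
  }
  bulk <- state$bulk
  if (is.null(bulk)) bulk <- config_bulk(config)
  fields <- state$fields
  if (is.null(fields)) {
    fields <- lapply(names(specs), function(s) array(bulk$Sb[[s]], dim = grid$n))
    names(fields) <- names(specs)
  }
  velocity <- state$velocity
  t_bio <- state$t %||% 0

  if (!is.null(state$rng)) {
    assign(".Random.seed", state$rng, envir = globalenv())
  } else {
    set.seed(config$seed)
  }

  energy <- if (identical(config$kinetics, "energy")) build_energy_model(config) else NULL
  lysis_solute <- if ("lysis" %in% proc) config$lysis_solute else NULL
  # reaction closure against the frozen community of the current step
  make_reaction_fn <- function(particles) {
    if (is.null(energy)) {
      ctx <- reaction_context(particles, grid, groups, lysis_solute)
      function(flds) accumulate_from_context(ctx, flds, groups)
    } else {
      function(flds) energy_voxel_reactions(particles, grid, flds, groups,
                                            energy, specs,
                                            lysis_solute = lysis_solute)
    }
  }

  grid <- update_regions(grid, particles)
  history <- list()
  step <- 0L
  stage <- "init"
  withCallingHandlers({
    while (t_bio < t_end - 1e-9) {
      step <- step + 1L
      iters <- 0L
      pressure <- NA_real_
      reaction_fn <- make_reaction_fn(particles)

      if ("mass_balance" %in% proc && length(specs)) {
        stage <- "solute steady state"
        sol <- solve_to_steady_state(fields, specs, grid, reaction_fn,
                                     dt = config$timesteps$diffusion,
                                     tol = config$solver$diffusion_tol,
                                     max_iters = config$solver$max_sweeps,
                                     velocity = velocity, Sb = bulk$Sb)
        fields <- sol$fields
        iters <- sol$iterations
      }

      if ("bulk" %in% proc && length(specs)) {
        stage <- "bulk mass balance"
        bulk <- bulk_update(bulk, reaction_fn(fields), grid, dt_bio)
      }

      if ("growth" %in% proc) {
        stage <- "growth"
        rates <- if (is.null(energy)) {
          particle_growth_rates(particles, grid, fields, groups)
        } else {
          energy_particle_rates(particles, grid, fields, groups, energy, specs)
        }
        particles$mu <- rates$mu
        particles <- integrate_growth(particles, groups, dt_bio,
                                      mu_gross = rates$mu_gross)
      }
      if (!is.null(lysis_solute)) {
        stage <- "lysis"
        particles <- apply_lysis(particles, groups, dt_bio)
      }
      if ("division" %in% proc) {
        stage <- "division"
        particles <- divide_particles(particles, groups, domain,
                                      distance_mode = config$division_distance)
      }
      if ("death" %in% proc) {
        stage <- "death"
        particles <- apply_death(particles, groups)
      }
      if ("eps" %in% proc) {
        stage <- "EPS excretion"
        particles <- eps_excrete(particles, groups, domain)
      }

      if ("mechanics" %in% proc && nrow(particles)) {
        stage <- "mechanical relaxation"
        rx <- relax(particles, params, domain, groups,
                    dt = config$timesteps$mechanical,
                    pressure_tol = config$solver$pressure_tol,
                    max_steps = config$solver$relax_max_steps,
                    window = config$solver$relax_window,
                    velocity = velocity, grid = grid, max_disp = grid$dx)
        particles <- rx$particles
        pressure <- rx$pressure
      }

      stage <- "region update"
      grid <- update_regions(grid, particles)
      t_bio <- t_bio + dt_bio

      stage <- "observation"
      hm <- height_map(particles, domain, bin_size = grid$dx)
      bm <- group_biomass(particles, groups)
      row <- data.frame(time = t_bio, n_particles = nrow(particles),
                        solver_iterations = iters, pressure = pressure,
                        mean_height = average_height(hm),
                        roughness = roughness(hm),
                        area_density = area_density(particles, domain),
                        stringsAsFactors = FALSE)
      for (g in names(bm)) row[[paste0("biomass_", g)]] <- bm[[g]]
      for (s in names(bulk$Sb)) row[[paste0("bulk_", s)]] <- bulk$Sb[[s]]
      history[[step]] <- row
      if (progress) {
        message(sprintf("t = %8.0f s  particles = %6d  sweeps = %5d  P = %9.3g Pa",
                        t_bio, nrow(particles), iters, pressure))
      }
      if (!is.null(config$output$dir) && step %% config$output$every == 0L) {
        stage <- "output"
        write_snapshot(list(particles = particles, fields = fields,
                            bulk = bulk, t = t_bio),
                       config$output$dir, grid, groups,
                       vtk = isTRUE(config$output$vtk))
      }
    }
  }, error = function(e) {
    stop(sprintf("stage '%s' failed at biological step %d (t = %g s): %s",
                 stage, step, t_bio, conditionMessage(e)), call. = FALSE)
  })

  history <- if (length(history)) do.call(rbind, history) else data.frame()
  state_out <- list(particles = particles, fields = fields, bulk = bulk,
                    t = t_bio, velocity = velocity,
                    rng = get(".Random.seed", envir = globalenv()))
  structure(list(state = state_out, history = history, config = config),
            class = "ibm_run")
}

#' @export
print.ibm_run <- function(x, ...) {
  cat(sprintf("<ibm_run> t = %g s, %d particles, %d recorded steps\n",
              x$state$t, nrow(x$state$particles), nrow(x$history)))
  invisible(x)
}

#' Write a simulation snapshot to disk
#'
#' Emits the particle table as plain text and, optionally, VTK legacy files
#' (polydata for particles, structured points per solute field), labelled by
#' the simulation time.
#'
#' @param state a state list with `particles`, `fields`, `t`.
#' @param dir output directory (created if missing).
#' @param grid an `ibm_grid`.
#' @param groups named list of [ibm_group()].
#' @param vtk also write VTK files.
#' @return the directory, invisibly.
#' @export
write_snapshot <- function(state, dir, grid, groups, vtk = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  label <- sprintf("%012.0f", state$t)
  write_particles_txt(state$particles,
                      file.path(dir, sprintf("particles_%s.txt", label)))
  if (vtk) {
    write_vtk_particles(state$particles,
                        file.path(dir, sprintf("particles_%s.vtk", label)),
                        groups)
    for (s in names(state$fields)) {
      write_vtk_field(state$fields[[s]], grid,
                      file.path(dir, sprintf("field_%s_%s.vtk", s, label)),
                      name = s)
    }
  }
  invisible(dir)
}

# ---- energy-based kinetics ------------------------------------------------

# Assemble the energy model from the config: per-group metabolic parameters
# plus the acid-base system used for the active (non-charged) substrate form.
build_energy_model <- function(config) {
  en <- config$energy
  if (is.null(en)) stop("kinetics 'energy' needs an 'energy' config section")
  ab <- config$acid_base
  system <- if (!is.null(ab)) {
    ibm_acid_base(lapply(ab$nutrients, function(n) {
      list(charges = unlist(n$charges), K = unlist(n$K))
    }), Kw = ab$Kw %||% 1e-14, temperature = ab$temperature %||% 298.15)
  } else {
    ibm_acid_base()
  }
  list(groups = en, system = system)
}

# Per-voxel pH and active-form (undissociated) concentration factors for
# every dissociating solute; returns list(pH array, frac named list).
voxel_speciation <- function(fields, specs, system) {
  dims <- dim(fields[[1]])
  nvox <- prod(dims)
  diss <- names(specs)[vapply(specs, function(s) !is.null(s$acid_base),
                              logical(1))]
  frac <- lapply(stats::setNames(diss, diss), function(s) array(1, dim = dims))
  pH <- array(7, dim = dims)
  if (!length(diss) || !length(system$nutrients)) {
    return(list(pH = pH, frac = frac))
  }
  molar <- vapply(diss, function(s) {
    mm <- specs[[s]]$molar_mass
    if (is.null(mm)) stop(sprintf("solute %s needs a molar mass for pH coupling", s))
    mm
  }, numeric(1))
  for (v in seq_len(nvox)) {
    totals <- vapply(diss, function(s) fields[[s]][v] / molar[[s]] / 1000,
                     numeric(1))
    names(totals) <- vapply(diss, function(s) specs[[s]]$acid_base,
                            character(1))
    sol <- solve_ph(totals, system)
    pH[v] <- sol$pH
    for (s in diss) {
      nut <- specs[[s]]$acid_base
      alpha <- speciation_fractions(system$nutrients[[nut]], sol$H)
      frac[[s]][v] <- alpha[1L]   # most-protonated, non-charged form
    }
  }
  list(pH = pH, frac = frac)
}

# Reaction rates under the energy model: per voxel, per group,
# R_s = stoich_s * mu (Cat/Y + Ana) X, with mu = Y (q_met - m_req) and q_met
# Monod-saturating on the active substrate form; gas-liquid transfer adds its
# source to gas-coupled solutes.
energy_voxel_reactions <- function(particles, grid, fields, groups, energy,
                                   specs, lysis_solute = NULL) {
  dims <- grid$n
  Vvox <- grid$dx^3
  R <- lapply(fields, function(f) array(0, dim = dims))
  sp <- voxel_speciation(fields, specs, energy$system)
  M <- voxel_group_mass(particles, grid, groups)
  for (g in names(energy$groups)) {
    eg <- energy$groups[[g]]
    if (!g %in% colnames(M)) next
    X <- array(M[, g], dim = dims) / Vvox
    if (all(X == 0)) next
    s <- eg$substrate
    S_act <- fields[[s]] * (if (!is.null(sp$frac[[s]])) sp$frac[[s]] else 1)
    q <- eg$q_max * S_act / (eg$K + S_act)
    mu <- eg$Y * (q - eg$m_req)
    rate <- mu * (eg$Cat / eg$Y + eg$Ana) * X
    for (sn in names(eg$stoich)) {
      if (!is.null(R[[sn]])) R[[sn]] <- R[[sn]] + eg$stoich[[sn]] * rate
    }
  }
  for (sn in names(specs)) {
    gas <- specs[[sn]]$gas
    if (!is.null(gas)) {
      R[[sn]] <- R[[sn]] + gas$KLa * (gas$Sgas - fields[[sn]] / gas$KH)
    }
  }
  if (!is.null(lysis_solute) && !is.null(groups[["DEAD"]]) &&
      groups[["DEAD"]]$lysis_rate > 0 && !is.null(R[[lysis_solute]]) &&
      any(particles$group == "DEAD")) {
    Mdead <- array(M[, "DEAD"], dim = dims)
    R[[lysis_solute]] <- R[[lysis_solute]] +
      groups[["DEAD"]]$lysis_rate * Mdead / Vvox
  }
  R
}

# Per-particle growth rates under the energy model.
energy_particle_rates <- function(particles, grid, fields, groups, energy,
                                  specs) {
  n <- nrow(particles)
  mu <- numeric(n)
  if (n == 0L) return(list(mu = mu, mu_gross = mu))
  sp <- voxel_speciation(fields, specs, energy$system)
  lin <- voxel_linear_index(grid, locate_voxel(grid,
                                               cbind(particles$x, particles$y,
                                                     particles$z)))
  for (g in names(energy$groups)) {
    eg <- energy$groups[[g]]
    sel <- particles$group == g
    if (!any(sel)) next
    s <- eg$substrate
    S_act <- fields[[s]][lin[sel]] *
      (if (!is.null(sp$frac[[s]])) sp$frac[[s]][lin[sel]] else 1)
    q <- eg$q_max * S_act / (eg$K + S_act)
    mu[sel] <- eg$Y * (q - eg$m_req)
  }
  list(mu = mu, mu_gross = pmax(mu, 0))
}
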