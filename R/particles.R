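# Column layout of the particle table. One row per microbial agent.
PARTICLE_COLS <- c("id", "group", "x", "y", "z", "vx", "vy", "vz",
                   "fx", "fy", "fz", "mass", "density", "diameter",
                   "outer_mass", "outer_diameter", "mu")

#' Spherical-particle mass/diameter conversions
#'
#' Microbes are soft spheres of uniform density, so
#' `diameter = (6 m / (pi rho))^(1/3)` and conversely.
#'
#' @param diameter sphere diameter (m).
#' @param mass sphere mass (kg).
#' @param density sphere density (kg m^-3).
#' @return a numeric vector of masses (kg) or diameters (m).
#' @export
mass_from_diameter <- function(diameter, density) {
  density * pi * diameter^3 / 6
}

#' @rdname mass_from_diameter
#' @export
diameter_from_mass <- function(mass, density) {
  (6 * mass / (pi * density))^(1 / 3)
}

#' Outer diameter of a particle carrying an EPS shell
#'
#' The EPS shell of mass `outer_mass` and density `eps_density` wraps the
#' core sphere; the outer diameter is the diameter of the sphere whose volume
#' is core volume plus shell volume.
#'
#' @param diameter core diameter (m).
#' @param outer_mass shell mass (kg, >= 0).
#' @param eps_density EPS density (kg m^-3); lower than the microbe density.
#' @return outer diameter (m), `>= diameter`.
#' @export
outer_diameter_from_shell <- function(diameter, outer_mass, eps_density) {
  (diameter^3 + 6 * outer_mass / (pi * eps_density))^(1 / 3)
}

#' Define a microbial functional group
#'
#' A functional group is a microbe type whose members share one parameter set:
#' kinetics (growth pathways, first-order decay), density, and division/death
#' diameter thresholds. Heterotrophs additionally carry EPS shell parameters.
#'
#' @param name group name, e.g. `"HET"`, `"AOB"`, `"NOB"`, `"EPS"`, `"DEAD"`.
#' @param density biomass density (kg m^-3).
#' @param division_diameter core diameter (m) at or above which a microbe
#'   divides; must exceed `death_diameter`.
#' @param death_diameter core diameter (m) below which a microbe is declared
#'   dead; agents below a tenth of it are removed outright.
#' @param decay_rate first-order endogenous decay rate b (s^-1), subtracted
#'   from the gross growth rate.
#' @param yield biomass yield Y (kg biomass per kg substrate), in (0, 1].
#' @param pathways named list of growth pathways. Each pathway is a list with
#'   `mumax` (s^-1), `eta` (rate reduction factor, 1 for aerobic growth,
#'   `etaHET` under anoxic denitrifying conditions), `K` (named vector of
#'   half-saturation constants, kg m^-3, one per limiting solute) and `stoich`
#'   (named vector of solute mass produced (+) or consumed (-) per unit of new
#'   core biomass).
#' @param eps optional EPS shell parameters for heterotrophs: list with
#'   `density` (kg m^-3), `yield` (EPS yield Y_EPS; shell grows at
#'   `Y_EPS / Y` times the core rate) and `shell_ratio` (outer/core diameter
#'   ratio that triggers excretion).
#' @param active logical; inert groups (EPS, DEAD) take no part in growth.
#' @param adhesive logical; whether members carry/are EPS and feel the van der
#'   Waals adhesion force. Defaults to TRUE for groups with shells and "EPS".
#' @param lysis_rate first-order rate (s^-1) at which DEAD biomass converts to
#'   soluble substrate (only meaningful for the DEAD group).
#' @return an object of class `ibm_group`.
#' @export
ibm_group <- function(name, density, division_diameter = Inf,
                      death_diameter = 0, decay_rate = 0, yield = 1,
                      pathways = list(), eps = NULL, active = TRUE,
                      adhesive = NULL, lysis_rate = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("group name must be a non-empty string")
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  if (death_diameter < 0) stop("death_diameter must be >= 0")
  if (division_diameter <= death_diameter)
    stop("division_diameter must exceed death_diameter")
  if (decay_rate < 0 || lysis_rate < 0) stop("rates must be >= 0")
  if (yield <= 0 || yield > 1) stop("yield must lie in (0, 1]")
  for (pw in pathways) {
    if (is.null(pw$mumax) || pw$mumax < 0) stop("pathway mumax must be >= 0")
    if (!is.null(pw$K) && any(unlist(pw$K) < 0)) stop("half-saturation constants must be >= 0")
  }
  if (!is.null(eps)) {
    if (is.null(eps$density) || eps$density <= 0) stop("eps$density must be positive")
    if (is.null(eps$yield) || eps$yield < 0) stop("eps$yield must be >= 0")
    if (is.null(eps$shell_ratio) || eps$shell_ratio <= 1)
      stop("eps$shell_ratio must exceed 1")
  }
  if (is.null(adhesive)) adhesive <- !is.null(eps) || identical(name, "EPS")
  structure(list(name = name, density = density,
                 division_diameter = division_diameter,
                 death_diameter = death_diameter, decay_rate = decay_rate,
                 yield = yield, pathways = pathways, eps = eps,
                 active = active, adhesive = adhesive,
                 lysis_rate = lysis_rate),
            class = "ibm_group")
}

#' Construct an empty or validated particle table
#'
#' The particle table is a data frame with one row per agent: id, functional
#' group, position, velocity, force accumulator, mass, density, core diameter,
#' EPS shell mass (`outer_mass`), outer diameter and current net growth rate.
#' An attribute `next_id` holds the next never-used id; ids are never reused
#' within a run.
#'
#' @param df optional data frame with the particle columns.
#' @return a `data.frame` of class `ibm_particles`.
#' @export
new_particles <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(id = integer(), group = character(),
                     x = numeric(), y = numeric(), z = numeric(),
                     vx = numeric(), vy = numeric(), vz = numeric(),
                     fx = numeric(), fy = numeric(), fz = numeric(),
                     mass = numeric(), density = numeric(),
                     diameter = numeric(), outer_mass = numeric(),
                     outer_diameter = numeric(), mu = numeric(),
                     stringsAsFactors = FALSE)
  }
  missing <- setdiff(PARTICLE_COLS, names(df))
  if (length(missing))
    stop("particle table misses columns: ", paste(missing, collapse = ", "))
  df <- df[, PARTICLE_COLS]
  if (anyDuplicated(df$id)) stop("particle ids must be unique")
  if (any(df$mass <= 0)) stop("particle masses must be positive")
  if (any(df$outer_mass < 0)) stop("outer_mass must be >= 0")
  if (any(df$outer_diameter < df$diameter - 1e-15 * df$diameter))
    stop("outer_diameter must be >= diameter")
  attr(df, "next_id") <- if (nrow(df)) max(df$id) + 1L else 1L
  class(df) <- c("ibm_particles", "data.frame")
  df
}

#' Create particles of a given group
#'
#' Convenience constructor deriving mass from diameter and density and the
#' outer diameter from an optional shell mass.
#'
#' @param group an [ibm_group()].
#' @param position n x 3 matrix of centre positions (m).
#' @param diameter core diameter(s) (m).
#' @param outer_mass EPS shell mass(es) (kg), default 0.
#' @param id optional integer ids; auto-assigned from 1 if omitted.
#' @return an `ibm_particles` table.
#' @export
make_particles <- function(group, position, diameter, outer_mass = 0,
                           id = NULL) {
  pos <- matrix(as.numeric(position), ncol = 3L)
  n <- nrow(pos)
  diameter <- rep_len(diameter, n)
  outer_mass <- rep_len(outer_mass, n)
  if (is.null(id)) id <- seq_len(n)
  eps_rho <- if (!is.null(group$eps)) group$eps$density else group$density
  df <- data.frame(id = as.integer(id), group = group$name,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   vx = 0, vy = 0, vz = 0, fx = 0, fy = 0, fz = 0,
                   mass = mass_from_diameter(diameter, group$density),
                   density = group$density, diameter = diameter,
                   outer_mass = outer_mass,
                   outer_diameter = outer_diameter_from_shell(diameter,
                                                              outer_mass,
                                                              eps_rho),
                   mu = 0, stringsAsFactors = FALSE)
  new_particles(df)
}

# Append rows to a particle table, preserving and advancing the id counter.
append_particles <- function(particles, extra) {
  nid <- attr(particles, "next_id")
  out <- rbind(as.data.frame(particles), as.data.frame(extra))
  attr(out, "next_id") <- max(nid, if (nrow(out)) max(out$id) + 1L else 1L)
  class(out) <- c("ibm_particles", "data.frame")
  out
}

# Reserve `n` fresh ids from the table's counter.
take_ids <- function(particles, n) {
  nid <- attr(particles, "next_id")
  seq.int(nid, length.out = n)
}

#' @export
print.ibm_particles <- function(x, ...) {
  cat(sprintf("<ibm_particles> %d agents", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$group)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# Total occupied volume (outer spheres) of a particle set.
particle_volumes <- function(particles) {
  pi * particles$outer_diameter^3 / 6
}

# Group lookup: named list of ibm_group keyed by name.
group_of <- function(groups, name) {
  g <- groups[[name]]
  if (is.null(g)) stop("unknown functional group: ", name)
  g
}

# Per-particle group field extraction, vectorised over the table.
group_field <- function(particles, groups, field, default = NA_real_) {
  vals <- vapply(groups, function(g) {
    v <- g[[field]]
    if (is.null(v)) default else as.numeric(v)
  }, numeric(1))
  unname(vals[match(particles$group, names(vals))])
}
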