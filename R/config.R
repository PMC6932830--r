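# Declarative simulation configuration: YAML parsing, validation with
# defaults, serialisation, and builders for the model objects.

CONFIG_DEFAULTS <- list(
  kinetics = "monod",
  division_distance = "radius_sum",
  lysis_solute = "sub",
  seed = 1L,
  timesteps = list(bio = 900, diffusion = NULL, mechanical = 1e-7,
                   t_end = 900),
  solver = list(diffusion_tol = 1e-6, max_sweeps = 200000L,
                pressure_tol = 1e-3, relax_max_steps = 5000L,
                relax_window = 100L),
  processes = c("mass_balance", "bulk", "growth", "division", "death",
                "eps", "mechanics"),
  output = list(every = 1L, dir = NULL, vtk = FALSE)
)

KNOWN_PROCESSES <- c("mass_balance", "bulk", "growth", "division", "death",
                     "eps", "lysis", "mechanics")

CONFIG_KEYS <- list(
  top = c("domain", "groups", "solutes", "bulk", "mechanics", "timesteps",
          "solver", "processes", "kinetics", "division_distance",
          "lysis_solute", "seed", "output", "energy", "acid_base"),
  domain = c("lengths", "voxel", "periodic", "boundary_layer"),
  group = c("density", "division_diameter", "death_diameter", "decay_rate",
            "yield", "active", "adhesive", "eps", "pathways", "lysis_rate"),
  eps = c("density", "yield", "shell_ratio"),
  pathway = c("mumax", "eta", "K", "stoich", "inhibition"),
  solute = c("diffusion", "bulk", "influent", "fixed_bulk", "molar_mass",
             "acid_base", "gas"),
  gas = c("KLa", "KH", "Sgas"),
  bulk = c("Q", "V", "A_f"),
  mechanics = c("Kn", "gamma_n", "Ha", "h_floor", "adhesion_cutoff",
                "mu_fluid", "viscous", "z_top", "pressure_floor"),
  timesteps = c("bio", "diffusion", "mechanical", "t_end"),
  solver = c("diffusion_tol", "max_sweeps", "pressure_tol",
             "relax_max_steps", "relax_window"),
  output = c("every", "dir", "vtk")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")))
}

# Overlay defaults onto a (possibly partial) list, one level deep.
fill_defaults <- function(x, defaults) {
  if (is.null(x)) return(defaults)
  for (k in names(defaults)) {
    if (is.null(x[[k]])) x[k] <- defaults[k]
  }
  x
}

#' Parse and validate a simulation configuration
#'
#' The configuration is a YAML document with sections `domain`, `groups`,
#' `solutes`, `bulk`, `mechanics`, `timesteps`, `solver`, `processes`,
#' `output` and scalar options (`kinetics`, `division_distance`,
#' `lysis_solute`, `seed`). Unknown keys are rejected with their location;
#' omitted optional values receive documented defaults. The mandatory
#' sections are `domain` and `groups`.
#'
#' @param text a YAML string, a parsed list, or the path of a YAML file.
#' @return a validated configuration of class `ibm_config`.
#' @export
parse_config <- function(text) {
  cfg <- if (is.list(text)) {
    text
  } else if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    yaml::read_yaml(text)
  } else {
    yaml::yaml.load(paste(text, collapse = "\n"))
  }
  if (!is.list(cfg)) stop("configuration must be a mapping")
  check_keys(cfg, CONFIG_KEYS$top, "configuration")
  for (k in c("domain", "groups"))
    if (is.null(cfg[[k]])) stop("missing mandatory section: ", k)

  check_keys(cfg$domain, CONFIG_KEYS$domain, "domain")
  cfg$domain <- fill_defaults(cfg$domain,
                              list(periodic = c(TRUE, TRUE, FALSE),
                                   boundary_layer = 0))
  if (is.null(cfg$domain$lengths) || is.null(cfg$domain$voxel))
    stop("domain needs 'lengths' and 'voxel'")

  for (g in names(cfg$groups)) {
    check_keys(cfg$groups[[g]], CONFIG_KEYS$group, paste0("groups/", g))
    grp <- fill_defaults(cfg$groups[[g]],
                         list(division_diameter = Inf, death_diameter = 0,
                              decay_rate = 0, yield = 1, active = TRUE,
                              lysis_rate = 0))
    if (!is.null(grp$eps))
      check_keys(grp$eps, CONFIG_KEYS$eps, paste0("groups/", g, "/eps"))
    for (p in names(grp$pathways)) {
      check_keys(grp$pathways[[p]], CONFIG_KEYS$pathway,
                 paste0("groups/", g, "/pathways/", p))
      if (is.null(grp$pathways[[p]]$mumax))
        stop(sprintf("pathway %s of group %s needs mumax", p, g))
      grp$pathways[[p]] <- fill_defaults(grp$pathways[[p]], list(eta = 1))
    }
    cfg$groups[[g]] <- grp
  }

  for (s in names(cfg$solutes)) {
    check_keys(cfg$solutes[[s]], CONFIG_KEYS$solute, paste0("solutes/", s))
    if (is.null(cfg$solutes[[s]]$diffusion))
      stop(sprintf("solute %s needs a diffusion coefficient", s))
    cfg$solutes[[s]] <- fill_defaults(cfg$solutes[[s]],
                                      list(bulk = 0, influent = 0,
                                           fixed_bulk = FALSE))
    if (!is.null(cfg$solutes[[s]]$gas))
      check_keys(cfg$solutes[[s]]$gas, CONFIG_KEYS$gas,
                 paste0("solutes/", s, "/gas"))
  }

  if (!is.null(cfg$bulk)) check_keys(cfg$bulk, CONFIG_KEYS$bulk, "bulk")
  if (!is.null(cfg$mechanics))
    check_keys(cfg$mechanics, CONFIG_KEYS$mechanics, "mechanics")
  if (!is.null(cfg$timesteps))
    check_keys(cfg$timesteps, CONFIG_KEYS$timesteps, "timesteps")
  if (!is.null(cfg$solver)) check_keys(cfg$solver, CONFIG_KEYS$solver, "solver")
  if (!is.null(cfg$output)) check_keys(cfg$output, CONFIG_KEYS$output, "output")

  cfg$timesteps <- fill_defaults(cfg$timesteps, CONFIG_DEFAULTS$timesteps)
  cfg$solver <- fill_defaults(cfg$solver, CONFIG_DEFAULTS$solver)
  cfg$output <- fill_defaults(cfg$output, CONFIG_DEFAULTS$output)
  for (k in c("kinetics", "division_distance", "lysis_solute", "seed",
              "processes"))
    if (is.null(cfg[[k]])) cfg[k] <- CONFIG_DEFAULTS[k]

  if (!cfg$kinetics %in% c("monod", "energy"))
    stop("kinetics must be 'monod' or 'energy'")
  if (!cfg$division_distance %in% c("radius_sum", "diameter_sum"))
    stop("division_distance must be 'radius_sum' or 'diameter_sum'")
  bad <- setdiff(cfg$processes, KNOWN_PROCESSES)
  if (length(bad))
    stop("unknown process name(s): ", paste(bad, collapse = ", "))
  dt <- cfg$timesteps
  if (!is.null(dt$diffusion) && dt$mechanical > dt$diffusion)
    stop("timesteps must satisfy mechanical <= diffusion <= bio")
  if (!is.null(dt$diffusion) && dt$diffusion > dt$bio)
    stop("timesteps must satisfy mechanical <= diffusion <= bio")

  # validate buildable objects early so errors name their section
  config_domain(cfg)
  config_groups(cfg)
  config_solutes(cfg)
  structure(cfg, class = "ibm_config")
}

#' Serialise a configuration back to YAML
#'
#' `parse_config(serialize_config(cfg))` reproduces `cfg` exactly.
#'
#' @param config an `ibm_config`.
#' @return a YAML string.
#' @export
serialize_config <- function(config) {
  yaml::as.yaml(unclass(config), precision = 15L)
}

# ---- builders -------------------------------------------------------------

config_domain <- function(config) {
  d <- config$domain
  ibm_domain(unlist(d$lengths), unlist(d$periodic), d$boundary_layer)
}

config_grid <- function(config) {
  build_grid(config_domain(config), config$domain$voxel)
}

config_groups <- function(config) {
  out <- lapply(names(config$groups), function(g) {
    grp <- config$groups[[g]]
    pathways <- lapply(grp$pathways, function(pw) {
      list(mumax = pw$mumax, eta = if (is.null(pw$eta)) 1 else pw$eta,
           K = unlist(pw$K), stoich = unlist(pw$stoich),
           inhibition = unlist(pw$inhibition))
    })
    ibm_group(g, density = grp$density,
              division_diameter = grp$division_diameter %||% Inf,
              death_diameter = grp$death_diameter %||% 0,
              decay_rate = grp$decay_rate %||% 0,
              yield = grp$yield %||% 1,
              pathways = pathways, eps = grp$eps,
              active = grp$active %||% TRUE,
              adhesive = grp$adhesive, lysis_rate = grp$lysis_rate %||% 0)
  })
  stats::setNames(out, names(config$groups))
}

config_solutes <- function(config) {
  out <- lapply(names(config$solutes), function(s) {
    sp <- config$solutes[[s]]
    ibm_solute(s, diffusion = sp$diffusion, bulk = sp$bulk %||% 0,
               influent = sp$influent %||% 0,
               fixed_bulk = isTRUE(sp$fixed_bulk),
               molar_mass = sp$molar_mass, acid_base = sp$acid_base,
               gas = sp$gas)
  })
  stats::setNames(out, names(config$solutes))
}

config_bulk <- function(config) {
  specs <- config_solutes(config)
  Sb <- vapply(specs, function(s) s$bulk, numeric(1))
  Sin <- vapply(specs, function(s) s$influent, numeric(1))
  fixed <- vapply(specs, function(s) s$fixed_bulk, logical(1))
  b <- config$bulk
  if (is.null(b)) b <- list(Q = 0, V = 1, A_f = 0)
  ibm_bulk(b$Q, b$V, b$A_f, Sb, Sin, fixed)
}

config_force_params <- function(config) {
  m <- config$mechanics
  if (is.null(m)) return(ibm_force_params())
  args <- m[intersect(names(m), names(formals(ibm_force_params)))]
  do.call(ibm_force_params, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
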