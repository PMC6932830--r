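# Seeded generators for initial states and ready-to-run test scenarios, so
# every module is exercisable without external data.

#' Specify an inoculum
#'
#' @param counts named integer vector: particles per functional group.
#' @param mode placement: `"random_substratum"` (z = radius, random x/y),
#'   `"lattice"` (regular grid on the substratum) or `"random_box"`.
#' @param diameter fixed diameter (m) or length-2 range for uniform sampling;
#'   must lie strictly between the groups' death and division thresholds.
#' @return an object of class `ibm_inoculum`.
#' @export
ibm_inoculum <- function(counts, mode = c("random_substratum", "lattice",
                                          "random_box"),
                         diameter = 1e-6) {
  mode <- match.arg(mode)
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(counts = counts, mode = mode, diameter = diameter),
            class = "ibm_inoculum")
}

#' Place the initial community in a domain
#'
#' Substratum modes rest every particle on the bottom face (z = radius).
#' Random placements use rejection sampling to forbid core-sphere overlaps;
#' the layout is deterministic for a fixed RNG seed. 1e4 consecutive
#' rejections raise a packing error.
#'
#' @param spec an [ibm_inoculum()].
#' @param domain an [ibm_domain()].
#' @param groups named list of [ibm_group()] covering the requested names.
#' @return an `ibm_particles` table.
#' @export
inoculate <- function(spec, domain, groups) {
  total <- sum(spec$counts)
  particles <- new_particles()
  if (total == 0L) return(particles)
  draw_d <- function(n) {
    if (length(spec$diameter) == 2L)
      stats::runif(n, spec$diameter[1], spec$diameter[2])
    else rep(spec$diameter, n)
  }
  if (spec$mode == "lattice") {
    side <- ceiling(sqrt(total))
    sx <- domain$L[1] / side
    sy <- domain$L[2] / side
    k <- seq_len(total) - 1L
    gx <- (k %% side + 0.5) * sx
    gy <- (k %/% side + 0.5) * sy
    d <- draw_d(total)
    pos <- cbind(gx, gy, d / 2)
  } else {
    d <- draw_d(total)
    footprint <- sum(pi * (d / 2)^2)
    if (spec$mode == "random_substratum" &&
        footprint >= domain$L[1] * domain$L[2])
      stop("requested packing infeasible: inoculum footprint exceeds the substratum")
    pos <- matrix(NA_real_, total, 3L)
    rejects <- 0L
    placed <- 0L
    while (placed < total) {
      i <- placed + 1L
      cand <- c(stats::runif(1, 0, domain$L[1]),
                stats::runif(1, 0, domain$L[2]),
                if (spec$mode == "random_box")
                  stats::runif(1, d[i] / 2, domain$L[3] - d[i] / 2)
                else d[i] / 2)
      ok <- TRUE
      if (placed > 0L) {
        dd <- sweep(pos[seq_len(placed), , drop = FALSE], 2L, cand, "-")
        for (ax in 1:2) {
          if (domain$periodic[ax]) {
            L <- domain$L[ax]
            dd[, ax] <- dd[, ax] - L * round(dd[, ax] / L)
          }
        }
        rmin <- (d[seq_len(placed)] + d[i]) / 2
        ok <- all(rowSums(dd^2) >= rmin^2)
      }
      if (ok) {
        pos[i, ] <- cand
        placed <- placed + 1L
        rejects <- 0L
      } else {
        rejects <- rejects + 1L
        if (rejects >= 1e4)
          stop("packing error: 1e4 consecutive rejections while placing the inoculum")
      }
    }
  }
  grp_names <- rep(names(spec$counts), spec$counts)
  out <- NULL
  offset <- 0L
  for (g in unique(grp_names)) {
    sel <- which(grp_names == g)
    p <- make_particles(group_of(groups, g), pos[sel, , drop = FALSE],
                        d[sel], id = sel)
    out <- if (is.null(out)) p else append_particles(out, as.data.frame(p))
  }
  out
}

# Shared nitrifying-community parameter set: three active functional groups
# (heterotrophs with an EPS shell, ammonia oxidisers, nitrite oxidisers) plus
# inert EPS and DEAD types, five soluble species, ASM-style kinetics.
nitrifying_config_list <- function() {
  Y_H <- 0.61; Y_E <- 0.18; Y_A <- 0.33; Y_N <- 0.083
  list(
    domain = list(lengths = c(1e-4, 1e-4, 1e-4), voxel = 1e-5,
                  periodic = c(TRUE, TRUE, FALSE), boundary_layer = 2e-5),
    groups = list(
      HET = list(density = 150, division_diameter = 1.3e-6,
                 death_diameter = 4e-7, decay_rate = 4.63e-6, yield = Y_H,
                 eps = list(density = 30, yield = Y_E, shell_ratio = 1.25),
                 pathways = list(
                   aerobic = list(
                     mumax = 6.94e-5, eta = 1,
                     K = list(sub = 4e-3, o2 = 2e-4),
                     stoich = list(sub = -1 / Y_H,
                                   o2 = -(1 - Y_H - Y_E) / Y_H)),
                   anoxic_no3 = list(
                     mumax = 6.94e-5, eta = 0.6,
                     K = list(sub = 4e-3, no3 = 5e-4),
                     inhibition = list(o2 = 2e-4),
                     stoich = list(sub = -1 / Y_H,
                                   no3 = -(1 - Y_H - Y_E) / (2.86 * Y_H))),
                   anoxic_no2 = list(
                     mumax = 6.94e-5, eta = 0.6,
                     K = list(sub = 4e-3, no2 = 3e-4),
                     inhibition = list(o2 = 2e-4),
                     stoich = list(sub = -1 / Y_H,
                                   no2 = -(1 - Y_H - Y_E) / (1.71 * Y_H))))),
      AOB = list(density = 150, division_diameter = 1.3e-6,
                 death_diameter = 4e-7, decay_rate = 1.27e-6, yield = Y_A,
                 pathways = list(
                   aerobic = list(
                     mumax = 1.16e-5, eta = 1,
                     K = list(nh4 = 1e-3, o2 = 5e-4),
                     stoich = list(nh4 = -1 / Y_A,
                                   o2 = -(3.42 - Y_A) / Y_A,
                                   no2 = 1 / Y_A)))),
      NOB = list(density = 150, division_diameter = 1.3e-6,
                 death_diameter = 4e-7, decay_rate = 6.94e-7, yield = Y_N,
                 pathways = list(
                   aerobic = list(
                     mumax = 9.15e-6, eta = 1,
                     K = list(no2 = 1.3e-3, o2 = 6.8e-4),
                     stoich = list(no2 = -1 / Y_N,
                                   o2 = -(1.15 - Y_N) / Y_N,
                                   no3 = 1 / Y_N)))),
      EPS = list(density = 30, active = FALSE, adhesive = TRUE,
                 death_diameter = 0),
      DEAD = list(density = 150, active = FALSE, lysis_rate = 1e-6,
                  death_diameter = 4e-7)   # removal below a tenth of this
    ),
    solutes = list(
      sub = list(diffusion = 1.6e-9, bulk = 4e-3, influent = 4e-3),
      o2 = list(diffusion = 2.3e-9, bulk = 0.01, influent = 0.01,
                fixed_bulk = TRUE),
      nh4 = list(diffusion = 1.8e-9, bulk = 0.03, influent = 0.03),
      no2 = list(diffusion = 1.7e-9, bulk = 0, influent = 0),
      no3 = list(diffusion = 1.7e-9, bulk = 0, influent = 0)
    ),
    bulk = list(Q = 5e-11, V = 1e-6, A_f = 3e-2),
    mechanics = list(Kn = 1e-3, gamma_n = 1e5, Ha = 1e-20, h_floor = 1e-9),
    timesteps = list(bio = 900, mechanical = 1e-7, t_end = 900),
    solver = list(diffusion_tol = 1e-5, relax_max_steps = 800L,
                  relax_window = 50L),
    processes = c("mass_balance", "bulk", "growth", "division", "death",
                  "eps", "lysis", "mechanics"),
    seed = 1L
  )
}

#' Ready-made small scenarios
#'
#' Returns a parsed configuration and matching initial particle state for
#' one of the registered scenarios:
#' \describe{
#'   \item{flat_film}{a complete monolayer of heterotrophs on the substratum
#'     (initial surface roughness 0), single solute.}
#'   \item{two_particle_overlap}{two heterotrophs overlapping by 10% of a
#'     radius; mechanics only.}
#'   \item{mushroom_colony}{a hemispherical heterotroph cluster for
#'     morphology statistics.}
#'   \item{nitrifying_community}{heterotrophs, ammonia oxidisers and nitrite
#'     oxidisers inoculated 40 cells strong on the substratum of a
#'     100 x 100 x 100 um domain, five solutes, chemostat bulk; the
#'     multi-functional-group biofilm configuration.}
#'   \item{decay_only}{starving heterotrophs (no growth pathways, first-order
#'     decay) exercising death, removal and lysis.}
#' }
#'
#' @param name scenario name.
#' @param seed RNG seed stored in the config.
#' @return list with `config` (an `ibm_config`) and `state`
#'   (list with `particles`).
#' @export
make_scenario <- function(name = c("flat_film", "two_particle_overlap",
                                   "mushroom_colony", "nitrifying_community",
                                   "decay_only"),
                          seed = 1L) {
  name <- match.arg(name)
  base <- nitrifying_config_list()
  base$seed <- as.integer(seed)
  if (name == "nitrifying_community") {
    base$timesteps$t_end <- 72 * 900
    config <- parse_config(base)
    groups <- config_groups(config)
    set.seed(seed)
    particles <- inoculate(ibm_inoculum(c(HET = 20L, AOB = 10L, NOB = 10L),
                                        "random_substratum",
                                        diameter = c(1e-6, 1.25e-6)),
                           config_domain(config), groups)
    return(list(config = config, state = list(particles = particles)))
  }
  if (name == "flat_film") {
    base$solutes <- base$solutes["sub"]
    base$groups <- base$groups[c("HET", "EPS", "DEAD")]
    base$processes <- c("mass_balance", "growth", "mechanics")
    config <- parse_config(base)
    groups <- config_groups(config)
    dom <- config_domain(config)
    # exact lattice monolayer: one particle per 10 um bin, uniform diameter
    side <- 10L
    xy <- expand.grid(x = (seq_len(side) - 0.5) * dom$L[1] / side,
                      y = (seq_len(side) - 0.5) * dom$L[2] / side)
    particles <- make_particles(groups$HET, cbind(xy$x, xy$y, 5e-7), 1e-6)
    return(list(config = config, state = list(particles = particles)))
  }
  if (name == "two_particle_overlap") {
    base$solutes <- NULL
    base$bulk <- NULL
    base$groups <- base$groups[c("HET", "EPS", "DEAD")]
    base$processes <- "mechanics"
    config <- parse_config(base)
    groups <- config_groups(config)
    r <- 5e-7
    # centres closer than 2r by 10% of a radius
    particles <- make_particles(groups$HET,
                                rbind(c(5e-5, 5e-5, r),
                                      c(5e-5 + 2 * r - 0.1 * r, 5e-5, r)),
                                2 * r)
    return(list(config = config, state = list(particles = particles)))
  }
  if (name == "mushroom_colony") {
    base$solutes <- base$solutes["sub"]
    base$groups <- base$groups[c("HET", "EPS", "DEAD")]
    base$processes <- c("growth", "mechanics")
    config <- parse_config(base)
    groups <- config_groups(config)
    dom <- config_domain(config)
    # hemispherical cap of cells over the domain centre
    set.seed(seed)
    nc <- 120L
    pts <- matrix(stats::rnorm(3L * nc * 40L), ncol = 3L)
    pts[, 3] <- abs(pts[, 3])
    pts <- pts / sqrt(rowSums(pts^2)) *
      (2e-5 * stats::runif(nrow(pts))^(1 / 3))
    pts <- pts[!duplicated(round(pts / 1e-6)), , drop = FALSE]
    pts <- pts[seq_len(min(nc, nrow(pts))), , drop = FALSE]
    centre <- c(dom$L[1] / 2, dom$L[2] / 2, 0)
    pos <- sweep(pts, 2L, centre, "+")
    pos[, 3] <- pmax(pos[, 3], 5e-7)
    particles <- make_particles(groups$HET, pos, 1e-6)
    return(list(config = config, state = list(particles = particles)))
  }
  # decay_only
  base$solutes <- base$solutes["sub"]
  base$groups$HET$pathways <- NULL
  base$groups$HET$decay_rate <- 1e-4
  base$groups <- base$groups[c("HET", "EPS", "DEAD")]
  base$processes <- c("growth", "death", "lysis")
  base$timesteps$t_end <- 20 * 900
  config <- parse_config(base)
  groups <- config_groups(config)
  set.seed(seed)
  particles <- inoculate(ibm_inoculum(c(HET = 10L), "random_substratum",
                                      8e-7),
                         config_domain(config), groups)
  list(config = config, state = list(particles = particles))
}
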