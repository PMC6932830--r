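# Morphology and summary statistics of the community: height map, surface
# roughness, area density, floc equivalent diameter and box-counting fractal
# dimension, per-group biomass totals.

#' Biofilm height map over the substratum
#'
#' Bins the substratum plane into squares of `bin_size` and records, per bin,
#' the top of the highest particle whose centre falls in the bin
#' (`z + outer radius`, EPS shell included); empty bins read 0.
#'
#' @param particles an `ibm_particles` table.
#' @param domain an [ibm_domain()].
#' @param bin_size bin edge (m); must divide `Lx` and `Ly`. Default: the
#'   domain split into 10 bins per axis.
#' @return an object of class `ibm_height_map`: list with matrix `h`
#'   (nx x ny, metres) and `bin_size`.
#' @export
height_map <- function(particles, domain, bin_size = NULL) {
  if (is.null(bin_size)) bin_size <- min(domain$L[1:2]) / 10
  nb <- domain$L[1:2] / bin_size
  if (any(abs(nb - round(nb)) > 1e-9 * pmax(1, nb)))
    stop("bin_size must divide the domain's Lx and Ly")
  nb <- as.integer(round(nb))
  h <- matrix(0, nb[1], nb[2])
  if (nrow(particles)) {
    pos <- wrap_positions(cbind(particles$x, particles$y, particles$z), domain)
    ix <- pmin(nb[1], as.integer(floor(pos[, 1] / bin_size)) + 1L)
    iy <- pmin(nb[2], as.integer(floor(pos[, 2] / bin_size)) + 1L)
    top <- pos[, 3] + particles$outer_diameter / 2
    lin <- ix + nb[1] * (iy - 1L)
    agg <- vapply(split(top, lin), max, numeric(1))
    h[as.integer(names(agg))] <- agg
  }
  structure(list(h = h, bin_size = bin_size), class = "ibm_height_map")
}

#' Mean biofilm height
#'
#' Discrete evaluation of the surface integral
#' `(1 / Lx Ly) Int h(x, y) dx dy` as the bin average.
#'
#' @param map an `ibm_height_map`.
#' @return mean height (m).
#' @export
average_height <- function(map) {
  mean(map$h)
}

#' Biofilm surface roughness
#'
#' Discrete form of `sqrt((1 / Lx Ly) Int (h - hbar)^2 dx dy)`: the
#' population standard deviation of the bin heights. Zero for a flat film
#' and invariant to adding a constant to all heights.
#'
#' @param map an `ibm_height_map`.
#' @return roughness (m).
#' @export
roughness <- function(map) {
  h <- map$h
  sqrt(mean((h - mean(h))^2))
}

#' Biomass area density
#'
#' Total biomass (core plus EPS shell mass) per unit substratum area.
#'
#' @param particles an `ibm_particles` table.
#' @param domain an [ibm_domain()].
#' @return area density (kg m^-2).
#' @export
area_density <- function(particles, domain) {
  (sum(particles$mass) + sum(particles$outer_mass)) /
    (domain$L[1] * domain$L[2])
}

#' Floc equivalent diameter and box-counting fractal dimension
#'
#' The equivalent diameter is the diameter of the sphere matching the summed
#' particle volumes. The fractal dimension is estimated by box counting over
#' particle centres: occupied-box counts `N(l)` at `n_scales` dyadic box
#' sizes, least-squares slope of `log N` against `log(1/l)`. A single
#' particle has no defined dimension (`NA`).
#'
#' @param particles an `ibm_particles` table with at least one row.
#' @param n_scales number of dyadic box scales (>= 4).
#' @return list with `equivalent_diameter` (m) and `fractal_dimension`.
#' @export
floc_stats <- function(particles, n_scales = 5L) {
  if (nrow(particles) == 0L) stop("floc statistics need at least one particle")
  vol <- sum(particle_volumes(particles))
  deq <- (6 * vol / pi)^(1 / 3)
  fd <- NA_real_
  if (nrow(particles) > 1L && n_scales >= 4L) {
    pos <- cbind(particles$x, particles$y, particles$z)
    lo <- apply(pos, 2L, min)
    extent <- max(apply(pos, 2L, max) - lo)
    if (extent > 0) {
      # dyadic grids of 2^s boxes per side covering the bounding cube
      side <- extent * (1 + 1e-9)
      rel <- sweep(pos, 2L, lo, "-") / side
      scales <- side / 2^seq_len(n_scales)
      counts <- vapply(seq_len(n_scales), function(s) {
        key <- floor(rel * 2^s)
        nrow(unique(key))
      }, numeric(1))
      fit <- stats::lm.fit(cbind(1, log(1 / scales)), log(counts))
      fd <- unname(fit$coefficients[2])
    }
  }
  list(equivalent_diameter = deq, fractal_dimension = fd)
}

#' Per-group biomass totals
#'
#' @param particles an `ibm_particles` table.
#' @param groups named list of [ibm_group()]; fixes the output ordering.
#' @return named numeric vector of total mass (core + shell, kg) per group.
#' @export
group_biomass <- function(particles, groups) {
  out <- stats::setNames(numeric(length(groups)), names(groups))
  if (nrow(particles)) {
    tot <- particles$mass + particles$outer_mass
    agg <- rowsum(tot, particles$group)
    out[rownames(agg)] <- agg[, 1]
  }
  out
}
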