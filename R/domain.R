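# Region codes for the z-layered decomposition of the computational domain.
REGION_BIOFILM <- 1L
REGION_BOUNDARY_LAYER <- 2L
REGION_BULK <- 3L

#' Define the rectangular computational domain
#'
#' The domain is a micro-scale 3D rectangular box `Lx x Ly x Lz` holding the
#' microbial agents and the voxelised solute fields. The substratum is always
#' the bottom face (z = 0). Faces can be periodic (particles and solute
#' stencils wrap) or fixed; periodicity applies per axis, i.e. to a face pair.
#'
#' @param lengths numeric length-3, box dimensions in metres (`Lx, Ly, Lz`).
#' @param periodic logical length-3, per-axis periodicity. The z axis must be
#'   fixed because the substratum lives at z = 0.
#' @param boundary_layer height (m) of the diffusion boundary layer measured
#'   upward from the maximum biofilm thickness.
#' @return an object of class `ibm_domain`.
#' @examples
#' dom <- ibm_domain(c(100e-6, 100e-6, 100e-6), boundary_layer = 20e-6)
#' @export
ibm_domain <- function(lengths, periodic = c(TRUE, TRUE, FALSE),
                       boundary_layer = 0) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("domain lengths must be three positive numbers")
  periodic <- as.logical(periodic)
  if (length(periodic) != 3L || any(is.na(periodic)))
    stop("periodic must be three logicals")
  if (periodic[3L])
    stop("the z axis cannot be periodic: the substratum is the bottom face")
  if (!is.finite(boundary_layer) || boundary_layer < 0)
    stop("boundary_layer height must be >= 0")
  structure(list(L = lengths, periodic = periodic,
                 boundary_layer = as.numeric(boundary_layer)),
            class = "ibm_domain")
}

#' @export
print.ibm_domain <- function(x, ...) {
  cat(sprintf("<ibm_domain> %.3g x %.3g x %.3g m, periodic: %s%s%s, boundary layer %.3g m\n",
              x$L[1], x$L[2], x$L[3],
              if (x$periodic[1]) "x" else "-",
              if (x$periodic[2]) "y" else "-",
              if (x$periodic[3]) "z" else "-",
              x$boundary_layer))
  invisible(x)
}

#' Discretise a domain into a uniform cubic voxel grid
#'
#' Voxels are cubes of edge `voxel_size` with scalar values stored at voxel
#' centres (marker-and-cell layout). The voxel size must divide every domain
#' length exactly (to a relative tolerance of 1e-9). All region labels start
#' as bulk liquid; call [update_regions()] once particles exist.
#'
#' @param domain an [ibm_domain()].
#' @param voxel_size voxel edge length (m), identical on all axes.
#' @return an object of class `ibm_grid` with fields `dx`, `n` (voxel counts),
#'   `domain` and `region` (integer array of per-voxel labels).
#' @examples
#' g <- build_grid(ibm_domain(c(1e-4, 1e-4, 1e-4)), 1e-5)
#' g$n   # 10 10 10
#' @export
build_grid <- function(domain, voxel_size) {
  stopifnot(inherits(domain, "ibm_domain"))
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be positive")
  nreal <- domain$L / voxel_size
  for (ax in 1:3) {
    if (abs(nreal[ax] - round(nreal[ax])) > 1e-9 * max(1, nreal[ax]))
      stop(sprintf("voxel size %g does not divide the %s-axis domain length %g",
                   voxel_size, c("x", "y", "z")[ax], domain$L[ax]))
  }
  n <- as.integer(round(nreal))
  structure(list(dx = as.numeric(voxel_size), n = n, domain = domain,
                 region = array(REGION_BULK, dim = n)),
            class = "ibm_grid")
}

#' @export
print.ibm_grid <- function(x, ...) {
  tab <- tabulate(x$region, 3L)
  cat(sprintf("<ibm_grid> %d x %d x %d voxels, dx = %.3g m (biofilm %d / boundary layer %d / bulk %d)\n",
              x$n[1], x$n[2], x$n[3], x$dx, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Voxel centre coordinates along one axis
#'
#' @param grid an `ibm_grid`.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return numeric vector of centre coordinates `(i - 1/2) * dx`.
#' @export
voxel_centres <- function(grid, axis) {
  (seq_len(grid$n[axis]) - 0.5) * grid$dx
}

# Wrap positions onto the primary cell on periodic axes; error if a position
# lies outside a fixed face. `pos` is an n x 3 matrix.
wrap_positions <- function(pos, domain) {
  pos <- matrix(as.numeric(pos), ncol = 3L)
  for (ax in 1:3) {
    if (domain$periodic[ax]) {
      pos[, ax] <- pos[, ax] %% domain$L[ax]
    } else if (any(pos[, ax] < 0 | pos[, ax] > domain$L[ax])) {
      stop(sprintf("position outside the fixed %s-axis boundary",
                   c("x", "y", "z")[ax]))
    }
  }
  pos
}

#' Locate the voxel containing each position
#'
#' Voxels are half-open intervals `[(i-1) dx, i dx)` along each axis, so a
#' point exactly on a voxel face belongs to the upper voxel (except at the
#' very top of a fixed axis, where the index is clamped to the last voxel).
#' Positions on periodic axes are wrapped first; positions outside a fixed
#' face raise an error.
#'
#' @param grid an `ibm_grid`.
#' @param position a 3-vector or an n x 3 matrix of positions (m).
#' @return an n x 3 integer matrix of 1-based voxel indices `(i, j, k)`.
#' @export
locate_voxel <- function(grid, position) {
  pos <- wrap_positions(position, grid$domain)
  idx <- matrix(0L, nrow = nrow(pos), ncol = 3L)
  for (ax in 1:3) {
    i <- as.integer(floor(pos[, ax] / grid$dx)) + 1L
    idx[, ax] <- pmin(pmax(i, 1L), grid$n[ax])
  }
  idx
}

# Linear (column-major) voxel index from an n x 3 index matrix.
voxel_linear_index <- function(grid, idx) {
  idx[, 1L] + grid$n[1L] * ((idx[, 2L] - 1L) + grid$n[2L] * (idx[, 3L] - 1L))
}

#' Relabel grid voxels as biofilm, boundary layer or bulk liquid
#'
#' The biofilm thickness is the maximum over particles of `z + outer radius`
#' (EPS shell included), zero with no particles. The biofilm/boundary-layer
#' interface is snapped up to the next voxel face so regions conform to whole
#' voxels; the boundary layer extends a user-set height above it, and the
#' rest of the column is perfectly mixed bulk liquid.
#'
#' @param grid an `ibm_grid`.
#' @param particles a particle table (see [new_particles()]); may be empty.
#' @param layer_height boundary-layer height (m); defaults to the domain's.
#' @return the grid with its `region` array updated.
#' @export
update_regions <- function(grid, particles,
                           layer_height = grid$domain$boundary_layer) {
  H <- biofilm_thickness(particles)
  dx <- grid$dx
  nz <- grid$n[3L]
  # snap interfaces up to the next voxel face
  k_bio <- min(nz, as.integer(ceiling(H / dx - 1e-12)))
  k_lay <- min(nz, k_bio + as.integer(ceiling(layer_height / dx - 1e-12)))
  if (k_bio * dx + layer_height > grid$domain$L[3L] + 1e-15)
    warning("boundary layer truncated by the domain top; bulk region may be empty")
  reg <- rep(REGION_BULK, nz)
  if (k_bio >= 1L) reg[seq_len(k_bio)] <- REGION_BIOFILM
  if (k_lay > k_bio) reg[(k_bio + 1L):k_lay] <- REGION_BOUNDARY_LAYER
  grid$region <- array(rep(reg, each = grid$n[1L] * grid$n[2L]), dim = grid$n)
  grid
}

#' Biofilm thickness (top of the highest particle, EPS shell included)
#'
#' @param particles a particle table; may be empty or `NULL`.
#' @return maximum of `z + outer_diameter/2` over particles, 0 if none.
#' @export
biofilm_thickness <- function(particles) {
  if (is.null(particles) || nrow(particles) == 0L) return(0)
  max(particles$z + particles$outer_diameter / 2)
}
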