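# Output writers and restart: plain-text particle state, VTK legacy ASCII
# (polydata for particles, structured points for solute fields), CSV time
# series, and a versioned binary restart.

RESTART_VERSION <- 1L

#' Write / read the plain-text particle state format
#'
#' One record per particle: `id group diameter density x y z outer_diameter`
#' (SI units), whitespace-separated with a `#`-prefixed header line. Shell
#' mass is reconstructed from the outer diameter on read.
#'
#' @param particles an `ibm_particles` table.
#' @param path file path.
#' @param groups named list of [ibm_group()] (read only; supplies EPS shell
#'   density for shell-mass reconstruction).
#' @return `read_particles_txt` returns an `ibm_particles` table;
#'   `write_particles_txt` returns `path` invisibly.
#' @export
write_particles_txt <- function(particles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id group diameter density x y z outer_diameter", con)
  if (nrow(particles)) {
    writeLines(sprintf("%d %s %.12e %.12e %.12e %.12e %.12e %.12e",
                       particles$id, particles$group, particles$diameter,
                       particles$density, particles$x, particles$y,
                       particles$z, particles$outer_diameter), con)
  }
  invisible(path)
}

#' @rdname write_particles_txt
#' @export
read_particles_txt <- function(path, groups) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("id", "group", "diameter", "density",
                                        "x", "y", "z", "outer_diameter"),
                          colClasses = c("integer", "character", rep("numeric", 6)),
                          stringsAsFactors = FALSE)
  eps_rho <- vapply(df$group, function(g) {
    grp <- groups[[g]]
    if (!is.null(grp$eps)) grp$eps$density else grp$density
  }, numeric(1))
  shell <- pmax(0, pi * eps_rho * (df$outer_diameter^3 - df$diameter^3) / 6)
  out <- data.frame(id = df$id, group = df$group,
                    x = df$x, y = df$y, z = df$z,
                    vx = 0, vy = 0, vz = 0, fx = 0, fy = 0, fz = 0,
                    mass = mass_from_diameter(df$diameter, df$density),
                    density = df$density, diameter = df$diameter,
                    outer_mass = unname(shell),
                    outer_diameter = df$outer_diameter, mu = 0,
                    stringsAsFactors = FALSE)
  new_particles(out)
}

#' Write particles as VTK legacy polydata (ASCII)
#'
#' Emits points plus per-point data: radius, outer radius, integer group id
#' and velocity vectors; readable by ParaView and the VTK toolkit.
#'
#' @param particles an `ibm_particles` table (may be empty).
#' @param path output file path.
#' @param groups named list of [ibm_group()]; fixes the group id coding.
#' @return `path`, invisibly.
#' @export
write_vtk_particles <- function(particles, path, groups) {
  n <- nrow(particles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "microbial community snapshot", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  if (n) writeLines(sprintf("%.9e %.9e %.9e",
                            particles$x, particles$y, particles$z), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS radius double 1", "LOOKUP_TABLE default"), con)
  if (n) writeLines(sprintf("%.9e", particles$diameter / 2), con)
  writeLines(c("SCALARS outer_radius double 1", "LOOKUP_TABLE default"), con)
  if (n) writeLines(sprintf("%.9e", particles$outer_diameter / 2), con)
  writeLines(c("SCALARS group int 1", "LOOKUP_TABLE default"), con)
  if (n) writeLines(sprintf("%d", match(particles$group, names(groups))), con)
  writeLines("VECTORS velocity double", con)
  if (n) writeLines(sprintf("%.9e %.9e %.9e",
                            particles$vx, particles$vy, particles$vz), con)
  invisible(path)
}

#' Write a voxel scalar field as VTK legacy structured points (ASCII)
#'
#' @param field 3D array on the grid's voxels.
#' @param grid an `ibm_grid`.
#' @param path output file path.
#' @param name data-array name in the file.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(field, grid, path, name = "concentration") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("solute field %s", name), "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$n[1], grid$n[2], grid$n[3]),
               sprintf("ORIGIN %.9e %.9e %.9e", grid$dx / 2, grid$dx / 2,
                       grid$dx / 2),
               sprintf("SPACING %.9e %.9e %.9e", grid$dx, grid$dx, grid$dx),
               sprintf("POINT_DATA %d", prod(grid$n)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9e", as.vector(field)), con)  # x fastest (VTK order)
  invisible(path)
}

#' Save / load a versioned simulation restart
#'
#' The restart captures particles, solute fields, bulk state, simulation
#' clock and the random-number-generator state, so a run continued from a
#' restart reproduces the uninterrupted run step for step.
#'
#' @param state a simulation state list (as returned in `run()$state`).
#' @param path restart file path.
#' @return `load_restart` returns the state; a version mismatch or an
#'   unreadable file is an explicit error.
#' @export
save_restart <- function(state, path) {
  payload <- list(version = RESTART_VERSION, state = state)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_restart
#' @export
load_restart <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("unreadable restart file: ",
                                               conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$version))
    stop("unreadable restart file: no version tag")
  if (payload$version != RESTART_VERSION)
    stop(sprintf("restart version mismatch: file %s, supported %d",
                 payload$version, RESTART_VERSION))
  payload$state
}

#' Append one time-series row to a CSV summary file
#'
#' Columns: time, particle count, per-group biomass, average height,
#' roughness, area density.
#'
#' @param history the `history` data frame of a run.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
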