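#' Specification of a synthetic pore geometry
#'
#' Atoms tile the inner wall of a cylinder (or constricted cylinder) of
#' known radius, so the spherical-probe profile has an analytic truth:
#' probe radius = wall radius minus atom van der Waals radius at every
#' axial position.  The default constricted geometry narrows to a wall
#' radius of 2.25 Angstrom, i.e. an analytic probe minimum of 0.75
#' Angstrom with 1.5-Angstrom wall atoms -- the scale of a closed
#' potassium-channel gate at the helical bundle crossing.
#'
#' @param geometry `"cylinder"` or `"constricted"`.
#' @param wall_radius wall radius of the uniform cylinder (Angstrom).
#' @param constriction_radius minimal wall radius of the constricted
#'   geometry.
#' @param constriction_z axial position of the constriction.
#' @param constriction_width Gaussian axial width of the constriction.
#' @param z_range axial extent, length 2 (Angstrom).
#' @param atom_radius van der Waals radius assigned to wall atoms.
#' @param atom_spacing target spacing between wall atoms (axial and
#'   circumferential); spacing coarser than `atom_radius` leaves gaps and
#'   is flagged in the truth record.
#' @param seed RNG seed (recorded; the tiling itself is deterministic).
#' @return list of class `pore_spec`.
#' @export
pore_spec <- function(geometry = c("cylinder", "constricted"),
                      wall_radius = 4.0, constriction_radius = 2.25,
                      constriction_z = 0, constriction_width = 3,
                      z_range = c(-10, 10), atom_radius = 1.5,
                      atom_spacing = 0.5, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(wall_radius > 0, constriction_radius > 0,
            constriction_radius <= wall_radius,
            atom_radius > 0, atom_spacing > 0, length(z_range) == 2,
            z_range[1] < z_range[2], constriction_width > 0)
  structure(list(geometry = geometry, wall_radius = wall_radius,
                 constriction_radius = constriction_radius,
                 constriction_z = constriction_z,
                 constriction_width = constriction_width,
                 z_range = z_range, atom_radius = atom_radius,
                 atom_spacing = atom_spacing, seed = as.integer(seed)),
            class = "pore_spec")
}

.wall_radius_at <- function(spec, z) {
  if (spec$geometry == "cylinder") return(rep(spec$wall_radius, length(z)))
  dip <- (spec$wall_radius - spec$constriction_radius) *
    exp(-((z - spec$constriction_z)^2) / (2 * spec$constriction_width^2))
  spec$wall_radius - dip
}

#' Generate a synthetic pore with analytic probe-radius truth
#'
#' @param spec a [pore_spec()].
#' @return list: `coords` (wall-atom matrix), `elements`, `atom_radii`,
#'   `topology` ([md_topology()]; each axial ring is one residue, so
#'   landmark lookups work), `truth` (data.frame z, wall_radius,
#'   probe_radius; `min` record; `coarse_tiling` flag; seed).
#' @export
gen_pore <- function(spec) {
  stopifnot(inherits(spec, "pore_spec"))
  zs <- seq(spec$z_range[1], spec$z_range[2], by = spec$atom_spacing)
  wall <- .wall_radius_at(spec, zs)
  coords <- NULL; resid <- integer(0)
  for (i in seq_along(zs)) {
    n_ring <- max(8L, ceiling(2 * pi * wall[i] / spec$atom_spacing))
    ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
    coords <- rbind(coords, cbind(wall[i] * cos(ang),
                                  wall[i] * sin(ang),
                                  zs[i]))
    resid <- c(resid, rep(i, n_ring))
  }
  n <- nrow(coords)
  atoms <- data.frame(atom_id = seq_len(n),
                      name = "W", element = "C", mass = 12.011,
                      resid = resid, resname = "POR", chain = "P",
                      stringsAsFactors = FALSE)
  ring_z <- data.frame(resid = seq_along(zs), z = zs,
                       wall_radius = wall,
                       probe_radius = wall - spec$atom_radius)
  i_min <- which.min(ring_z$probe_radius)
  list(coords = coords,
       elements = rep("C", n),
       atom_radii = rep(spec$atom_radius, n),
       topology = md_topology(atoms),
       truth = list(profile = ring_z,
                    min = list(z = ring_z$z[i_min],
                               probe_radius = ring_z$probe_radius[i_min]),
                    coarse_tiling = spec$atom_spacing > spec$atom_radius,
                    seed = spec$seed))
}
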