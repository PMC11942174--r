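#' Bondi van der Waals radii
#'
#' Default per-element van der Waals radii (Angstrom) for pore profiling,
#' from the standard Bondi compilation; any element can be overridden.
#'
#' @param ... named overrides, e.g. `C = 1.8`.
#' @return named numeric vector, element symbol -> radius.
#' @export
bondi_radii <- function(...) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
         S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, K = 2.75, NA. = 2.27)
  names(r)[names(r) == "NA."] <- "NA"
  ov <- list(...)
  for (nm in names(ov)) {
    if (ov[[nm]] <= 0) stop("radii must be positive")
    r[toupper(nm)] <- ov[[nm]]
  }
  r
}

.vdw_for <- function(elements, radii) {
  r <- radii[toupper(elements)]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  as.numeric(r)
}

# largest-probe objective: for probe centre (x, y) in the plane at height z,
# min over atoms of (distance - vdw) is the largest probe radius there
.probe_radius_at <- function(xy, z, ax, ay, az, ar) {
  d <- sqrt((xy[1] - ax)^2 + (xy[2] - ay)^2 + (z - az)^2) - ar
  min(d)
}

#' Spherical-probe pore radius profile
#'
#' HOLE-style profiling: for each plane along the pore axis, find the
#' largest sphere centred in that plane whose surface touches no atom's
#' van der Waals sphere.  Planes are traced in axial order and each
#' plane's lateral search is confined to within `lateral_bound` of the
#' previous plane's probe centre (starting from the axis), which keeps
#' the probe inside the pore lumen -- an unconstrained search would jump
#' outside the wall wherever the channel narrows.  Within that window
#' the search is a deterministic coarse grid refined by a 0.1 Angstrom
#' local grid and a Nelder-Mead polish, replacing HOLE's simulated
#' annealing for exact reproducibility.  Radii are capped at `max_probe`
#' (flagged), and a fully blocked plane reports radius 0.
#'
#' Coordinates are assumed pre-oriented; `axis` is rotated onto z before
#' profiling (the default axis is the channel symmetry axis, +z).
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param elements element symbols, one per atom (for vdW lookup), or a
#'   numeric vector of per-atom radii.
#' @param radii a [bondi_radii()] table (ignored when `elements` is
#'   numeric).
#' @param axis pore axis direction (unit vector, default +z).
#' @param z_range length-2 axial range to profile (default: atom extent).
#' @param z_step axial sampling step (Angstrom).
#' @param max_probe probe-radius cap (Angstrom).
#' @param lateral_bound maximum lateral displacement of the probe centre
#'   between adjacent planes (Angstrom); the first plane searches this
#'   window around the axis.
#' @return object of class `pore_profile`: `profile` (data.frame z,
#'   radius, x, y, capped, blocked), `minimum` (list z, radius, x, y),
#'   `z_step`, `max_probe`.
#' @export
pore_profile <- function(coords, elements, radii = bondi_radii(),
                         axis = c(0, 0, 1), z_range = NULL, z_step = 0.5,
                         max_probe = 5, lateral_bound = 1.5) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, z_step > 0, max_probe > 0)
  axis <- axis / sqrt(sum(axis^2))
  if (abs(sum(axis^2) - 1) > 1e-8) stop("axis must be normalizable")
  # rotate axis onto +z
  zhat <- c(0, 0, 1)
  if (sum((axis - zhat)^2) > 1e-12) {
    v <- .cross3(axis, zhat)
    s <- sqrt(sum(v^2)); cth <- sum(axis * zhat)
    if (s < 1e-12) {                      # antiparallel: flip about x
      R <- diag(c(1, -1, -1))
    } else {
      vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
    }
    coords <- coords %*% t(R)
  }
  ar <- if (is.numeric(elements)) {
    if (length(elements) != nrow(coords))
      stop("per-atom radii length mismatch")
    elements
  } else .vdw_for(elements, radii)
  if (any(ar <= 0)) stop("atom radii must be positive")

  ax <- coords[, 1]; ay <- coords[, 2]; az <- coords[, 3]
  if (is.null(z_range)) z_range <- range(az)
  zs <- seq(z_range[1], z_range[2], by = z_step)

  coarse_off <- as.matrix(expand.grid(
    x = seq(-lateral_bound, lateral_bound, by = 0.25),
    y = seq(-lateral_bound, lateral_bound, by = 0.25)))

  prof <- data.frame(z = zs, radius = NA_real_, x = NA_real_, y = NA_real_,
                     capped = FALSE, blocked = FALSE)
  centre <- c(0, 0)                       # probe path starts on the axis
  for (k in seq_along(zs)) {
    z <- zs[k]
    reach <- max(ar) + max_probe + lateral_bound + sum(abs(centre))
    s <- which(abs(az - z) <= reach)
    if (!length(s)) {
      prof$radius[k] <- max_probe; prof$capped[k] <- TRUE
      prof$x[k] <- centre[1]; prof$y[k] <- centre[2]
      next
    }
    sx <- ax[s]; sy <- ay[s]; sz <- az[s]; sr <- ar[s]
    grid_eval <- function(pts) {
      d <- sqrt(outer(pts[, 1], sx, "-")^2 + outer(pts[, 2], sy, "-")^2 +
                  matrix(rep((z - sz)^2, each = nrow(pts)), nrow(pts))) -
        matrix(rep(sr, each = nrow(pts)), nrow(pts))
      apply(d, 1, min)
    }
    coarse <- sweep(coarse_off, 2, centre, "+")
    f0 <- grid_eval(coarse)
    best <- coarse[which.max(f0), ]
    fine <- as.matrix(expand.grid(
      x = seq(best[1] - 0.25, best[1] + 0.25, by = 0.1),
      y = seq(best[2] - 0.25, best[2] + 0.25, by = 0.1)))
    f1 <- grid_eval(fine)
    start <- fine[which.max(f1), ]
    opt <- stats::optim(start, function(p)
      -.probe_radius_at(p, z, sx, sy, sz, sr),
      method = "Nelder-Mead",
      control = list(reltol = 1e-10, maxit = 500))
    rbest <- -opt$value
    # keep the polished centre inside the tracing window
    if (sqrt(sum((opt$par - centre)^2)) > lateral_bound) {
      rbest <- max(f1)
      opt$par <- start
    }
    prof$x[k] <- opt$par[1]; prof$y[k] <- opt$par[2]
    centre <- as.numeric(opt$par)
    if (rbest <= 0) {
      prof$radius[k] <- 0; prof$blocked[k] <- TRUE
    } else if (rbest >= max_probe) {
      prof$radius[k] <- max_probe; prof$capped[k] <- TRUE
    } else {
      prof$radius[k] <- rbest
    }
  }
  open_rows <- which(!prof$capped)
  i_min <- if (length(open_rows)) open_rows[which.min(prof$radius[open_rows])]
           else which.min(prof$radius)
  structure(list(profile = prof,
                 minimum = list(z = prof$z[i_min],
                                radius = prof$radius[i_min],
                                x = prof$x[i_min], y = prof$y[i_min]),
                 z_step = z_step, max_probe = max_probe),
            class = "pore_profile")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf(
    "Pore profile: %d planes, z in [%.1f, %.1f] A; minimum %.3f A at z = %.2f A\n",
    nrow(x$profile), min(x$profile$z), max(x$profile$z),
    x$minimum$radius, x$minimum$z))
  invisible(x)
}

#' Local minimum of a pore profile near named residues
#'
#' Locates the constriction (e.g. the helical-bundle-crossing gate) as the
#' profile minimum within `+/- window` Angstrom of the mean axial
#' coordinate of the given residues.
#'
#' @param profile a [pore_profile()] result.
#' @param residue_ids residue ids defining the landmark.
#' @param topology an [md_topology()] whose atoms are in the same frame
#'   as the profiled coordinates.
#' @param coords the coordinates the profile was computed from (used for
#'   the residues' axial position).
#' @param window axial half-window (Angstrom, default 5).
#' @return list: `z`, `radius`; warns if the minimum sits on the window
#'   edge (monotone profile within the window).
#' @export
min_radius_near <- function(profile, residue_ids, topology, coords,
                            window = 5) {
  rows <- which(topology$atoms$resid %in% residue_ids)
  if (!length(rows))
    stop("residue(s) not present in topology: ",
         paste(residue_ids, collapse = ", "))
  z0 <- mean(coords[rows, 3])
  prof <- profile$profile
  if (z0 < min(prof$z) - window || z0 > max(prof$z) + window)
    stop("residues lie outside the profiled z-range")
  inwin <- which(abs(prof$z - z0) <= window)
  if (!length(inwin)) stop("no profile samples within the window")
  i <- inwin[which.min(prof$radius[inwin])]
  if (i == min(inwin) || i == max(inwin))
    warning("profile is monotone within the window; endpoint minimum")
  list(z = prof$z[i], radius = prof$radius[i])
}
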