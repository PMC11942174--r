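#' Construct a molecular topology
#'
#' Minimal static description of the system shared by all trajectory
#' frames: one row per atom plus named atom-id selections (e.g. the pocket
#' C-alpha set used for alignment, the ligand atoms, the Kir6.2 distal
#' N-terminal peptide residues).
#'
#' @param atoms data.frame with columns `atom_id` (unique integer),
#'   `name`, `element`, `mass`, `resid` (1-based residue id), `resname`,
#'   `chain`.
#' @param selections named list of integer atom-id vectors.
#' @return object of class `md_topology`.
#' @export
md_topology <- function(atoms, selections = list()) {
  need <- c("atom_id", "name", "element", "mass", "resid", "resname",
            "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$atom_id)) stop("atom ids must be unique")
  for (nm in names(selections)) {
    unknown <- setdiff(selections[[nm]], atoms$atom_id)
    if (length(unknown))
      stop("selection '", nm, "' references unknown atom id(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(atoms = atoms, selections = selections),
            class = "md_topology")
}

#' @export
print.md_topology <- function(x, ...) {
  cat(sprintf("md_topology: %d atoms, %d residues, selections: %s\n",
              nrow(x$atoms), length(unique(x$atoms$resid)),
              paste(names(x$selections), collapse = ", ")))
  invisible(x)
}

is_hydrogen <- function(topology) toupper(topology$atoms$element) == "H"

#' Row indices (into the atom table) of a set of atom ids
#' @noRd
atom_rows <- function(topology, atom_ids) {
  idx <- match(atom_ids, topology$atoms$atom_id)
  if (anyNA(idx))
    stop("unknown atom id(s): ",
         paste(atom_ids[is.na(idx)], collapse = ", "))
  idx
}

#' Construct a multi-run trajectory ensemble
#'
#' @param runs list of coordinate arrays, each `n_frames x n_atoms x 3`
#'   in Angstrom, all sharing the same topology/atom order.
#' @param stride frame stride metadata (frames per stored frame).
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(runs, stride = 1L) {
  stopifnot(is.list(runs), length(runs) >= 1)
  n_atoms <- dim(runs[[1]])[2]
  for (r in seq_along(runs)) {
    d <- dim(runs[[r]])
    if (length(d) != 3 || d[3] != 3)
      stop("run ", r, ": frames must be an n_frames x n_atoms x 3 array")
    if (d[2] != n_atoms)
      stop("run ", r, ": atom count ", d[2], " differs from run 1 (",
           n_atoms, ")")
    if (!all(is.finite(runs[[r]])))
      stop("run ", r, ": non-finite coordinates")
  }
  structure(list(runs = runs, stride = as.integer(stride)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$runs, function(r) dim(r)[1], integer(1))
  cat(sprintf("trajectory_ensemble: %d run(s), frames: %s, %d atoms\n",
              length(x$runs), paste(nf, collapse = "/"),
              dim(x$runs[[1]])[2]))
  invisible(x)
}
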