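#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rigid transform mapping `mobile` onto `reference` over a
#' selection of matched atoms, via singular value decomposition of the
#' covariance matrix with the usual reflection correction, so the returned
#' rotation is always proper (determinant +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices with matched rows.
#' @param sel_rows optional row indices defining the fit selection
#'   (default: all rows); at least 3 non-collinear points.
#' @return list: `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` over the selection.  The transform is
#'   `y = x %*% rotation + translation` (row-vector convention).
#' @export
kabsch_superpose <- function(mobile, reference, sel_rows = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(sel_rows)) sel_rows <- seq_len(nrow(mobile))
  if (length(sel_rows) < 3)
    stop("selection must contain at least 3 atoms")
  A <- mobile[sel_rows, , drop = FALSE]
  B <- reference[sel_rows, , drop = FALSE]
  cm_a <- colMeans(A); cm_b <- colMeans(B)
  Ac <- sweep(A, 2, cm_a); Bc <- sweep(B, 2, cm_b)
  C <- crossprod(Ac, Bc)                   # 3x3 covariance
  sv <- svd(C)
  # collinear/degenerate selection: rotation about the degenerate axis is
  # unconstrained
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear or coincident) selection")
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  transl <- cm_b - as.numeric(cm_a %*% R)
  fitted <- sweep(Ac %*% R, 2, cm_b, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = transl, rmsd = rmsd)
}

#' Align every frame of an ensemble onto frame 0 of its run
#'
#' Each frame is rigidly superposed onto the first frame of its own run
#' using the fit selection (typically the C-alpha atoms of the pocket
#' helices surrounding the ligand); the same transform is applied to all
#' atoms, so ligand and peptide atoms move with the pocket frame of
#' reference.  This removes global tumbling/drift before mobility and
#' contact analysis.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param topology the shared [md_topology()].
#' @param selection name of a topology selection, or an integer vector of
#'   atom ids, used for the fit.
#' @return aligned [trajectory_ensemble()] with per-frame fit RMSDs in
#'   attribute `fit_rmsd` (list per run).
#' @export
align_ensemble <- function(ensemble, topology, selection = "pocket_ca") {
  ids <- if (is.character(selection)) {
    if (is.null(topology$selections[[selection]]))
      stop("topology has no selection '", selection, "'")
    topology$selections[[selection]]
  } else selection
  rows <- atom_rows(topology, ids)
  runs <- ensemble$runs
  rmsds <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    arr <- runs[[r]]
    ref <- arr[1, , ]
    rr <- numeric(dim(arr)[1])
    for (f in seq_len(dim(arr)[1])[-1]) {
      tr <- tryCatch(kabsch_superpose(arr[f, , ], ref, rows),
                     error = function(e)
                       stop("run ", r, ", frame ", f, ": ",
                            conditionMessage(e), call. = FALSE))
      arr[f, , ] <- sweep(arr[f, , ] %*% tr$rotation, 2, tr$translation, "+")
      rr[f] <- tr$rmsd
    }
    runs[[r]] <- arr
    rmsds[[r]] <- rr
  }
  out <- trajectory_ensemble(runs, ensemble$stride)
  attr(out, "fit_rmsd") <- rmsds
  out
}

.group_rows <- function(topology, scheme, heavy_only) {
  h <- is_hydrogen(topology)
  lapply(stats::setNames(names(scheme), names(scheme)), function(g) {
    rows <- atom_rows(topology, scheme[[g]])
    if (heavy_only) rows <- rows[!h[rows]]
    if (!length(rows))
      stop("group '", g, "' has no atoms",
           if (heavy_only) " after hydrogen exclusion" else "")
    rows
  })
}

#' Fragment centre-of-mass traces and mobility
#'
#' For each named atom group (e.g. ligand fragments a--e) the centre of
#' mass is traced through every frame of every aligned run.  Mobility is
#' summarized as the root-mean-square displacement of the COM from its
#' initial (frame-0) position -- the standard deviation of the positions
#' about the starting pose -- per run, pooled across runs as the root
#' mean square of the per-run values.
#'
#' @param ensemble an aligned [trajectory_ensemble()].
#' @param topology the shared [md_topology()].
#' @param scheme named list of atom-id vectors (an atom-group scheme).
#' @param mass_weighted mass-weight the COM (default) or use the
#'   geometric centre.
#' @param heavy_only exclude hydrogens (default TRUE).
#' @return object of class `mobility_report`: `com` (per run: list of
#'   `n_frames x 3` matrices per group), `sd` (data.frame group, run,
#'   sd), `pooled_sd` (named vector, Angstrom).
#' @export
group_com_trace <- function(ensemble, topology, scheme,
                            mass_weighted = TRUE, heavy_only = TRUE) {
  grp_rows <- .group_rows(topology, scheme, heavy_only)
  masses <- topology$atoms$mass
  com_all <- vector("list", length(ensemble$runs))
  sd_tab <- NULL
  for (r in seq_along(ensemble$runs)) {
    arr <- ensemble$runs[[r]]
    nf <- dim(arr)[1]
    com_run <- lapply(grp_rows, function(rows) {
      w <- if (mass_weighted) masses[rows] else rep(1, length(rows))
      w <- w / sum(w)
      com <- matrix(0, nf, 3)
      for (f in seq_len(nf)) {
        m <- arr[f, rows, ]
        dim(m) <- c(length(rows), 3L)
        com[f, ] <- colSums(m * w)
      }
      com
    })
    com_all[[r]] <- com_run
    sds <- vapply(com_run, function(com) {
      if (nrow(com) < 2) return(0)
      d2 <- rowSums(sweep(com, 2, com[1, ])^2)
      sqrt(mean(d2))
    }, numeric(1))
    sd_tab <- rbind(sd_tab, data.frame(group = names(grp_rows), run = r,
                                       sd = sds, stringsAsFactors = FALSE))
  }
  pooled <- vapply(names(grp_rows), function(g) {
    v <- sd_tab$sd[sd_tab$group == g]
    sqrt(mean(v^2))
  }, numeric(1))
  structure(list(com = com_all, sd = sd_tab, pooled_sd = pooled),
            class = "mobility_report")
}

#' @export
print.mobility_report <- function(x, ...) {
  cat("Fragment COM mobility (RMS displacement from frame-0 COM, Angstrom)\n")
  print(round(x$pooled_sd, 3))
  invisible(x)
}

# min distance between two row-sets of one frame's coordinate matrix
.min_cross_dist <- function(xyz, rows_a, rows_b) {
  a <- xyz[rows_a, , drop = FALSE]
  b <- xyz[rows_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Residue-ligand contact fractions
#'
#' A residue is "in contact" in a frame iff the minimum heavy-atom pair
#' distance between any of its atoms and any ligand atom is `<= cutoff`
#' (default 3.5 Angstrom).  Fractions of contact frames are reported per
#' residue per run, plus a per-group breakdown in which each fragment's
#' atoms stand in for the full ligand.
#'
#' @param ensemble an aligned [trajectory_ensemble()].
#' @param topology the shared [md_topology()].
#' @param ligand_selection selection name or atom-id vector of the ligand.
#' @param scheme optional atom-group scheme for the per-fragment
#'   breakdown.
#' @param cutoff contact distance (Angstrom, default 3.5).
#' @param residues residue ids to assess (default: all residues having
#'   at least one heavy atom outside the ligand selection).
#' @return object of class `contact_report`: `fractions` (data.frame
#'   residue, run, fraction), `by_group` (data.frame residue, group, run,
#'   fraction or NULL), `cutoff`, `n_runs`.
#' @export
contact_fractions <- function(ensemble, topology, ligand_selection = "ligand",
                              scheme = NULL, cutoff = 3.5, residues = NULL) {
  stopifnot(cutoff > 0)
  lig_ids <- if (is.character(ligand_selection)) {
    if (is.null(topology$selections[[ligand_selection]]))
      stop("topology has no selection '", ligand_selection, "'")
    topology$selections[[ligand_selection]]
  } else ligand_selection
  if (!length(lig_ids)) stop("empty ligand selection")
  h <- is_hydrogen(topology)
  lig_rows <- setdiff(atom_rows(topology, lig_ids), which(h))
  if (!length(lig_rows)) stop("ligand selection has no heavy atoms")

  atoms <- topology$atoms
  if (is.null(residues)) {
    non_lig <- setdiff(seq_len(nrow(atoms)), atom_rows(topology, lig_ids))
    residues <- sort(unique(atoms$resid[non_lig]))
  }
  res_rows <- lapply(residues, function(rid)
    setdiff(which(atoms$resid == rid & !h), atom_rows(topology, lig_ids)))
  keep <- lengths(res_rows) > 0
  residues <- residues[keep]; res_rows <- res_rows[keep]

  grp_rows <- if (!is.null(scheme))
    .group_rows(topology, scheme, heavy_only = TRUE) else NULL

  frac <- NULL; by_group <- NULL
  for (r in seq_along(ensemble$runs)) {
    arr <- ensemble$runs[[r]]
    nf <- dim(arr)[1]
    hits <- matrix(0L, nf, length(residues))
    g_hits <- if (!is.null(grp_rows))
      array(0L, c(nf, length(residues), length(grp_rows))) else NULL
    for (f in seq_len(nf)) {
      xyz <- arr[f, , ]
      for (i in seq_along(residues)) {
        if (.min_cross_dist(xyz, res_rows[[i]], lig_rows) <= cutoff)
          hits[f, i] <- 1L
        if (!is.null(grp_rows)) {
          for (g in seq_along(grp_rows)) {
            if (.min_cross_dist(xyz, res_rows[[i]], grp_rows[[g]]) <= cutoff)
              g_hits[f, i, g] <- 1L
          }
        }
      }
    }
    frac <- rbind(frac, data.frame(residue = residues, run = r,
                                   fraction = colMeans(hits)))
    if (!is.null(grp_rows)) {
      for (g in seq_along(grp_rows)) {
        gm <- matrix(g_hits[, , g], nrow = nf)
        by_group <- rbind(by_group, data.frame(
          residue = residues, group = names(grp_rows)[g], run = r,
          fraction = colMeans(gm), stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(fractions = frac, by_group = by_group, cutoff = cutoff,
                 n_runs = length(ensemble$runs)),
            class = "contact_report")
}

#' Aggregate contacts into the retained-residue set
#'
#' A residue is retained iff its contact fraction is at least
#' `inclusion_fraction` in at least `run_quorum` runs (both comparisons
#' inclusive).  Defaults follow the convention of requiring contact for
#' at least 30% of the simulation time in at least three out of five
#' trajectories; for ensembles of other sizes the quorum generalizes to
#' `ceiling(3/5 * n_runs)`.
#'
#' @param report a [contact_fractions()] report.
#' @param inclusion_fraction occupancy threshold (default 0.30).
#' @param run_quorum minimum number of qualifying runs (default
#'   `ceiling(0.6 * n_runs)`).
#' @return sorted vector of retained residue ids.
#' @export
aggregate_contacts <- function(report, inclusion_fraction = 0.30,
                               run_quorum = NULL) {
  n_runs <- report$n_runs
  if (is.null(run_quorum)) run_quorum <- ceiling(3 / 5 * n_runs)
  if (run_quorum > n_runs)
    stop("run_quorum (", run_quorum, ") exceeds number of runs (",
         n_runs, ")")
  fr <- report$fractions
  qual <- fr$fraction >= inclusion_fraction
  counts <- tapply(qual, fr$residue, sum)
  retained <- names(counts)[counts >= run_quorum]
  sort(as.integer(retained))
}

#' Contact-frequency reporting table
#'
#' Rows are restricted to residues whose whole-ligand mean contact
#' fraction across runs is strictly greater than `display_threshold`
#' (default 0.40, i.e. "over 40% of the trajectory"); per-fragment mean
#' fractions are reported unfiltered for those rows.
#'
#' @param report a [contact_fractions()] report (with a group breakdown
#'   if per-fragment columns are wanted).
#' @param display_threshold strict lower bound on the whole-ligand mean
#'   fraction.
#' @return data.frame: residue, mean_fraction, then one column per group.
#' @export
frequency_report <- function(report, display_threshold = 0.40) {
  fr <- report$fractions
  mean_frac <- tapply(fr$fraction, fr$residue, mean)
  out <- data.frame(residue = as.integer(names(mean_frac)),
                    mean_fraction = as.numeric(mean_frac))
  out <- out[out$mean_fraction > display_threshold, , drop = FALSE]
  if (!is.null(report$by_group) && nrow(out)) {
    bg <- report$by_group
    for (g in unique(bg$group)) {
      gb <- bg[bg$group == g, ]
      gm <- tapply(gb$fraction, gb$residue, mean)
      out[[g]] <- as.numeric(gm[as.character(out$residue)])
    }
  }
  out <- out[order(-out$mean_fraction, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
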