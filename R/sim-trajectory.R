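#' Specification of a synthetic binding-pocket MD-like ensemble
#'
#' Emulates the analysis input of a multi-run ligand-in-pocket simulation:
#' pocket residues arranged on a ring around a five-fragment ligand, with
#' per-fragment isotropic positional jitter, planted per-residue contact
#' occupancies, and an optional global rigid-body drift that alignment
#' must remove.  Defaults follow the study conditions this package is
#' built around: five runs, fragments labelled a--e with the last
#' fragment (the imidazole-like group "e") far more mobile than the rest.
#'
#' @param n_runs number of independent runs (default 5).
#' @param n_frames frames per run.
#' @param pocket_residues residue ids placed around the pocket ring.
#' @param fragment_sigmas named vector, fragment label -> isotropic jitter
#'   SD (Angstrom); all >= 0.
#' @param contact_plan data.frame with columns `residue`, `run`,
#'   `occupancy` (target contact fraction in \[0,1\]); rows absent from
#'   the plan mean occupancy 0.
#' @param global_drift rigid-body drift amplitude: per-frame random
#'   translation up to this many Angstrom per axis and rotation up to
#'   5x this many degrees.
#' @param seed RNG seed.
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_runs = 5L, n_frames = 200L,
                            pocket_residues = c(306L, 377L, 380L, 381L,
                                                430L, 433L, 434L, 1246L),
                            fragment_sigmas = c(a = 0.2, b = 0.3, c = 0.3,
                                                d = 0.5, e = 2.0),
                            contact_plan = NULL,
                            global_drift = 0, seed = 1L) {
  stopifnot(n_runs >= 1, n_frames >= 1, all(fragment_sigmas >= 0),
            global_drift >= 0, length(pocket_residues) >= 3)
  if (is.null(names(fragment_sigmas)) || any(names(fragment_sigmas) == ""))
    stop("fragment_sigmas must be a fully named vector")
  if (!is.null(contact_plan)) {
    need <- c("residue", "run", "occupancy")
    if (!all(need %in% names(contact_plan)))
      stop("contact_plan needs columns: ", paste(need, collapse = ", "))
    stopifnot(all(contact_plan$occupancy >= 0),
              all(contact_plan$occupancy <= 1),
              all(contact_plan$run >= 1),
              all(contact_plan$run <= n_runs))
    if (!all(contact_plan$residue %in% pocket_residues))
      stop("contact_plan references residues not in pocket_residues")
    if (anyDuplicated(contact_plan[c("residue", "run")]))
      stop("duplicate (residue, run) entries in contact_plan")
  }
  structure(list(n_runs = as.integer(n_runs),
                 n_frames = as.integer(n_frames),
                 pocket_residues = as.integer(pocket_residues),
                 fragment_sigmas = fragment_sigmas,
                 contact_plan = contact_plan,
                 global_drift = global_drift, seed = as.integer(seed)),
            class = "trajectory_spec")
}

.rot_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)),
    3, 3, byrow = TRUE)
}

#' Generate a synthetic pocket ensemble with known truth
#'
#' Pocket residues (three heavy atoms each, innermost atom facing the
#' ligand) sit on a 14-Angstrom ring; ligand fragments jitter around the
#' pocket centre with their planted sigmas (jitter is zero in frame 0 and
#' truncated at 3 sigma, so planted contact truths stay exact).  Each
#' residue named in the contact plan receives a dedicated ligand anchor
#' atom placed exactly 3.0 Angstrom from the residue's innermost atom in
#' contact frames and 6.0 Angstrom away otherwise; contact frames are a
#' random subset of size `round(occupancy * n_frames)`.  A per-frame
#' rigid rotation/translation of amplitude `global_drift` is applied
#' last, so all planted distances are preserved and alignment onto
#' frame 0 removes the drift exactly.
#'
#' After generation the planted occupancies are re-measured with the same
#' minimum-heavy-atom-pair-distance definition the contact analyzer uses;
#' a plan whose placements conflict is rejected with a diagnostic rather
#' than silently mis-planted.
#'
#' @param spec a [trajectory_spec()].
#' @return list: `topology` ([md_topology()] with selections `pocket_ca`
#'   and `ligand`), `ensemble` ([trajectory_ensemble()]), `scheme` (named
#'   atom-group list, fragments a--e), `truth` (expected per-residue,
#'   per-run contact fractions; planted sigmas; anchor-fragment map;
#'   seed).
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  withr::with_seed(spec$seed, {
    ring_r <- 14; inner_off <- 1.3
    nres <- length(spec$pocket_residues)
    theta <- 2 * pi * (seq_len(nres) - 1) / nres

    atoms <- NULL; coords0 <- NULL
    aid <- 0L
    add_atom <- function(name, element, mass, resid, resname, chain, xyz) {
      aid <<- aid + 1L
      atoms <<- rbind(atoms, data.frame(
        atom_id = aid, name = name, element = element, mass = mass,
        resid = resid, resname = resname, chain = chain,
        stringsAsFactors = FALSE))
      coords0 <<- rbind(coords0, xyz)
      aid
    }

    pocket_ca <- integer(0)
    inner_pos <- matrix(0, nres, 3)   # the residue atom facing the ligand
    for (i in seq_len(nres)) {
      rid <- spec$pocket_residues[i]
      dirv <- c(cos(theta[i]), sin(theta[i]), 0)
      ca <- ring_r * dirv
      cb <- (ring_r - inner_off) * dirv
      cg <- (ring_r - inner_off) * c(cos(theta[i] + 0.08),
                                     sin(theta[i] + 0.08), 0) + c(0, 0, 0.5)
      pocket_ca <- c(pocket_ca,
                     add_atom("CA", "C", 12.011, rid, "POC", "A", ca))
      add_atom("CB", "C", 12.011, rid, "POC", "A", cb)
      add_atom("CG", "C", 12.011, rid, "POC", "A", cg)
      inner_pos[i, ] <- cb
    }

    frag_labels <- names(spec$fragment_sigmas)
    frag_centers <- list(c(1.2, 0, 0), c(-1.2, 0, 0), c(0, 1.2, 0),
                         c(0, -1.2, 0), c(0, 0, 1.2))
    lig_resid <- 9001L
    lig_ids <- integer(0)
    scheme <- stats::setNames(vector("list", length(frag_labels)),
                              frag_labels)
    frag_atom_rows <- stats::setNames(vector("list", length(frag_labels)),
                                      frag_labels)
    tri <- rbind(c(0.5, 0, 0), c(-0.25, 0.43, 0), c(-0.25, -0.43, 0.2))
    for (g in seq_along(frag_labels)) {
      ctr <- frag_centers[[((g - 1) %% length(frag_centers)) + 1]]
      ids_g <- integer(0)
      for (t in 1:3) {
        id <- add_atom(paste0("C", g, t), "C", 12.011, lig_resid, "LIG",
                       "L", ctr + tri[t, ])
        ids_g <- c(ids_g, id)
      }
      idh <- add_atom(paste0("H", g), "H", 1.008, lig_resid, "LIG", "L",
                      ctr + c(0, 0, 0.4))
      ids_g <- c(ids_g, idh)
      scheme[[frag_labels[g]]] <- ids_g
      lig_ids <- c(lig_ids, ids_g)
    }

    # dedicated anchor atoms for planted contacts, one per planned residue
    plan <- spec$contact_plan
    planned_res <- if (is.null(plan)) integer(0)
                   else sort(unique(plan$residue))
    anchor_atom <- stats::setNames(integer(length(planned_res)),
                                   planned_res)
    anchor_frag <- stats::setNames(character(length(planned_res)),
                                   planned_res)
    for (k in seq_along(planned_res)) {
      rid <- planned_res[k]
      i <- match(rid, spec$pocket_residues)
      dirv <- inner_pos[i, ] / sqrt(sum(inner_pos[i, ]^2))
      pos_far <- inner_pos[i, ] - 6.0 * dirv
      id <- add_atom(paste0("X", k), "C", 12.011, lig_resid, "LIG", "L",
                     pos_far)
      frag <- frag_labels[((k - 1) %% length(frag_labels)) + 1]
      scheme[[frag]] <- c(scheme[[frag]], id)
      lig_ids <- c(lig_ids, id)
      anchor_atom[k] <- id
      anchor_frag[k] <- frag
    }
    rownames(coords0) <- NULL
    n_atoms <- nrow(coords0)

    # planted contact-frame sets and expected fractions
    nf <- spec$n_frames
    occ <- matrix(0, nres, spec$n_runs,
                  dimnames = list(spec$pocket_residues, NULL))
    contact_frames <- list()
    if (!is.null(plan)) {
      for (j in seq_len(nrow(plan))) {
        n_contact <- round(plan$occupancy[j] * nf)
        frames <- sort(sample.int(nf, n_contact))
        contact_frames[[paste(plan$residue[j], plan$run[j], sep = ":")]] <-
          frames
        occ[as.character(plan$residue[j]), plan$run[j]] <- n_contact / nf
      }
    }

    # jitter draws precede all drift draws in the RNG stream, so the same
    # seed yields identical internal motion whether or not drift is added
    # (the rigid-motion-invariance contract is then testable exactly)
    sig <- spec$fragment_sigmas
    jitter <- lapply(seq_len(spec$n_runs), function(r) {
      lapply(frag_labels, function(g) {
        s <- sig[[g]]
        J <- matrix(0, nf, 3)
        if (s > 0 && nf > 1) {
          J[-1, ] <- stats::rnorm(3 * (nf - 1), 0, s)
          nj <- sqrt(rowSums(J^2))
          big <- nj > 3 * s                  # truncate to keep plants exact
          J[big, ] <- J[big, , drop = FALSE] * (3 * s / nj[big])
        }
        J
      })
    })
    drift <- if (spec$global_drift > 0) {
      lapply(seq_len(spec$n_runs), function(r) lapply(seq_len(nf), function(f) {
        if (f == 1) return(NULL)
        list(R = .rot_about(stats::rnorm(3),
                            stats::runif(1, -1, 1) *
                              5 * spec$global_drift * pi / 180),
             t = stats::runif(3, -1, 1) * spec$global_drift)
      }))
    } else NULL

    runs <- vector("list", spec$n_runs)
    anchor_rows <- atom_rows_raw(atoms, anchor_atom)
    for (r in seq_len(spec$n_runs)) {
      arr <- array(0, c(nf, n_atoms, 3))
      for (f in seq_len(nf)) {
        xyz <- coords0
        for (g in seq_along(frag_labels)) {
          j <- jitter[[r]][[g]][f, ]
          if (any(j != 0)) {
            rows <- setdiff(atom_rows_raw(atoms, scheme[[frag_labels[g]]]),
                            anchor_rows)
            xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2, j, "+")
          }
        }
        for (k in seq_along(planned_res)) {
          rid <- planned_res[k]
          i <- match(rid, spec$pocket_residues)
          dirv <- inner_pos[i, ] / sqrt(sum(inner_pos[i, ]^2))
          key <- paste(rid, r, sep = ":")
          in_contact <- !is.null(contact_frames[[key]]) &&
            f %in% contact_frames[[key]]
          d <- if (in_contact) 3.0 else 6.0
          xyz[anchor_rows[k], ] <- inner_pos[i, ] - d * dirv
        }
        if (!is.null(drift) && f > 1) {
          xyz <- xyz %*% t(drift[[r]][[f]]$R)
          xyz <- sweep(xyz, 2, drift[[r]][[f]]$t, "+")
        }
        arr[f, , ] <- xyz
      }
      runs[[r]] <- arr
    }

    topology <- md_topology(atoms, selections = list(
      pocket_ca = pocket_ca, ligand = lig_ids))
    ensemble <- trajectory_ensemble(runs)

    # verify plants with the analyzer's own distance definition
    if (length(planned_res)) {
      realized <- contact_fractions(ensemble, topology, "ligand",
                                    cutoff = 3.5,
                                    residues = spec$pocket_residues)$fractions
      for (j in seq_len(nrow(realized))) {
        want <- occ[as.character(realized$residue[j]), realized$run[j]]
        if (abs(realized$fraction[j] - want) > 1e-12)
          stop("infeasible contact plan: residue ", realized$residue[j],
               ", run ", realized$run[j], " realizes occupancy ",
               realized$fraction[j], " instead of ", want)
      }
    }

    list(topology = topology, ensemble = ensemble, scheme = scheme,
         truth = list(expected_fractions = occ,
                      contact_frames = contact_frames,
                      anchor_fragment = anchor_frag,
                      fragment_sigmas = sig,
                      seed = spec$seed))
  })
}

# atom-id -> row lookup usable before the topology object exists
atom_rows_raw <- function(atoms, ids) match(ids, atoms$atom_id)
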