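# Independent reference implementations used to cross-check the package.
# These deliberately use different algorithms / naive enumeration and are
# never shared with the code paths they verify.

# Horn's quaternion method for optimal rigid superposition: the largest
# eigenvector of the 4x4 profile matrix gives the rotation quaternion.
quaternion_superpose_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(A, B)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  fitted <- A %*% t(R)
  sqrt(mean(rowSums((fitted - B)^2)))
}

# Exhaustive all-pairs contact scan: explicit loops over every
# (residue heavy atom, ligand heavy atom) pair, no matrix algebra.
oracle_contact_fractions <- function(ensemble, topology, lig_ids,
                                     cutoff = 3.5) {
  at <- topology$atoms
  hyd <- toupper(at$element) == "H"
  lig_rows <- match(lig_ids, at$atom_id)
  lig_rows <- lig_rows[!hyd[lig_rows]]
  res_ids <- sort(unique(at$resid[-match(lig_ids, at$atom_id)]))
  out <- NULL
  for (r in seq_along(ensemble$runs)) {
    arr <- ensemble$runs[[r]]
    nf <- dim(arr)[1]
    for (rid in res_ids) {
      rrows <- which(at$resid == rid & !hyd)
      rrows <- setdiff(rrows, match(lig_ids, at$atom_id))
      if (!length(rrows)) next
      hits <- 0L
      for (f in seq_len(nf)) {
        contact <- FALSE
        for (i in rrows) {
          for (j in lig_rows) {
            dx <- arr[f, i, 1] - arr[f, j, 1]
            dy <- arr[f, i, 2] - arr[f, j, 2]
            dz <- arr[f, i, 3] - arr[f, j, 3]
            if (sqrt(dx * dx + dy * dy + dz * dz) <= cutoff) {
              contact <- TRUE
              break
            }
          }
          if (contact) break
        }
        if (contact) hits <- hits + 1L
      }
      out <- rbind(out, data.frame(residue = rid, run = r,
                                   fraction = hits / nf))
    }
  }
  out
}

# Brute-force sphere-exclusion reference: recomputes every pairwise
# similarity and every neighbor count from scratch each round.
oracle_butina <- function(library, cutoff) {
  n <- nrow(library)
  ids <- library$compound_id
  assigned <- rep(NA_integer_, n)
  k <- 0L
  while (anyNA(assigned)) {
    best_i <- NA_integer_; best_count <- -1L
    for (i in order(ids)) {
      if (!is.na(assigned[i])) next
      count <- 0L
      for (j in seq_len(n)) {
        if (j == i || !is.na(assigned[j])) next
        if (suppressWarnings(tanimoto(library$bits[[i]],
                                      library$bits[[j]])) >= cutoff)
          count <- count + 1L
      }
      if (count > best_count) {   # first hit in id order wins ties
        best_count <- count
        best_i <- i
      }
    }
    k <- k + 1L
    assigned[best_i] <- k
    for (j in seq_len(n)) {
      if (!is.na(assigned[j]) || j == best_i) next
      if (suppressWarnings(tanimoto(library$bits[[best_i]],
                                    library$bits[[j]])) >= cutoff)
        assigned[j] <- k
    }
  }
  assigned
}

# random small fingerprint library for clustering equivalence checks
random_library <- function(n, n_bits = 64, seed) {
  withr::with_seed(seed, {
    bits <- lapply(seq_len(n), function(i)
      sort(sample.int(n_bits, sample(5:20, 1)) - 1L))
    fp_library(sprintf("R%03d", sample(seq_len(n))), bits,
               stats::runif(n))
  })
}

# dense brute-force lateral grid for pore cross-checks
oracle_pore_radius <- function(coords, radii, z, grid_half = 1.5,
                               grid_step = 0.05) {
  xs <- seq(-grid_half, grid_half, by = grid_step)
  best <- -Inf
  for (x in xs) {
    for (y in xs) {
      d <- sqrt((x - coords[, 1])^2 + (y - coords[, 2])^2 +
                  (z - coords[, 3])^2) - radii
      best <- max(best, min(d))
    }
  }
  best
}
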