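#' Specification of a synthetic fingerprint library
#'
#' Toy-scale emulation of a commercial screening library with planted
#' structure: a handful of scaffold clusters (members derived from a
#' cluster seed fingerprint by per-bit flips), optional exact look-alikes
#' of designated known binders (to exercise the novelty filter), and
#' random decoys filling the remainder.
#'
#' @param n_compounds library size.
#' @param n_bits fingerprint length (ECFP4-like bit space).
#' @param cluster_plan list of `c(size, flip_rate)` pairs; sizes must sum
#'   to at most `n_compounds`.
#' @param known_binder_seeds number of compounds generated as near-copies
#'   of designated known binders.
#' @param n_on expected on-bits per fingerprint.
#' @param score_model function(n) -> n scores; default standard uniform.
#' @param seed RNG seed.
#' @return list of class `library_spec`.
#' @export
library_spec <- function(n_compounds = 100L, n_bits = 512L,
                         cluster_plan = list(c(10, 0.02), c(10, 0.02)),
                         known_binder_seeds = 0L, n_on = 60L,
                         score_model = NULL, seed = 1L) {
  sizes <- vapply(cluster_plan, function(p) p[1], numeric(1))
  rates <- vapply(cluster_plan, function(p) p[2], numeric(1))
  stopifnot(all(rates >= 0), all(rates <= 1), all(sizes >= 1),
            known_binder_seeds >= 0, n_on >= 1, n_on < n_bits)
  if (sum(sizes) + known_binder_seeds > n_compounds)
    stop("cluster sizes plus known-binder look-alikes exceed n_compounds")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_bits = as.integer(n_bits),
                 cluster_plan = cluster_plan,
                 known_binder_seeds = as.integer(known_binder_seeds),
                 n_on = as.integer(n_on),
                 score_model = score_model, seed = as.integer(seed)),
            class = "library_spec")
}

.random_bits <- function(n_bits, n_on) sort(sample.int(n_bits, n_on) - 1L)

.flip_bits <- function(bits, n_bits, rate) {
  if (rate == 0) return(bits)
  flips <- which(stats::runif(n_bits) < rate) - 1L
  sort(union(setdiff(bits, flips), setdiff(flips, bits)))
}

#' Generate a synthetic fingerprint library with known truth
#'
#' @param spec a [library_spec()].
#' @return list: `library` (an [fp_library()]), `known_binders` (list of
#'   bit-sets), `truth` (cluster membership per compound, 0 = unclustered
#'   decoy; ids of known-binder look-alikes; seed).
#' @export
gen_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_compounds
    ids <- sprintf("C%04d", seq_len(n))
    bits <- vector("list", n)
    membership <- integer(n)
    i <- 0L

    known_binders <- list()
    lookalikes <- character(0)
    if (spec$known_binder_seeds > 0) {
      for (k in seq_len(spec$known_binder_seeds)) {
        kb <- .random_bits(spec$n_bits, spec$n_on)
        known_binders[[k]] <- kb
        i <- i + 1L
        bits[[i]] <- kb                     # exact look-alike copy
        lookalikes <- c(lookalikes, ids[i])
      }
    }
    for (k in seq_along(spec$cluster_plan)) {
      size <- spec$cluster_plan[[k]][1]
      rate <- spec$cluster_plan[[k]][2]
      seed_fp <- .random_bits(spec$n_bits, spec$n_on)
      for (m in seq_len(size)) {
        i <- i + 1L
        bits[[i]] <- .flip_bits(seed_fp, spec$n_bits, rate)
        membership[i] <- k
      }
    }
    while (i < n) {
      i <- i + 1L
      bits[[i]] <- .random_bits(spec$n_bits, spec$n_on)
    }
    scores <- if (is.null(spec$score_model)) stats::runif(n)
              else spec$score_model(n)
    lib <- fp_library(ids, bits, scores, n_bits = spec$n_bits)
    list(library = lib,
         known_binders = known_binders,
         truth = list(membership = stats::setNames(membership, ids),
                      lookalikes = lookalikes, seed = spec$seed))
  })
}
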