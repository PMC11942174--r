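#' Tanimoto similarity between two binary fingerprints
#'
#' Fingerprints are represented as integer vectors of "on" bit indices
#' (an ECFP4-like bit-set).  The Tanimoto (Jaccard) coefficient is
#' \eqn{|A \cap B| / |A \cup B|}.
#'
#' Two empty fingerprints are defined to have similarity 0 (with a warning):
#' a featureless molecule should neither be excluded as a known-binder
#' look-alike nor merged into a cluster on the strength of no evidence.
#'
#' @param a,b integer vectors of on-bit indices.
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 0.5
tanimoto <- function(a, b) {
  a <- unique(as.integer(a))
  b <- unique(as.integer(b))
  if (length(a) == 0L && length(b) == 0L) {
    warning("Tanimoto of two empty fingerprints defined as 0")
    return(0)
  }
  n_common <- length(intersect(a, b))
  n_common / (length(a) + length(b) - n_common)
}

#' Assemble a fingerprint library
#'
#' The triage unit is one row per compound: an id, a score (higher = better
#' predicted binder; the scoring model is pluggable and external to this
#' package), a bit-set fingerprint stored as a list column, and an optional
#' per-compound property list used by [apply_filters()].
#'
#' @param compound_id character vector, unique within the library.
#' @param bits list of integer vectors (on-bit indices).
#' @param score numeric vector of predicted-binder scores.
#' @param properties optional list (one named list per compound) of
#'   physicochemical properties, e.g. `mw`, `logp`, `hbd`, `hba`.
#' @param n_bits fingerprint length; bit indices must be `< n_bits`
#'   (0-based) when supplied.
#' @return data.frame of class `fp_library`.
#' @export
fp_library <- function(compound_id, bits, score = NA_real_,
                       properties = NULL, n_bits = NULL) {
  compound_id <- as.character(compound_id)
  if (anyDuplicated(compound_id))
    stop("compound_id must be unique within a library")
  if (!is.list(bits)) bits <- list(bits)
  bits <- lapply(bits, function(b) sort(unique(as.integer(b))))
  if (!is.null(n_bits)) {
    bad <- vapply(bits, function(b) length(b) && max(b) >= n_bits, logical(1))
    if (any(bad))
      stop("bit indices exceed fingerprint length for: ",
           paste(compound_id[bad], collapse = ", "))
  }
  lib <- data.frame(compound_id = compound_id,
                    score = rep_len(as.numeric(score), length(compound_id)),
                    stringsAsFactors = FALSE)
  lib$bits <- bits
  lib$properties <- if (is.null(properties)) {
    rep(list(list()), nrow(lib))
  } else {
    properties
  }
  if (!is.null(n_bits)) attr(lib, "n_bits") <- as.integer(n_bits)
  class(lib) <- c("fp_library", class(lib))
  lib
}

#' Triage funnel configuration
#'
#' Defaults mirror a typical post-scoring virtual-screen funnel: compounds
#' with Tanimoto similarity strictly greater than 0.5 to any known binder
#' are excluded, the top 30,000 by score are clustered with the Butina
#' algorithm at a 0.35 similarity cutoff, and 96 candidates are selected
#' for experimental testing.
#'
#' @param novelty_cutoff Tanimoto threshold for known-binder exclusion.
#' @param cluster_cutoff Tanimoto threshold for Butina clustering.
#' @param top_n number of top-scoring compounds carried into clustering.
#' @param n_select number of candidates selected.
#' @param filter_predicates named list of predicate functions applied by
#'   [apply_filters()]; see [lipinski_predicates()].
#' @return list of class `triage_config`.
#' @export
triage_config <- function(novelty_cutoff = 0.5, cluster_cutoff = 0.35,
                          top_n = 30000L, n_select = 96L,
                          filter_predicates = list()) {
  stopifnot(novelty_cutoff >= 0, novelty_cutoff <= 1,
            cluster_cutoff >= 0, cluster_cutoff <= 1,
            top_n >= 1, n_select >= 1)
  structure(list(novelty_cutoff = novelty_cutoff,
                 cluster_cutoff = cluster_cutoff,
                 top_n = as.integer(top_n),
                 n_select = as.integer(n_select),
                 filter_predicates = filter_predicates),
            class = "triage_config")
}

#' Exclude known-binder look-alikes
#'
#' A compound is excluded iff its maximum Tanimoto similarity to any known
#' binder is strictly greater than `cutoff`; a compound at exactly the
#' cutoff is retained.  The exclusion log names the most similar binder.
#'
#' @param library an [fp_library()].
#' @param known_binders list of integer bit-sets (known binders of the
#'   target and its close homologs).
#' @param cutoff similarity threshold (default 0.5).
#' @return list with `retained` (fp_library subset) and `excluded`
#'   (data.frame: compound_id, max_similarity, nearest_binder).
#' @export
novelty_filter <- function(library, known_binders, cutoff = 0.5) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (nrow(library) == 0L || length(known_binders) == 0L) {
    return(list(retained = library,
                excluded = data.frame(compound_id = character(),
                                      max_similarity = numeric(),
                                      nearest_binder = integer())))
  }
  sims <- vapply(library$bits, function(fp)
    vapply(known_binders, function(kb) tanimoto(fp, kb), numeric(1)),
    numeric(length(known_binders)))
  sims <- matrix(sims, nrow = length(known_binders))
  max_sim <- apply(sims, 2, max)
  nearest <- apply(sims, 2, which.max)
  drop <- max_sim > cutoff        # strictly greater: T == cutoff retained
  list(retained = library[!drop, , drop = FALSE],
       excluded = data.frame(compound_id = library$compound_id[drop],
                             max_similarity = max_sim[drop],
                             nearest_binder = nearest[drop],
                             stringsAsFactors = FALSE))
}

#' Rank by score and keep the top n
#'
#' Descending by score; ties broken ascending by `compound_id` so the
#' funnel is stable under permutation of the input order.
#'
#' @param library an [fp_library()]; every record must carry a score.
#' @param top_n number of compounds to keep.
#' @return the ordered top-`top_n` subset.
#' @export
rank_and_truncate <- function(library, top_n) {
  stopifnot(top_n >= 1)
  missing_score <- is.na(library$score)
  if (any(missing_score))
    stop("missing score for: ",
         paste(library$compound_id[missing_score], collapse = ", "))
  ord <- order(-library$score, library$compound_id)
  library[ord[seq_len(min(top_n, nrow(library)))], , drop = FALSE]
}

#' Butina sphere-exclusion clustering
#'
#' Neighbor lists are built at Tanimoto similarity `>= cutoff`.  The
#' unassigned compound with the most unassigned neighbors becomes the next
#' cluster centroid and sweeps its unassigned neighbors into the cluster;
#' counts are recomputed each round.  Ties on neighbor count are broken
#' ascending by `compound_id`.
#'
#' @param library an [fp_library()].
#' @param cutoff similarity cutoff (default 0.35).
#' @return object of class `butina_clusters`: data.frame with columns
#'   `compound_id`, `cluster`, `is_centroid`, plus attributes `centroids`
#'   and `singleton` (per-cluster flags).
#' @export
butina_cluster <- function(library, cutoff = 0.35) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  n <- nrow(library)
  ids <- library$compound_id
  if (n == 0L) {
    out <- data.frame(compound_id = character(), cluster = integer(),
                      is_centroid = logical())
    return(structure(out, centroids = character(), singleton = logical(),
                     class = c("butina_clusters", class(out))))
  }
  neigh <- vector("list", n)
  if (n > 1L) {
    sim <- matrix(1, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        s <- suppressWarnings(tanimoto(library$bits[[i]], library$bits[[j]]))
        sim[i, j] <- s
        sim[j, i] <- s
      }
    }
    for (i in seq_len(n))
      neigh[[i]] <- setdiff(which(sim[i, ] >= cutoff), i)
  }
  cluster <- rep(NA_integer_, n)
  centroid <- logical(n)
  k <- 0L
  # ascending-id ordering makes which.max's first-hit rule the tie-break
  id_rank <- order(ids)
  while (anyNA(cluster)) {
    un <- which(is.na(cluster))
    counts <- vapply(un, function(i) sum(is.na(cluster[neigh[[i]]])),
                     integer(1))
    un_sorted <- un[order(match(un, id_rank))]
    counts_sorted <- counts[order(match(un, id_rank))]
    c_i <- un_sorted[which.max(counts_sorted)]
    k <- k + 1L
    members <- c(c_i, neigh[[c_i]][is.na(cluster[neigh[[c_i]]])])
    cluster[members] <- k
    centroid[c_i] <- TRUE
  }
  out <- data.frame(compound_id = ids, cluster = cluster,
                    is_centroid = centroid, stringsAsFactors = FALSE)
  sizes <- table(cluster)
  structure(out,
            centroids = ids[centroid][order(cluster[centroid])],
            singleton = as.vector(sizes == 1L),
            class = c("butina_clusters", class(out)))
}

.req_prop <- function(props, name) {
  if (is.null(props[[name]]))
    stop("predicate requires missing property '", name, "'", call. = FALSE)
  props[[name]]
}

#' Lipinski-style oral-availability predicates
#'
#' Stand-in property filters in the spirit of medicinal-chemistry triage
#' rule sets (the proprietary rule sets used in industrial screens are not
#' reproduced here).  Each predicate takes a compound's property list and
#' returns `TRUE` to retain.  Defaults: molecular weight <= 500 Da,
#' logP <= 5, H-bond donors <= 5, H-bond acceptors <= 10, and absence of
#' flagged toxicophore substructures (property `toxicophores`, a count).
#'
#' @return named list of predicate functions for [apply_filters()].
#' @export
lipinski_predicates <- function() {
  list(
    mw_le_500   = function(p) .req_prop(p, "mw") <= 500,
    logp_le_5   = function(p) .req_prop(p, "logp") <= 5,
    hbd_le_5    = function(p) .req_prop(p, "hbd") <= 5,
    hba_le_10   = function(p) .req_prop(p, "hba") <= 10,
    no_toxicophore = function(p) {
      tox <- p[["toxicophores"]]
      is.null(tox) || tox == 0
    }
  )
}

#' Apply named property filters
#'
#' A record is retained iff all predicates pass; input order is preserved.
#' Rejection counts are attributed to each failing predicate.
#'
#' @param library an [fp_library()].
#' @param predicates named list of functions `function(properties)` ->
#'   logical.
#' @return list with `retained` (fp_library subset) and `rejections`
#'   (named integer vector of per-predicate rejection counts).
#' @export
apply_filters <- function(library, predicates) {
  if (length(predicates) == 0L)
    return(list(retained = library,
                rejections = integer(0)))
  if (is.null(names(predicates)) || any(names(predicates) == ""))
    stop("predicates must be a fully named list")
  pass <- matrix(TRUE, nrow(library), length(predicates),
                 dimnames = list(NULL, names(predicates)))
  for (j in seq_along(predicates)) {
    for (i in seq_len(nrow(library))) {
      pass[i, j] <- isTRUE(predicates[[j]](library$properties[[i]]))
    }
  }
  keep <- rowSums(pass) == ncol(pass)
  list(retained = library[keep, , drop = FALSE],
       rejections = colSums(!pass))
}

#' Select diverse candidates from clusters
#'
#' At most one compound per cluster: the best-scoring member (ties broken
#' ascending by id).  Clusters are visited in decreasing order of their
#' best member's score, so with more clusters than slots the strongest
#' scaffolds are picked first.
#'
#' @param clusters a [butina_cluster()] assignment covering `library`.
#' @param library the clustered [fp_library()] (provides the scores).
#' @param n_select number of candidates (default 96).
#' @return character vector of selected compound ids.
#' @export
select_candidates <- function(clusters, library, n_select = 96L) {
  if (n_select < 1) stop("n_select must be >= 1")
  m <- merge(as.data.frame(clusters)[c("compound_id", "cluster")],
             as.data.frame(library)[c("compound_id", "score")],
             by = "compound_id")
  if (nrow(m) < nrow(clusters))
    stop("clusters reference compounds missing from the library")
  m <- m[order(-m$score, m$compound_id), ]
  best <- m[!duplicated(m$cluster), ]        # best-scoring member per cluster
  best <- best[order(-best$score, best$compound_id), ]
  best$compound_id[seq_len(min(n_select, nrow(best)))]
}

#' Run the full post-scoring triage funnel
#'
#' Stages, in order: known-binder novelty filter, score ranking and
#' truncation, Butina diversity clustering, property filters, candidate
#' selection.  The report records counts at every stage and the exclusion
#' logs, so the funnel is auditable end to end.
#'
#' @param library an [fp_library()] with scores.
#' @param known_binders list of known-binder bit-sets.
#' @param config a [triage_config()].
#' @return list of class `triage_report`: `selected` (compound ids),
#'   `stage_counts`, `novelty_excluded`, `filter_rejections`, `clusters`.
#' @export
run_triage <- function(library, known_binders = list(),
                       config = triage_config()) {
  stopifnot(inherits(config, "triage_config"))
  counts <- c(input = nrow(library))
  nov <- novelty_filter(library, known_binders, config$novelty_cutoff)
  counts["after_novelty"] <- nrow(nov$retained)
  top <- rank_and_truncate(nov$retained, config$top_n)
  counts["after_rank"] <- nrow(top)
  cl <- butina_cluster(top, config$cluster_cutoff)
  counts["n_clusters"] <- length(attr(cl, "centroids"))
  flt <- apply_filters(top, config$filter_predicates)
  counts["after_filters"] <- nrow(flt$retained)
  cl_kept <- cl[cl$compound_id %in% flt$retained$compound_id, , drop = FALSE]
  sel <- select_candidates(cl_kept, flt$retained, config$n_select)
  counts["selected"] <- length(sel)
  structure(list(selected = sel,
                 stage_counts = counts,
                 novelty_excluded = nov$excluded,
                 filter_rejections = flt$rejections,
                 clusters = cl),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Virtual-screen triage funnel\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-14s %d\n", nm, x$stage_counts[[nm]]))
  invisible(x)
}
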