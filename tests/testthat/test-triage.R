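test_that("tanimoto matches the set definition and its edge conventions", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(c(5, 9, 11), c(5, 9, 11)), 1.0)
  expect_equal(tanimoto(1:4, 11:14), 0.0)
  expect_warning(z <- tanimoto(integer(0), integer(0)), "empty")
  expect_equal(z, 0)
  # symmetry over random pairs
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- sample.int(64, 10) - 1L
      b <- sample.int(64, 12) - 1L
      expect_identical(tanimoto(a, b), tanimoto(b, a))
    }
  })
})

test_that("novelty filter excludes strictly above the cutoff", {
  kb <- list(c(1L, 2L, 3L, 4L))
  lib <- fp_library(
    c("identical", "half", "far"),
    list(c(1L, 2L, 3L, 4L),    # T = 1.0 -> excluded
         c(1L, 2L, 5L, 6L),    # T = 2/6 -> retained
         c(50L, 51L)),         # T = 0   -> retained
    score = c(1, 2, 3))
  out <- novelty_filter(lib, kb, cutoff = 0.5)
  expect_setequal(out$retained$compound_id, c("half", "far"))
  expect_equal(out$excluded$compound_id, "identical")
  expect_equal(out$excluded$max_similarity, 1.0)

  # boundary: exactly at the cutoff is retained ("greater than" is strict)
  at_cut <- fp_library("edge", list(c(1L, 2L)), 1)   # T = 2/4 = 0.5 to kb2
  kb2 <- list(c(1L, 2L, 3L, 4L))
  expect_equal(novelty_filter(at_cut, kb2, 0.5)$retained$compound_id,
               "edge")
  # no known binders: everything is retained
  expect_equal(nrow(novelty_filter(lib, list(), 0.5)$retained), 3)
})

test_that("rank_and_truncate sorts by score with id tie-break", {
  lib <- fp_library(c("b", "a", "c", "d"),
                    list(1L, 2L, 3L, 4L),
                    score = c(0.9, 0.9, 0.5, 1.0))
  top <- rank_and_truncate(lib, 3)
  expect_equal(top$compound_id, c("d", "a", "b"))
  expect_equal(rank_and_truncate(lib, 99)$compound_id,
               c("d", "a", "b", "c"))
  lib$score[2] <- NA
  expect_error(rank_and_truncate(lib, 3), "missing score for: a")
})

test_that("butina clustering handles the degenerate extremes", {
  # all pairwise similarities >= cutoff: one cluster
  lib1 <- fp_library(c("x", "y", "z"),
                     list(c(1L, 2L), c(1L, 2L), c(1L, 2L, 3L)), 1:3)
  cl1 <- butina_cluster(lib1, 0.3)
  expect_equal(length(unique(cl1$cluster)), 1)
  # all pairwise similarities < cutoff: all singletons
  lib2 <- fp_library(c("x", "y", "z"),
                     list(c(1L, 2L), c(10L, 11L), c(20L, 21L)), 1:3)
  cl2 <- butina_cluster(lib2, 0.3)
  expect_equal(length(unique(cl2$cluster)), 3)
  expect_true(all(attr(cl2, "singleton")))
  # centroid is always a member of its own cluster
  expect_true(all(tapply(cl1$is_centroid, cl1$cluster, sum) == 1))
})

test_that("butina matches the exhaustive reference on random libraries", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed * 1000L, sample(4:12, 1))
    lib <- random_library(n, seed = seed)
    got <- butina_cluster(lib, 0.35)
    want <- oracle_butina(lib, 0.35)
    # same partition and same centroid-selection order
    expect_identical(got$cluster, want, label = paste("seed", seed))
  }
})

test_that("apply_filters attributes rejections to the failing predicate", {
  lib <- fp_library(c("ok", "heavy"), list(1L, 2L), c(1, 2),
                    properties = list(
                      list(mw = 300, logp = 2, hbd = 1, hba = 4),
                      list(mw = 600, logp = 2, hbd = 1, hba = 4)))
  out <- apply_filters(lib, lipinski_predicates())
  expect_equal(out$retained$compound_id, "ok")
  expect_equal(unname(out$rejections[["mw_le_500"]]), 1)
  expect_true(all(out$rejections[names(out$rejections) != "mw_le_500"] == 0))
  # empty predicate list is the identity
  expect_equal(apply_filters(lib, list())$retained$compound_id,
               lib$compound_id)
  # missing property is an error naming the property
  lib_bad <- fp_library("p", list(1L), 1, properties = list(list(mw = 100)))
  expect_error(apply_filters(lib_bad, lipinski_predicates()), "logp")
})

test_that("select_candidates picks the best member per cluster", {
  lib <- fp_library(c("a1", "a2", "b1", "c1"), list(1L, 2L, 3L, 4L),
                    score = c(0.8, 0.9, 0.7, 0.95))
  cl <- data.frame(compound_id = c("a1", "a2", "b1", "c1"),
                   cluster = c(1L, 1L, 2L, 3L),
                   is_centroid = c(TRUE, FALSE, TRUE, TRUE))
  sel <- select_candidates(cl, lib, 96)
  expect_equal(sel, c("c1", "a2", "b1"))   # one per cluster, best first
  expect_equal(select_candidates(cl, lib, 2), c("c1", "a2"))
  expect_error(select_candidates(cl, lib, 0), "n_select")
})

test_that("selection from all-singleton clusters equals plain ranking", {
  lib <- random_library(10, seed = 11)
  cl <- data.frame(compound_id = lib$compound_id,
                   cluster = seq_len(10), is_centroid = TRUE)
  expect_equal(select_candidates(cl, lib, 6),
               rank_and_truncate(lib, 6)$compound_id)
})

test_that("the funnel is stable under permutation of input order", {
  g <- gen_library(library_spec(n_compounds = 30, known_binder_seeds = 2,
                                cluster_plan = list(c(6, 0.02), c(6, 0.02)),
                                seed = 5))
  cfg <- triage_config(top_n = 30, n_select = 8)
  sel1 <- run_triage(g$library, g$known_binders, cfg)$selected
  perm <- withr::with_seed(9, sample(nrow(g$library)))
  sel2 <- run_triage(g$library[perm, ], g$known_binders, cfg)$selected
  expect_identical(sel1, sel2)
})
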