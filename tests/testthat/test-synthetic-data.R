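test_that("generators are pure functions of spec and seed", {
  s <- plate_spec(seed = 17)
  expect_identical(gen_plate(s), gen_plate(s))
  ls_ <- library_spec(n_compounds = 30, known_binder_seeds = 2, seed = 17)
  expect_identical(gen_library(ls_), gen_library(ls_))
  ts <- trajectory_spec(n_runs = 2, n_frames = 15, global_drift = 1,
                        seed = 17)
  expect_identical(gen_trajectory(ts)$ensemble, gen_trajectory(ts)$ensemble)
  ps <- pore_spec(seed = 17)
  expect_identical(gen_pore(ps), gen_pore(ps))
  # generators leave the global RNG stream untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(gen_plate(s))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("plate truths follow the planted hill curve", {
  # noiseless midpoint and vehicle identities
  s <- plate_spec(top = 0.6, bottom = 0, ic50 = 10, slope = 1.7,
                  doses = c(0, 1, 5, 10, 50, 200), noise_cv = 0,
                  background_fraction = 0.1, seed = 2)
  p <- gen_plate(s)
  w <- p$wells[!p$wells$is_untransfected, ]
  f <- fractional_efflux(w$efflux_signal, w$lysate_signal)
  expect_equal(unique(round(f[w$dose_uM == 10], 12)),
               0.1 + (0.6 + 0) / 2)           # background + hill midpoint
  expect_equal(unique(round(f[w$dose_uM == 0], 12)), 0.1 + 0.6)
  ut <- p$wells[p$wells$is_untransfected, ]
  expect_equal(unique(round(fractional_efflux(ut$efflux_signal,
                                              ut$lysate_signal), 12)), 0.1)
})

test_that("noisy plate fractions are unbiased within Monte-Carlo error", {
  s <- plate_spec(doses = c(0, rep(10, 99)), n_technical = 1,
                  n_biological = 2, noise_cv = 0.05, seed = 33)
  p <- gen_plate(s)
  w <- p$wells[!p$wells$is_untransfected & p$wells$dose_uM == 10, ]
  f <- fractional_efflux(w$efflux_signal, w$lysate_signal)
  truth <- 0.10 + hill_curve(10, 0.70, 0, 9.23, 1)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - truth), 3 * se + 1e-4)
})

test_that("plate spec rejects impossible fractions", {
  expect_error(plate_spec(top = 0.95, background_fraction = 0.2), "exceed")
  expect_error(plate_spec(ic50 = -1))
  expect_error(plate_spec(background_fraction = 0.8))
})

test_that("library plants clusters and look-alikes as specified", {
  g <- gen_library(library_spec(n_compounds = 30, n_bits = 256,
                                cluster_plan = list(c(8, 0), c(7, 0)),
                                known_binder_seeds = 3, seed = 12))
  # flip rate 0: every member identical to its cluster seed (T = 1)
  for (k in 1:2) {
    ids <- names(g$truth$membership)[g$truth$membership == k]
    b0 <- g$library$bits[[match(ids[1], g$library$compound_id)]]
    for (id in ids)
      expect_equal(tanimoto(g$library$bits[[match(id, g$library$compound_id)]],
                            b0), 1.0)
  }
  # exact look-alikes are exactly what the novelty filter removes
  out <- novelty_filter(g$library, g$known_binders, 0.5)
  expect_setequal(out$excluded$compound_id, g$truth$lookalikes)
  expect_equal(length(g$truth$lookalikes), 3)
})

test_that("well-separated planted clusters are recovered by butina", {
  g <- gen_library(library_spec(n_compounds = 20, n_bits = 512,
                                cluster_plan = list(c(10, 0), c(10, 0)),
                                seed = 21))
  cl <- butina_cluster(g$library, 0.35)
  expect_equal(length(unique(cl$cluster)), 2)
  # recovered partition matches the plant
  split_got <- split(cl$compound_id, cl$cluster)
  split_want <- split(names(g$truth$membership), g$truth$membership)
  expect_true(all(vapply(split_got, function(s)
    any(vapply(split_want, setequal, logical(1), y = s)), logical(1))))
})

test_that("trajectory fixture honours its zero-noise contracts", {
  # occupancy 1.0 forces a contact in every frame of the planned run
  plan <- data.frame(residue = 306L, run = 1L, occupancy = 1.0)
  tr <- gen_trajectory(trajectory_spec(
    n_runs = 1, n_frames = 12, contact_plan = plan,
    fragment_sigmas = c(a = 0, e = 0), global_drift = 0, seed = 9))
  cf <- contact_fractions(tr$ensemble, tr$topology, "ligand")
  expect_equal(cf$fractions$fraction[cf$fractions$residue == 306], 1.0)
  # all sigmas 0, no drift, constant plan: every frame equals frame 0
  arr <- tr$ensemble$runs[[1]]
  for (f in 2:12) expect_identical(arr[f, , ], arr[1, , ])
})

test_that("infeasible contact plans are rejected with a diagnostic", {
  # two planned residues so close together that one residue's contact
  # anchor sits within the cutoff of the other residue as well
  expect_error(
    gen_trajectory(trajectory_spec(
      n_runs = 1, n_frames = 10,
      pocket_residues = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
                          11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L,
                          19L, 20L, 21L, 22L, 23L, 24L, 25L, 26L,
                          27L, 28L, 29L, 30L, 31L, 32L, 33L, 34L,
                          35L, 36L, 37L, 38L, 39L, 40L),
      contact_plan = data.frame(residue = c(1L, 2L), run = 1L,
                                occupancy = c(1.0, 0)),
      fragment_sigmas = c(a = 0), seed = 10)),
    "infeasible")
})

test_that("pore fixtures carry an analytic truth", {
  cyl <- gen_pore(pore_spec("cylinder", wall_radius = 4, atom_radius = 1.5,
                            seed = 1))
  expect_true(all(cyl$truth$profile$probe_radius == 2.5))
  con <- gen_pore(pore_spec("constricted", constriction_radius = 2.25,
                            atom_radius = 1.5, seed = 1))
  expect_equal(con$truth$min$probe_radius, 0.75)
  expect_equal(con$truth$min$z, 0)
  expect_false(con$truth$coarse_tiling)
  coarse <- gen_pore(pore_spec("cylinder", atom_spacing = 2, seed = 1))
  expect_true(coarse$truth$coarse_tiling)
})
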