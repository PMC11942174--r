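rand_rot <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("kabsch recovers exact transforms and stays proper", {
  withr::with_seed(31, {
    ref <- matrix(rnorm(30), 10, 3)
    same <- kabsch_superpose(ref, ref)
    expect_equal(same$rmsd, 0, tolerance = 1e-12)
    expect_equal(same$rotation, diag(3), tolerance = 1e-9)
    for (i in 1:10) {
      R <- rand_rot(); t <- rnorm(3, 0, 5)
      mob <- sweep(ref %*% t(R), 2, t, "+")
      fit <- kabsch_superpose(mob, ref)
      expect_lt(fit$rmsd, 1e-8)
      expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    }
  })
})

test_that("kabsch RMSD matches the quaternion oracle on random sets", {
  withr::with_seed(32, {
    for (i in 1:50) {
      a <- matrix(rnorm(15), 5, 3)
      b <- matrix(rnorm(15), 5, 3)
      expect_equal(kabsch_superpose(a, b)$rmsd,
                   quaternion_superpose_rmsd(a, b), tolerance = 1e-9)
    }
    # second independent route: bio3d's least-squares fit
    a <- matrix(rnorm(24), 8, 3)
    b <- matrix(rnorm(24), 8, 3)
    fitted <- bio3d::fit.xyz(fixed = as.vector(t(b)),
                             mobile = as.vector(t(a)),
                             fixed.inds = 1:24, mobile.inds = 1:24)
    rmsd_bio3d <- sqrt(mean(rowSums(
      (matrix(fitted, ncol = 3, byrow = TRUE) - b)^2)))
    expect_equal(kabsch_superpose(a, b)$rmsd, rmsd_bio3d,
                 tolerance = 1e-6)
  })
})

test_that("kabsch rejects degenerate selections", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("alignment removes pure rigid drift exactly", {
  tr <- gen_trajectory(trajectory_spec(
    n_runs = 2, n_frames = 20,
    fragment_sigmas = c(a = 0, b = 0, c = 0, d = 0, e = 0),
    global_drift = 2, seed = 41))
  al <- align_ensemble(tr$ensemble, tr$topology)
  for (r in 1:2) {
    arr <- al$runs[[r]]
    for (f in 2:20)
      expect_lt(max(abs(arr[f, , ] - arr[1, , ])), 1e-6)
  }
  # an already-aligned ensemble is unchanged
  al2 <- align_ensemble(al, tr$topology)
  expect_equal(al2$runs, al$runs, tolerance = 1e-9)
})

test_that("mobility is zero for rigid fixtures and single frames", {
  tr <- gen_trajectory(trajectory_spec(
    n_runs = 1, n_frames = 10,
    fragment_sigmas = c(a = 0, b = 0, e = 0),
    global_drift = 0, seed = 43))
  mob <- group_com_trace(tr$ensemble, tr$topology, tr$scheme)
  expect_true(all(mob$sd$sd == 0))
  tr1 <- gen_trajectory(trajectory_spec(
    n_runs = 1, n_frames = 1,
    fragment_sigmas = c(a = 0.5, b = 1, e = 2), seed = 44))
  mob1 <- group_com_trace(tr1$ensemble, tr1$topology, tr1$scheme)
  expect_true(all(mob1$sd$sd == 0))
})

test_that("planted mobility ordering and magnitude are recovered", {
  tr <- gen_trajectory(trajectory_spec(n_runs = 5, n_frames = 500,
                                       global_drift = 0, seed = 45))
  mob <- group_com_trace(tr$ensemble, tr$topology, tr$scheme)
  sd_a <- mob$sd$sd[mob$sd$group == "a"]
  sd_e <- mob$sd$sd[mob$sd$group == "e"]
  expect_true(all(sd_e > sd_a))            # in every run
  # pooled RMS displacement of isotropic sigma-jitter ~ sqrt(3) * sigma
  expect_equal(unname(mob$pooled_sd["e"]), sqrt(3) * 2.0, tolerance = 0.15)
  expect_equal(unname(mob$pooled_sd["a"]), sqrt(3) * 0.2, tolerance = 0.15)
})

test_that("mobility and contacts are invariant under global rigid motion", {
  plan <- data.frame(residue = c(377L, 433L), run = c(1L, 2L),
                     occupancy = c(0.4, 0.6))
  base <- trajectory_spec(n_runs = 2, n_frames = 50, contact_plan = plan,
                          global_drift = 0, seed = 46)
  tr0 <- gen_trajectory(base)
  drifted <- base; drifted$global_drift <- 2
  tr1 <- gen_trajectory(drifted)
  a0 <- align_ensemble(tr0$ensemble, tr0$topology)
  a1 <- align_ensemble(tr1$ensemble, tr1$topology)
  m0 <- group_com_trace(a0, tr0$topology, tr0$scheme)
  m1 <- group_com_trace(a1, tr1$topology, tr1$scheme)
  expect_equal(m1$sd$sd, m0$sd$sd, tolerance = 1e-6)
  c0 <- contact_fractions(a0, tr0$topology, "ligand")
  c1 <- contact_fractions(a1, tr1$topology, "ligand")
  expect_equal(c1$fractions, c0$fractions, tolerance = 1e-12)
})

test_that("contact fractions honour the distance cutoff boundary", {
  # two-atom system: one residue atom at a fixed distance from one ligand atom
  mk <- function(d) {
    atoms <- data.frame(atom_id = 1:2, name = c("CA", "C1"),
                        element = "C", mass = 12.011,
                        resid = c(1L, 999L), resname = c("POC", "LIG"),
                        chain = c("A", "L"))
    top <- md_topology(atoms, list(ligand = 2L))
    arr <- array(0, c(3, 2, 3))
    arr[, 2, 1] <- d
    list(top = top, ens = trajectory_ensemble(list(arr)))
  }
  near <- mk(3.0)
  expect_equal(contact_fractions(near$ens, near$top, "ligand")$fractions$fraction, 1)
  far <- mk(3.6)
  expect_equal(contact_fractions(far$ens, far$top, "ligand")$fractions$fraction, 0)
  at <- mk(3.5)   # inclusive boundary
  expect_equal(contact_fractions(at$ens, at$top, "ligand")$fractions$fraction, 1)
})

test_that("contact fractions are monotone in the cutoff", {
  tr <- gen_trajectory(trajectory_spec(
    n_runs = 2, n_frames = 30,
    contact_plan = data.frame(residue = 377L, run = 1:2,
                              occupancy = c(0.5, 0.2)),
    seed = 47))
  f1 <- contact_fractions(tr$ensemble, tr$topology, "ligand", cutoff = 3.0)
  f2 <- contact_fractions(tr$ensemble, tr$topology, "ligand", cutoff = 3.5)
  f3 <- contact_fractions(tr$ensemble, tr$topology, "ligand", cutoff = 6.5)
  expect_true(all(f2$fractions$fraction >= f1$fractions$fraction))
  expect_true(all(f3$fractions$fraction >= f2$fractions$fraction))
})

test_that("planted occupancies are recovered exactly", {
  plan <- data.frame(residue = c(306L, 377L, 433L),
                     run = c(1L, 1L, 2L),
                     occupancy = c(0.30, 1.0, 0.74))
  tr <- gen_trajectory(trajectory_spec(n_runs = 2, n_frames = 100,
                                       contact_plan = plan, seed = 48))
  cf <- contact_fractions(tr$ensemble, tr$topology, "ligand")
  got <- cf$fractions
  for (i in seq_len(nrow(got))) {
    want <- unname(tr$truth$expected_fractions[as.character(got$residue[i]),
                                               got$run[i]])
    expect_identical(got$fraction[i], want)
  }
  # occupancy 1.0 means contact in every frame of that run
  expect_equal(got$fraction[got$residue == 377 & got$run == 1], 1.0)
})

test_that("aggregation applies the 30% / 3-of-5 inclusion rule inclusively", {
  mk_report <- function(frs) {
    structure(list(fractions = data.frame(residue = 1L, run = seq_along(frs),
                                          fraction = frs),
                   by_group = NULL, cutoff = 3.5, n_runs = length(frs)),
              class = "contact_report")
  }
  expect_equal(aggregate_contacts(mk_report(c(0.35, 0.31, 0.30, 0.10, 0))), 1L)
  expect_equal(length(aggregate_contacts(mk_report(rep(0.29, 5)))), 0)
  expect_equal(aggregate_contacts(mk_report(c(0.30, 0.30, 0.30, 0, 0))), 1L)
  expect_error(aggregate_contacts(mk_report(rep(1, 2)), run_quorum = 3),
               "exceeds")
})

test_that("frequency report applies a strict display threshold", {
  rep_ <- structure(list(
    fractions = data.frame(residue = c(1L, 1L, 2L, 2L, 3L, 3L),
                           run = c(1L, 2L, 1L, 2L, 1L, 2L),
                           fraction = c(0.41, 0.41, 0.40, 0.40, 0.9, 0.1)),
    by_group = NULL, cutoff = 3.5, n_runs = 2), class = "contact_report")
  tab <- frequency_report(rep_, 0.40)
  expect_setequal(tab$residue, c(1L, 3L))  # 0.40 exactly is excluded
  empty <- structure(list(fractions = data.frame(residue = integer(),
                                                 run = integer(),
                                                 fraction = numeric()),
                          by_group = NULL, cutoff = 3.5, n_runs = 0),
                     class = "contact_report")
  expect_equal(nrow(frequency_report(empty)), 0)
})
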