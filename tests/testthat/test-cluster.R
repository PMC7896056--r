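make_copies_ensemble <- function(pose, n) {
  coords <- array(rep(pose$xyz, n), dim = c(nrow(pose$xyz), 3, n))
  md_ensemble(pose$atoms, coords)
}

two_mode_ensemble <- function(n_a = 60, n_b = 40, noise_sd = 0.15,
                              seed = 101) {
  gen <- make_ensemble(ensemble_spec(
    n_frames = n_a + n_b, weights = c(n_a, n_b) / (n_a + n_b),
    switch_prob = 0.5, noise_sd = noise_sd, seed = seed))
  gen
}

test_that("averaging superposed members reproduces planted means", {
  pose <- synthetic_complex()
  # single member: just the superposed member itself
  avg1 <- average_structure(list(pose), pose)
  expect_equal(avg1$xyz, pose$xyz, tolerance = 1e-12)
  # two members displaced symmetrically along one axis average back
  d <- matrix(0, nrow(pose$xyz), 3); d[, 3] <- 0.4
  up <- labeled_structure(pose$atoms, pose$xyz + d)
  dn <- labeled_structure(pose$atoms, pose$xyz - d)
  avg2 <- average_structure(list(up, dn), pose)
  expect_equal(avg2$xyz, pose$xyz, tolerance = 1e-9)
  # three members with a known atom-wise mean after alignment (no
  # rotation component, so the mean is direct arithmetic)
  set.seed(71)
  offs <- lapply(1:3, function(i) matrix(rnorm(length(pose$xyz), 0, 0.1),
                                         nrow(pose$xyz), 3))
  members <- lapply(offs, function(o) labeled_structure(pose$atoms,
                                                        pose$xyz + o))
  ci <- which(pose$atoms$role == "protein-calpha")
  expected <- Reduce(`+`, lapply(members, function(m) {
    s <- kabsch_superpose(m$xyz[ci, ], pose$xyz[ci, ])
    apply_superposition(m$xyz, s)
  })) / 3
  avg3 <- average_structure(members, pose)
  expect_equal(avg3$xyz, expected, tolerance = 1e-10)
  expect_error(average_structure(list(), pose), "empty")
})

test_that("identical frames collapse to a single cluster equal to the frame", {
  pose <- synthetic_complex()
  ens <- make_copies_ensemble(pose, 10)
  res <- cluster_ensemble(ens)
  expect_length(res$clusters, 1L)
  expect_equal(res$clusters[[1]]$size, 10L)
  expect_equal(unname(res$assignment), rep(1L, 10))
  expect_equal(res$clusters[[1]]$average$xyz, pose$xyz, tolerance = 1e-9)
})

test_that("a single frame forms one cluster in one refinement cycle", {
  ens <- make_copies_ensemble(synthetic_complex(), 1)
  res <- cluster_ensemble(ens)
  expect_length(res$clusters, 1L)
  expect_equal(res$clusters[[1]]$iterations, 1L)
  expect_true(res$clusters[[1]]$converged)
})

test_that("planted two-mode ensembles are recovered exactly", {
  gen <- two_mode_ensemble()
  res <- cluster_ensemble(gen$ensemble)
  expect_length(res$clusters, 2L)
  expect_equal(ari(res$assignment, gen$truth$labels), 1.0)
  expect_equal(sort(vapply(res$clusters, `[[`, integer(1), "size")),
               sort(unname(as.integer(table(gen$truth$labels)))))
})

test_that("the assignment is always a partition of the frames", {
  for (seed in c(201, 202)) {
    gen <- make_ensemble(ensemble_spec(
      n_frames = 40, noise_sd = 0.6, switch_prob = 0.4, seed = seed))
    res <- cluster_ensemble(gen$ensemble, cutoff = 1.5)
    expect_true(all(res$assignment >= 1L))
    sizes <- vapply(res$clusters, `[[`, integer(1), "size")
    expect_equal(sum(sizes), n_frames(gen$ensemble))
    members <- sort(unlist(lapply(res$clusters, `[[`, "members")))
    expect_equal(members, seq_len(n_frames(gen$ensemble)))
  }
})

test_that("cutoff limits behave as expected", {
  gen <- two_mode_ensemble(n_a = 15, n_b = 10, seed = 103)
  # infinite cutoff: everything is one cluster
  res_inf <- cluster_ensemble(gen$ensemble, cutoff = 1e9)
  expect_length(res_inf$clusters, 1L)
  # vanishing cutoff on all-distinct frames: every frame is a singleton
  res_0 <- cluster_ensemble(gen$ensemble, cutoff = 1e-6)
  expect_length(res_0$clusters, n_frames(gen$ensemble))
  expect_true(all(vapply(res_0$clusters, `[[`, integer(1), "size") == 1L))
})

test_that("frame order within a well-separated mode does not change memberships", {
  gen <- two_mode_ensemble(n_a = 20, n_b = 15, seed = 104)
  res <- cluster_ensemble(gen$ensemble)
  # move a frame of the second discovered cluster to the front
  second <- res$clusters[[2]]$members[1]
  perm <- c(second, setdiff(seq_len(n_frames(gen$ensemble)), second))
  ens2 <- md_ensemble(gen$ensemble$topology,
                      gen$ensemble$coords[, , perm])
  res2 <- cluster_ensemble(ens2)
  # discovery order changes, the partition does not
  expect_equal(ari(res2$assignment, res$assignment[perm]), 1.0)
})

test_that("rmsd traces report per-frame deviation from a reference", {
  pose <- synthetic_complex()
  ens <- make_copies_ensemble(pose, 5)
  expect_equal(rmsd_trace(ens, pose), rep(0, 5), tolerance = 1e-10)
  # rigid ligand translation: constant closed-form trace
  li <- which(pose$atoms$role == "ligand-heavy")
  shifted <- pose$xyz
  shifted[li, ] <- sweep(shifted[li, ], 2, c(0, 0, 3), "+")
  ens2 <- md_ensemble(pose$atoms, array(rep(shifted, 4),
                                        dim = c(nrow(shifted), 3, 4)))
  m <- length(li)
  n <- m + sum(pose$atoms$role == "protein-calpha")
  expect_equal(rmsd_trace(ens2, pose), rep(3 * sqrt(m / n), 4),
               tolerance = 1e-9)
})

test_that("the trace of a two-mode ensemble is bimodal around the pose rmsds", {
  gen <- two_mode_ensemble(seed = 105)
  ref <- get_frame(gen$ensemble, which(gen$truth$labels == 1)[1])
  tr <- rmsd_trace(gen$ensemble, ref)
  in_mode <- tr[gen$truth$labels == gen$truth$labels[1] &
                  seq_along(tr) != which(gen$truth$labels == 1)[1]]
  # reference frame belongs to mode 1
  lab_ref <- gen$truth$labels[which(gen$truth$labels == 1)[1]]
  same <- tr[gen$truth$labels == lab_ref]
  other <- tr[gen$truth$labels != lab_ref]
  expect_lt(max(same), 2.0)
  expect_gt(min(other), 4.0)
})
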