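# Reaction coordinates, superposition RMSD, clustering and state
# classification.

test_that("distance series handles single-atom and centroid selections", {
  fr <- array(0, c(2, 4, 3))
  fr[1, 2, ] <- c(3, 4, 0)
  fr[2, 2, ] <- c(0, 0, 0)
  sp <- distance_spec("d", 1, 2)
  expect_equal(distance_series(fr, sp), c(5, 0))
  fr2 <- array(0, c(1, 3, 3))
  fr2[1, 2, ] <- c(1, 0, 0)
  fr2[1, 3, ] <- c(3, 0, 0)
  spc <- distance_spec("c", 1, c(2, 3), mode = "centroid")
  expect_equal(distance_series(fr2, spc), 2)
  expect_error(distance_spec("x", integer(0), 1), "non-empty")
  expect_error(distance_spec("x", c(1, 2), c(2, 3)), "disjoint")
  expect_error(distance_series(fr, distance_spec("d", 1, 9)),
               "selection error")
})

test_that("salt-bridge indicator uses the 5-unit formation cutoff", {
  expect_identical(salt_bridge_formed(c(3.3, 4.9, 5.0, 8.3)),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("superposition RMSD is invariant, symmetric and matches oracles", {
  set.seed(6)
  A <- matrix(rnorm(15), 5, 3)
  expect_equal(rmsd_after_superposition(A, A), 0, tolerance = 1e-12)
  R <- random_rotation()
  B <- A %*% R + matrix(rep(c(1, -2, 0.5), each = 5), 5, 3)
  expect_lt(rmsd_after_superposition(B, A), 1e-9)
  C <- A + matrix(rnorm(15, sd = 0.4), 5, 3)
  expect_equal(rmsd_after_superposition(C, A),
               rmsd_after_superposition(A, C), tolerance = 1e-9)
  expect_error(rmsd_after_superposition(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:4, 2 * (1:4), -(1:4))
  expect_error(rmsd_after_superposition(line, line), "collinear")

  # brute-force rotation-grid oracle on two 4-point sets
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0.8, 1.1, 0, 0.2, 0.4, 1.3), 4, 3,
              byrow = TRUE)
  Q <- P + matrix(c(0.1, -0.2, 0.05, 0, 0.15, -0.1,
                    -0.05, 0.1, 0.2, 0.12, 0, -0.08), 4, 3, byrow = TRUE)
  expect_equal(rmsd_after_superposition(P, Q), rmsd_grid_oracle(P, Q),
               tolerance = 1e-3)
})

test_that("superposition RMSD agrees with the bio3d reference fit", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  for (i in 1:5) {
    A <- matrix(rnorm(18), 6, 3)
    B <- A + matrix(rnorm(18, sd = 0.3), 6, 3)
    ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    expect_equal(rmsd_after_superposition(B, A), ref, tolerance = 1e-3)
  }
})

test_that("clustering recovers planted conformers and orders by population", {
  pc <- planted_conformers(n_each = 8)
  res <- hierarchical_cluster(pc$frames, n_clusters = 3)
  expect_true(same_partition(res$assignments, pc$truth))
  expect_equal(sum(res$populations), length(pc$truth))
  expect_true(all(diff(res$populations) <= 0))
  # representative is a member of its cluster
  for (cl in seq_along(res$populations))
    expect_equal(res$assignments[res$representatives[cl]], cl)
})

test_that("clustering degenerate cases behave as documented", {
  pc <- planted_conformers(n_each = 3)
  n <- dim(pc$frames)[1]
  singletons <- hierarchical_cluster(pc$frames, n_clusters = n)
  expect_true(all(singletons$populations == 1))
  expect_error(hierarchical_cluster(pc$frames, n_clusters = n + 1),
               "exceeds")
  # duplicating the frame set preserves the partition, doubling populations
  dup <- array(NA_real_, c(2 * n, dim(pc$frames)[2], 3))
  dup[seq_len(n), , ] <- pc$frames
  dup[n + seq_len(n), , ] <- pc$frames
  r1 <- hierarchical_cluster(pc$frames, n_clusters = 3)
  r2 <- hierarchical_cluster(dup, n_clusters = 3)
  expect_true(same_partition(r2$assignments[seq_len(n)], r1$assignments))
  expect_true(same_partition(r2$assignments[seq_len(n)],
                             r2$assignments[n + seq_len(n)]))
  expect_equal(sort(r2$populations), sort(2 * r1$populations))
})

test_that("cluster free energies follow the closed forms", {
  pc <- planted_conformers(n_each = 10)
  keep <- c(1:10, 11:17, 21:25)      # unbalanced populations 10, 7, 5
  res <- hierarchical_cluster(pc$frames[keep, , , drop = FALSE],
                              n_clusters = 3)
  n <- length(res$assignments)
  expect_equal(res$populations, c(10L, 7L, 5L))
  # dv = 0: dF_i = -ln(pop_i / pop_max)
  r0 <- cluster_free_energies(res, rep(0, n), beta = 1, cutoff_frames = 2)
  expect_equal(r0$delta_f,
               -log(r0$populations / max(r0$populations)),
               tolerance = 1e-9)
  # constant dv per cluster: dF difference picks up -(c2 - c1) on top of
  # the population term
  dv <- c(1.5, 4.0, 2.5)[res$assignments]
  rc <- cluster_free_energies(res, dv, beta = 1, cutoff_frames = 2)
  expected_diff <- -(log(res$populations[2] / res$populations[1]) +
                       (4.0 - 1.5))
  expect_equal(rc$delta_f[2] - rc$delta_f[1], expected_diff,
               tolerance = 1e-9)
  # single qualifying cluster anchors to zero
  r1 <- cluster_free_energies(res, rep(0, n), beta = 1,
                              cutoff_frames = max(res$populations))
  expect_equal(r1$delta_f[1], 0)
  expect_true(all(is.na(r1$delta_f[-1])))
  expect_error(cluster_free_energies(res, rep(0, n), cutoff_frames = 1e6),
               "empty profile")
  expect_error(cluster_free_energies(res, rep(0, n - 1)), "shape")
})

test_that("find_minima locates planted minima and honours the threshold", {
  hw <- make_harmonic_well(2)
  ph <- analytic_pmf(hw, beta = 1, bin_width = 0.5)
  mh <- find_minima(ph)
  expect_equal(nrow(mh), 1)
  expect_lt(abs(mh$position), 0.5)

  ts <- make_three_state_landscape(rbind(c(8.6, 8), c(11.1, 4), c(15.3, 5)),
                                   depths = c(6, 5, 5.5),
                                   widths = c(0.8, 0.8, 0.8))
  prof <- analytic_pmf(ts, coordinate_fn = function(p) p[, 1], beta = 1,
                       bin_width = 1, n_grid = 501L)
  m <- find_minima(prof, depth_threshold = 6)
  expect_equal(nrow(m), 3)
  expect_true(all(vapply(c(8.6, 11.1, 15.3), function(x0)
    any(abs(m$position - x0) <= 1), TRUE)))
  # depth_threshold = 0 keeps only the global minimum
  m0 <- find_minima(prof, depth_threshold = 0)
  expect_equal(nrow(m0), 1)
  expect_equal(m0$f_value, 0)
  # 2D minima on the full landscape
  prof2 <- analytic_pmf(ts, coordinate_fn = function(p) p, beta = 1,
                        bin_width = 1, n_grid = 401L)
  m2 <- find_minima(prof2, depth_threshold = 6)
  for (k in seq_len(3))
    expect_true(any(abs(m2$x - ts$minima[k, 1]) <= 1 &
                      abs(m2$y - ts$minima[k, 2]) <= 1))
})

test_that("state classification applies closed-open bands", {
  bands <- default_state_bands()
  m <- data.frame(position = c(15.3, 8.6, 11.1, 13.0, -2),
                  f_value = c(0.1, 0, 0.3, 0.2, 1))
  cs <- classify_states(m, bands)
  expect_identical(cs$state,
                   c("Active", "Inactive", "Intermediate", "Active",
                     "unassigned"))
  # the edge value 10 belongs to the upper band
  edge <- classify_states(data.frame(position = 10, f_value = 0), bands)
  expect_identical(edge$state, "Intermediate")
  expect_error(state_bands(c("A", "B"), c(0, 1)), "one more")
  expect_error(state_bands(c("A", "B"), c(0, 2, 1)), "increasing")
})

test_that("plateau ties resolve to the lowest-index bin center", {
  f <- array(c(2, 1, 1, 2, 0.5), 5)
  prof <- pepgamd:::new_profile(f, f, array(NA, 5), array(NA, 5),
                                array(1000, 5), idx0 = 0L, bin_width = 1,
                                beta = 1, cutoff_frames = 0)
  m <- find_minima(prof, depth_threshold = 3)
  expect_equal(nrow(m), 2)
  expect_true(1.5 %in% m$position)    # first bin of the {1,1} plateau
  expect_false(2.5 %in% m$position)
})
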