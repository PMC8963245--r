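# Analytic surfaces, the bead peptide-receptor system and the synthetic
# weighted-sample generator.

test_that("double well has the stated minima, barrier and stationary points", {
  dw <- make_double_well(barrier_height = 5, well_separation = 2)
  expect_equal(as.vector(dw$minima), c(-1, 1))
  v <- surface_energy(dw, c(-1, 0, 1))
  expect_equal(v[1], 0, tolerance = 1e-12)
  expect_equal(v[3], 0, tolerance = 1e-12)
  expect_equal(v[2] - v[1], 5, tolerance = 1e-12)
  g <- surface_gradient(dw, c(-1, 1))
  expect_lt(max(abs(g)), 1e-8)
  expect_error(make_double_well(0, 2), "barrier_height")
  expect_error(make_double_well(5, -1), "well_separation")
})

test_that("surface gradients agree with central finite differences", {
  surfaces <- list(
    make_harmonic_well(2.5),
    make_double_well(5, 2),
    make_three_state_landscape(rbind(c(8.6, 8), c(11.1, 4), c(15.3, 5)),
                               depths = c(6, 5, 5.5),
                               widths = c(0.8, 0.8, 0.8)))
  set.seed(1)
  h <- 1e-5
  for (s in surfaces) {
    d <- s$dimensionality
    for (rep in 1:20) {
      x <- runif(d, s$domain_bounds[1, ] + 0.5, s$domain_bounds[2, ] - 0.5)
      g <- as.numeric(surface_gradient(s, matrix(x, 1)))
      fd <- vapply(seq_len(d), function(j) {
        e <- numeric(d); e[j] <- h
        (surface_energy(s, matrix(x + e, 1)) -
           surface_energy(s, matrix(x - e, 1))) / (2 * h)
      }, 0.0)
      expect_equal(g, fd, tolerance = 1e-5)
      expect_true(is.finite(surface_energy(s, matrix(x, 1))))
    }
  }
})

test_that("three-state landscape plants recoverable local minima", {
  ts <- make_three_state_landscape(rbind(c(8.6, 8), c(11.1, 4), c(15.3, 5)),
                                   depths = c(5, 5, 5),
                                   widths = c(0.8, 0.8, 0.8))
  for (m in seq_len(3)) {
    ctr <- ts$minima[m, ]
    gx <- seq(ctr[1] - 1, ctr[1] + 1, by = 0.02)
    gy <- seq(ctr[2] - 1, ctr[2] + 1, by = 0.02)
    g <- as.matrix(expand.grid(gx, gy))
    found <- g[which.min(surface_energy(ts, g)), ]
    expect_lt(max(abs(found - ctr)), 0.1)
  }
  expect_error(make_three_state_landscape(rbind(c(0, 0)), 5, 0.5),
               "at least 2")
  expect_error(
    make_three_state_landscape(rbind(c(0, 0), c(1, 0)), c(5, 5), c(0.8, 0.8)),
    "overlapping")
})

test_that("doubling a basin's depth raises its Boltzmann occupancy", {
  mk <- function(d1) make_three_state_landscape(
    rbind(c(8.6, 8), c(11.1, 4), c(15.3, 5)),
    depths = c(d1, 4, 4), widths = c(0.7, 0.7, 0.7))
  occ1 <- basin_occupancy(mk(4))
  occ2 <- basin_occupancy(mk(8))
  expect_gt(occ2[1], occ1[1])
  expect_gt(occ2[1] / occ2[2], occ1[1] / occ1[2])
})

test_that("analytic_pmf matches closed forms and is shift/symmetry invariant", {
  hw <- make_harmonic_well(1.5)
  p <- analytic_pmf(hw, beta = 1, bin_width = 0.05, n_grid = 2000L)
  ctr <- p$centers[[1]]
  keep <- abs(ctr) < 1.5
  expected <- 0.5 * 1.5 * ctr^2
  expected <- expected - min(expected[keep])
  expect_lt(max(abs(as.vector(p$f)[keep] - expected[keep])), 1e-3)

  dw <- make_double_well(4, 2)
  pdw <- analytic_pmf(dw, beta = 1, bin_width = 0.2, n_grid = 2000L)
  f <- as.vector(pdw$f)
  expect_equal(f, rev(f), tolerance = 1e-6)   # symmetric well

  # adding a constant to the surface leaves the anchored PMF unchanged
  shifted <- make_custom_surface(function(x) dw$energy(x) + 7.3,
                                 domain_bounds = dw$domain_bounds)
  p_shift <- analytic_pmf(shifted, beta = 1, bin_width = 0.2,
                          n_grid = 2000L)
  expect_equal(as.vector(p_shift$f), as.vector(pdw$f), tolerance = 1e-9)
  expect_equal(min(pdw$f, na.rm = TRUE), 0)
  pr <- profile_probabilities(pdw)
  expect_equal(sum(pr, na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("analytic_pmf basin probabilities match an independent quadrature", {
  ts <- make_three_state_landscape(rbind(c(8.6, 8), c(11.1, 4), c(15.3, 5)),
                                   depths = c(6, 5, 5.5),
                                   widths = c(0.8, 0.8, 0.8))
  # profile-derived basin probabilities (bin width 0.5, grid 600)
  prof <- analytic_pmf(ts, beta = 1, bin_width = 0.5, n_grid = 600L)
  p <- profile_probabilities(prof)
  ctr <- prof$centers[[1]]
  splits <- c(-Inf, 10, 13.5, Inf)   # basin boundaries on bin edges
  p_prof <- vapply(seq_len(3), function(b)
    sum(p[ctr >= splits[b] & ctr < splits[b + 1]], na.rm = TRUE), 0.0)
  # independent x-split quadrature at a different resolution
  occ <- basin_occupancy_x(ts, beta = 1, splits = splits, n_grid = 977L)
  expect_equal(p_prof, occ, tolerance = 5e-3)
  expect_equal(-log(p_prof / p_prof[1]), -log(occ / occ[1]),
               tolerance = 0.02)
})

test_that("toy peptide system is deterministic and decomposes exactly", {
  s1 <- make_toy_peptide_system(3, seed = 1)
  s2 <- make_toy_peptide_system(3, seed = 1)
  expect_identical(s1, s2)
  expect_error(make_toy_peptide_system(1, seed = 1), "between 2 and 10")
  expect_error(make_toy_peptide_system(11, seed = 1), "between 2 and 10")

  # energy-decomposition conservation on random configurations
  set.seed(5)
  sys <- make_toy_peptide_system(5, seed = 3)
  for (i in seq_len(200)) {
    x <- sys$coords + matrix(rnorm(sys$n_beads * 3, sd = 0.8),
                             sys$n_beads, 3)
    x[sys$type == 1L, ] <- sys$coords[sys$type == 1L, ]
    e <- toy_energy(sys, x)
    expect_equal(e$v_total, sum(e$components), tolerance = 1e-12)
    v_indep <- bead_energy_R(sys$model, x)
    expect_equal(e$v_total, v_indep,
                 tolerance = 1e-9 * max(1, abs(v_indep)))
  }
})

test_that("peptide-receptor interaction decays and the funnel is attractive", {
  sys <- make_toy_peptide_system(3, seed = 2)
  far <- sys$coords
  far[sys$type == 0L, 1] <- far[sys$type == 0L, 1] + 1e3
  far[sys$type == 2L, 1] <- far[sys$type == 2L, 1] - 1e3
  e_far <- toy_energy(sys, far)
  expect_lt(abs(e_far$components[["pl_nb"]]), 1e-12)
  expect_lt(abs(e_far$components[["le_nb"]]), 1e-12)

  # hand-built bound vs unbound pose for the anchor pair
  bound <- sys$coords
  unbound <- sys$coords
  unbound[sys$type == 0L, 3] <- unbound[sys$type == 0L, 3] + 2.5
  expect_lt(toy_energy(sys, bound)$v_total,
            toy_energy(sys, unbound)$v_total)
})

test_that("receptor beads never move under dynamics", {
  sys <- make_toy_peptide_system(3, seed = 4)
  tr <- run_cmd(sys, protocol_spec(0, 0, 2000, n_replicas = 1, seed = 9))
  fr <- trajectory_frames(tr)
  for (i in which(sys$type == 1L))
    expect_equal(fr[dim(fr)[1], i, ], sys$coords[i, ], tolerance = 0)
})

test_that("synthetic weighted samples honour their contracts", {
  target <- function(x) (x - 5)^2 / 2
  s <- synth_weighted_samples(target, boost_gaussian(6, 2), n = 5000,
                              seed = 7, range = c(1, 9))
  expect_length(s$boost_values, length(s$coordinate_values))
  expect_true(all(s$boost_values >= 0))
  expect_error(synth_weighted_samples(target, boost_gaussian(6, 2), n = 0,
                                      seed = 1), "n must be >= 1")
  expect_error(boost_gaussian(6, -1), "sd")

  # constant boost: reweighted profile equals the unweighted histogram
  # PMF of the same draws, bin by bin
  sc <- synth_weighted_samples(target, boost_constant(4), n = 20000,
                               seed = 8, range = c(1, 9))
  p_rw <- reweight_profile(sc$coordinate_values, sc$boost_values,
                           bin_width = 0.5, cutoff_frames = 50)
  p_plain <- reweight_profile(sc$coordinate_values,
                              rep(0, length(sc$boost_values)),
                              bin_width = 0.5, cutoff_frames = 50)
  expect_equal(as.vector(p_rw$f), as.vector(p_plain$f), tolerance = 1e-12)
})

test_that("gaussian-boost synthetic samples reweight back to the target", {
  target <- function(x) 2 * (x - 5)^2 * ((x - 5)^2 - 2) / 4 + 2
  s <- synth_weighted_samples(target, boost_gaussian(6, 2), n = 5e5,
                              seed = 7, range = c(2, 8))
  prof <- reweight_profile(s$coordinate_values, s$boost_values,
                           bin_width = 0.25, cutoff_frames = 500)
  ctr <- prof$centers[[1]]
  f_target <- vapply(ctr, target, 0.0)
  keep <- is.finite(prof$f)
  f_target <- f_target - min(f_target[keep])
  err <- abs(as.vector(prof$f)[keep] - f_target[keep])
  expect_lt(max(err), 0.3)
})
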