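# Boost law, adaptive k0 selection, running statistics and the staged
# Langevin engine.

test_that("boost potential follows the harmonic law with a zero branch", {
  p <- list(k = 0.01, threshold_E = 100)
  expect_equal(boost_potential(90, p), 0.5 * 0.01 * 10^2, tolerance = 1e-15)
  expect_identical(boost_potential(100, p), 0)
  expect_identical(boost_potential(150, p), 0)
  # continuity at the threshold
  eps <- 1e-8
  expect_lt(boost_potential(100 - eps, p), 1e-12)
  expect_true(all(boost_potential(seq(0, 200, 5), p) >= 0))
})

test_that("boosted force scale damps but never inverts forces", {
  p <- list(k = 0.01, threshold_E = 100)
  expect_identical(boosted_force_scale(100, p), 1)
  expect_identical(boosted_force_scale(150, p), 1)
  # extreme allowed damping: k0 = 1 at V = Vmin gives scale 0
  vmax <- 100; vmin <- 0
  pe <- list(k = 1 / (vmax - vmin), threshold_E = vmax)
  expect_equal(boosted_force_scale(vmin, pe), 0, tolerance = 1e-15)
  # monotone non-decreasing in V below E
  v <- seq(0, 100, 1)
  expect_true(all(diff(boosted_force_scale(v, pe)) >= 0))
  expect_true(all(boosted_force_scale(v[-1], pe) > 0))
})

test_that("k0 formulas reproduce direct evaluation, including fallback", {
  expect_equal(k0_lower_bound(100, 0, 80, 5, 10), 1)
  expect_equal(k0_lower_bound(100, 0, 50, 10, 1), 0.2)
  expect_equal(k0_lower_bound(100, 0, 0.0 + 1e-300, 5, 5), 1)
  k0u <- k0_upper_bound(100, 0, 50, 11, 10)
  expect_equal(as.numeric(k0u), (1 - 10 / 11) * 2, tolerance = 1e-12)
  expect_identical(attr(k0u, "branch"), "upper")
  k0f <- k0_upper_bound(100, 0, 50, 40, 10)
  expect_equal(as.numeric(k0f), 0.5)
  expect_identical(attr(k0f, "branch"), "fallback_lower")
  # sigma_v <= sigma_0 forces the fallback (k0'' <= 0)
  k0n <- k0_upper_bound(100, 0, 50, 5, 10)
  expect_identical(attr(k0n, "branch"), "fallback_lower")
  expect_error(k0_lower_bound(100, 0, 100, 5, 10), "degenerate")
  expect_error(k0_lower_bound(100, 0, 50, 0, 10), "degenerate")

  # property: on random valid statistic tuples both formulas agree with
  # their closed forms and k0 stays in (0, 1]
  set.seed(11)
  for (i in 1:150) {
    vmin <- rnorm(1, 0, 50)
    vmax <- vmin + runif(1, 1, 100)
    vavg <- runif(1, vmin + 1e-3, vmax - 1e-3)
    sv <- runif(1, 0.1, 20)
    s0 <- runif(1, 0.1, 20)
    direct <- min(1, (s0 / sv) * (vmax - vmin) / (vmax - vavg))
    expect_equal(k0_lower_bound(vmax, vmin, vavg, sv, s0), direct,
                 tolerance = 1e-12)
    expect_true(direct > 0 && direct <= 1)
    up <- k0_upper_bound(vmax, vmin, vavg, sv, s0)
    kdd <- (1 - s0 / sv) * (vmax - vmin) / (vavg - vmin)
    if (kdd > 0 && kdd <= 1) {
      expect_equal(as.numeric(up), kdd, tolerance = 1e-12)
      expect_identical(attr(up, "branch"), "upper")
    } else {
      expect_equal(as.numeric(up), direct, tolerance = 1e-12)
      expect_identical(attr(up, "branch"), "fallback_lower")
    }
  }
})

test_that("running statistics are exact, stable and order-invariant", {
  p <- gamd_params(10)
  p <- update_statistics(p, 5)
  expect_equal(p$v_max, 5)
  expect_equal(p$v_min, 5)
  expect_equal(p$v_avg, 5)
  expect_equal(p$sigma_v, 0)
  expect_true(is.na(p$k0))          # deferred until spread appears

  p <- gamd_params(10)
  p <- update_statistics(p, c(1, 2, 3))
  expect_equal(p$v_avg, 2)
  expect_equal(p$sigma_v, sqrt(2 / 3), tolerance = 1e-12)

  set.seed(3)
  v <- rnorm(500, 10, 4)
  batchings <- list(v, rev(v), sample(v))
  stats <- lapply(batchings, function(vv) {
    q <- gamd_params(10)
    # mixed scalar/vector incremental updates
    q <- update_statistics(q, vv[1:100])
    for (z in vv[101:110]) q <- update_statistics(q, z)
    q <- update_statistics(q, vv[111:500])
    c(q$v_avg, q$sigma_v, q$v_max, q$v_min)
  })
  expect_equal(stats[[1]], stats[[2]], tolerance = 1e-10)
  expect_equal(stats[[1]], stats[[3]], tolerance = 1e-10)
  expect_equal(stats[[1]][1], mean(v), tolerance = 1e-12)
  expect_equal(stats[[1]][2], sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
})

test_that("threshold bracket Vmax <= E <= Vmin + 1/k holds in both modes", {
  set.seed(4)
  v <- rnorm(2000, 50, 6)
  for (mode in c("lower", "upper")) {
    for (s0 in c(0.5, 3, 10)) {
      p <- update_statistics(gamd_params(s0, mode), v)
      expect_gte(p$threshold_E, p$v_max * (1 - 1e-9) - 1e-9)
      expect_lte(p$threshold_E, (p$v_min + 1 / p$k) * (1 + 1e-9) + 1e-9)
      expect_true(p$k0 > 0 && p$k0 <= 1)
      expect_equal(p$k, p$k0 / (p$v_max - p$v_min), tolerance = 1e-12)
      # the SD constraint on the collected statistics themselves
      expect_lte(sigma_dv(p), s0 * (1 + 1e-9))
    }
  }
})

test_that("cMD sampling is canonical, deterministic and validated", {
  hw <- make_harmonic_well(2)
  pr <- protocol_spec(0, 0, 400000, n_replicas = 1, seed = 3)
  tr <- run_cmd(hw, pr)
  expect_true(all(tr$dv_total == 0))
  # equipartition: var(x) = kT / kappa
  expect_equal(var(trajectory_frames(tr)[, 1]), 1 / 2, tolerance = 0.05)
  tr2 <- run_cmd(hw, pr)
  expect_identical(trajectory_frames(tr), trajectory_frames(tr2))
  expect_error(protocol_spec(0, 0, 100, friction = 0), "NVE")
  expect_error(protocol_spec(-1, 0, 100), "n_cmd_steps")
})

test_that("integration instability raises a named error", {
  hw <- make_harmonic_well(1e6)   # far too stiff for dt = 0.5
  pr <- protocol_spec(0, 0, 1000, n_replicas = 1, dt = 0.5, seed = 1)
  expect_error(run_cmd(hw, pr), "instability.*step", perl = TRUE)
})

test_that("zero sigma_0 degenerates Pep-GaMD to cMD", {
  sys <- make_toy_peptide_system(3, seed = 1)
  pr <- protocol_spec(1000, 3000, 3000, n_replicas = 1, seed = 5)
  run <- run_pep_gamd(sys, pr, sigma_0_L = 0, sigma_0_D = 0)
  expect_lt(max(run$production[[1]]$dv_total), 1e-12)
})

test_that("trajectory boost columns satisfy the bookkeeping identities", {
  sys <- make_toy_peptide_system(3, seed = 1)
  pr <- protocol_spec(2000, 6000, 6000, n_replicas = 2, seed = 6)
  run <- run_pep_gamd(sys, pr, sigma_0_L = 6, sigma_0_D = 6)
  pL <- run$params$peptide
  pD <- run$params$rest
  for (tr in run$production) {
    expect_identical(tr$dv_total, tr$dv_peptide + tr$dv_rest)
    # offline recomputation from the frozen parameters
    expect_equal(tr$dv_peptide, boost_potential(tr$v_peptide, pL),
                 tolerance = 1e-12)
    expect_equal(tr$dv_rest, boost_potential(tr$v_rest, pD),
                 tolerance = 1e-12)
    # zero branch whenever V >= E
    expect_true(all(tr$dv_peptide[tr$v_peptide >= pL$threshold_E] == 0))
    expect_true(all(tr$dv_rest[tr$v_rest >= pD$threshold_E] == 0))
  }
  # replicas differ (independent streams)
  expect_false(identical(run$production[[1]]$v_total,
                         run$production[[2]]$v_total))
})

test_that("order preservation and smoothing hold on production frames", {
  sys <- make_toy_peptide_system(3, seed = 2)
  pr <- protocol_spec(2000, 8000, 8000, n_replicas = 1, seed = 7)
  run <- run_pep_gamd(sys, pr, sigma_0_L = 6, sigma_0_D = 6)
  tr <- run$production[[1]]
  for (term in c("peptide", "rest")) {
    v <- tr[[paste0("v_", term)]]
    dv <- tr[[paste0("dv_", term)]]
    p <- run$params[[term]]
    # guarantees apply on the statistics bracket [Vmin, E]
    below <- which(v < p$threshold_E & v >= p$v_min)
    o <- below[order(v[below])]
    vs <- v[o] + dv[o]
    dvv <- diff(v[o])
    pos <- dvv > 1e-12
    expect_true(all(diff(vs)[pos] > -1e-9))              # order preserved
    expect_true(all(diff(vs)[pos] < dvv[pos] + 1e-9))    # contraction
  }
})

test_that("equilibration keeps sigma_dV within sigma_0 and production near it", {
  sys <- make_toy_peptide_system(3, seed = 3)
  s0 <- 1.5   # small enough that the constraint actually binds
  pr <- protocol_spec(2000, 15000, 15000, n_replicas = 1, seed = 8)
  run <- run_pep_gamd(sys, pr, sigma_0_L = s0, sigma_0_D = s0)
  for (term in c("peptide", "rest")) {
    p <- run$params[[term]]
    expect_lte(sigma_dv(p), s0 * (1 + 1e-9))  # exact on equil statistics
    dv <- run$production[[1]][[paste0("dv_", term)]]
    expect_lte(sd(dv), 1.2 * s0)              # empirical, with slack
  }
})

test_that("same protocol seed reproduces a full staged run", {
  sys <- make_toy_peptide_system(3, seed = 4)
  pr <- protocol_spec(1000, 4000, 4000, n_replicas = 2, seed = 10)
  r1 <- run_pep_gamd(sys, pr, 6, 6)
  r2 <- run_pep_gamd(sys, pr, 6, 6)
  expect_identical(r1$production[[1]]$v_total, r2$production[[1]]$v_total)
  expect_identical(trajectory_frames(r1$production[[2]]),
                   trajectory_frames(r2$production[[2]]))
  expect_equal(r1$params$peptide$k, r2$params$peptide$k)
})
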