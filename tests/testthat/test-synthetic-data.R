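test_that("gen_fjc reproduces ideal-chain closed forms", {
  # single bond: end-to-end length is exactly b for every sample
  tr1 <- gen_fjc(1, b = 2.5, n_samples = 50, seed = 1)
  L1 <- vapply(tr1$frames, function(f) sqrt(sum((f$coords[2, ] - f$coords[1, ])^2)),
               numeric(1))
  expect_equal(L1, rep(2.5, 50), tolerance = 1e-12)

  # N = 100, b = 1: sqrt(<L^2>)/(N b) = 1/sqrt(N) = 0.100 +- 0.002
  tr <- gen_fjc(100, 1, n_samples = 20000, seed = 2)
  bb <- select_role(tr$topology, "backbone")
  L <- vapply(tr$frames, end_to_end_length, numeric(1), backbone_selection = bb)
  expect_equal(sqrt(mean(L^2)) / 100, 0.100, tolerance = 0.002 / 0.100)

  # <Rg^2> within 2% of the large-N limit N b^2 / 6
  rg <- vapply(tr$frames, radius_of_gyration, numeric(1), selection = bb)
  expect_equal(mean(rg^2), 100 / 6, tolerance = 0.02)

  # determinism
  tr_b <- gen_fjc(5, 1, n_samples = 3, seed = 99)
  tr_c <- gen_fjc(5, 1, n_samples = 3, seed = 99)
  expect_identical(tr_b$frames[[3]]$coords, tr_c$frames[[3]]$coords)
})

test_that("FJC ensemble moments match exact closed forms within 3 SE", {
  for (N in c(9, 16, 25, 100)) {
    tr <- gen_fjc(N, 1, n_samples = 4000, seed = 100 + N)
    bb <- select_role(tr$topology, "backbone")
    L2 <- vapply(tr$frames, end_to_end_length, numeric(1),
                 backbone_selection = bb)^2
    se <- sd(L2) / sqrt(length(L2))
    expect_lt(abs(mean(L2) - N), 3 * se)          # <L^2> = N b^2, exact at every N
    rg2 <- vapply(tr$frames, radius_of_gyration, numeric(1), selection = bb)^2
    exact <- N * (N + 2) / (6 * (N + 1))          # discrete-chain closed form
    se_rg <- sd(rg2) / sqrt(length(rg2))
    expect_lt(abs(mean(rg2) - exact), 3 * se_rg)
  }
})

test_that("gen_ideal_gas is uniform, seeded and validates n", {
  expect_error(gen_ideal_gas(0, 20), ">= 1")
  f1 <- gen_ideal_gas(500, 20, seed = 5)
  f2 <- gen_ideal_gas(500, 20, seed = 5)
  expect_identical(f1$coords, f2$coords)
  expect_true(all(f1$coords >= 0 & f1$coords <= 20))
})

test_that("gen_shell_cloud plants a recoverable Gaussian shell", {
  # A = 1 degenerates to an ideal gas: g ~ 1
  tr <- gen_shell_cloud(3.6, 0.3, 1.0, 0.0334, 30, n_ref = 1, n_frames = 40, seed = 4)
  r <- rdf(tr, 1L, select_role(tr$topology, "water_oxygen"), dr = 0.1)
  win <- r$r_centers >= 2 & r$r_centers <= 30 / 4
  expect_gt(mean(r$g[win]), 0.98)
  expect_lt(mean(r$g[win]), 1.02)

  # far-field density equals rho within 2%
  ff <- r$r_centers >= 3.6 + 4 * 0.3 & r$r_centers <= 0.9 * 15
  expect_equal(mean(r$g[ff]), 1, tolerance = 0.02)

  # planted bump recovered (moderate statistics here; the full-strength
  # planted-parameter recovery lives in the acceptance suite)
  tr2 <- gen_shell_cloud(3.6, 0.3, 2.0, 0.0334, 44, n_ref = 8, n_frames = 150, seed = 5)
  r2 <- rdf(tr2, select_role(tr2$topology, "terminal_carbon"),
            select_role(tr2$topology, "water_oxygen"), dr = 0.1, r_max = 12)
  pk <- first_peak(r2)
  expect_true(pk$found)
  expect_equal(pk$r, 3.6, tolerance = 0.1 / 3.6)
  expect_equal(pk$g_raw, 2.0, tolerance = 0.08)

  # A < 1: first feature is a trough. On the exact planted profile (the
  # noiseless oracle) no peak exists at all; on sampled data nothing
  # meaningfully above bulk may be reported (1.05 = bulk + ~3 sigma of the
  # flat-region noise at this sampling depth)
  rr <- seq(0.05, 12, by = 0.1)
  gstar <- 1 + (0.5 - 1) * exp(-(rr - 3.6)^2 / (2 * 0.3^2))
  expect_false(first_peak(list(r_centers = rr, g = gstar))$found)
  tr3 <- gen_shell_cloud(3.6, 0.3, 0.5, 0.0334, 44, n_ref = 8, n_frames = 100, seed = 6)
  r3 <- rdf(tr3, select_role(tr3$topology, "terminal_carbon"),
            select_role(tr3$topology, "water_oxygen"), dr = 0.1, r_max = 12)
  pk3 <- first_peak(r3)
  expect_true(!pk3$found || pk3$g <= 1.08)   # bulk + ~3 sigma at this depth

  # overlapping reference spheres are rejected
  expect_error(gen_shell_cloud(3.6, 0.3, 2.0, 0.0334, 30, n_ref = 2, n_frames = 1,
                               ref_coords = rbind(c(5, 5, 5), c(8, 5, 5))),
               "overlap")
  expect_error(gen_shell_cloud(10, 1.5, 2.0, 0.03, 30), "does not fit")
})

test_that("gen_hbond_fixture plants exact counts and auditable margins", {
  crit <- hbond_criteria(3.5, 150)
  fx <- gen_hbond_fixture(5, 3, 2, criteria = crit, seed = 6)
  expect_equal(nrow(find_hbonds(fx$frame, fx$topology, criteria = crit)), 5)

  fx0 <- gen_hbond_fixture(0, 10, 10, criteria = crit, seed = 7)
  expect_equal(nrow(find_hbonds(fx0$frame, fx0$topology, criteria = crit)), 0)

  # margins shrunk to 1e-6: the <= / >= convention keeps in-bonds detected
  # and near-misses excluded right up to the boundary
  fx_in <- gen_hbond_fixture(4, 0, 0, criteria = crit, seed = 8,
                             margin_d_in = 1e-6, margin_angle = 1e-6)
  expect_equal(nrow(find_hbonds(fx_in$frame, fx_in$topology, criteria = crit)), 4)
  fx_out <- gen_hbond_fixture(0, 4, 4, criteria = crit, seed = 9,
                              margin_d_in = 0.2, margin_d_out = 1e-6,
                              margin_angle = 1e-6)
  expect_equal(nrow(find_hbonds(fx_out$frame, fx_out$topology, criteria = crit)), 0)
})

test_that("gen_peak_curve tabulates curves for direct TCRP testing", {
  cv1 <- gen_peak_curve(c(278, 300, 323), c(1.2, 1.1, 0.9))
  res <- tcrp(cv1)
  expect_true(res$found)
  expect_gt(res$tcrp, 300); expect_lt(res$tcrp, 323)
  expect_equal(res$bracket, c(300, 323))

  expect_false(tcrp(gen_peak_curve(c(300, 350), c(1.5, 1.2)))$found)

  lin <- gen_peak_curve(c(278, 300, 323, 343, 368), function(T) 2 - T / 300)
  expect_equal(tcrp(lin)$tcrp, 300, tolerance = 1e-12)
})

test_that("toy temperature series melts the hydration shell monotonically", {
  temps <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  gs <- vapply(temps, function(T) {
    tr <- run_toy_langevin(temperature = T, seed = 900 + round(10 * T))
    r <- rdf(tr, select_role(tr$topology, "terminal_carbon"),
             select_role(tr$topology, "water_oxygen"), dr = 0.1)
    first_peak(r)$g
  }, numeric(1))
  expect_true(all(is.finite(gs)))
  # non-increasing within sampling error at this run length (single seeds:
  # ~2 sigma of a point-to-point difference)
  expect_true(all(diff(gs) < 0.2))
  # the series brackets g = 1, so a finite crossing is recovered inside it
  res <- tcrp(gen_peak_curve(temps, gs))
  expect_true(res$found)
  expect_gt(res$tcrp, temps[1]); expect_lt(res$tcrp, temps[length(temps)])
})

test_that("toy Langevin simulator is seeded, finite and validated", {
  tr <- run_toy_langevin(n_monomers = 8, solvent_count = 40, n_steps = 400,
                         n_equil = 100, stride = 50, seed = 3)
  tr2 <- run_toy_langevin(n_monomers = 8, solvent_count = 40, n_steps = 400,
                          n_equil = 100, stride = 50, seed = 3)
  expect_identical(tr$frames[[length(tr$frames)]]$coords,
                   tr2$frames[[length(tr2$frames)]]$coords)
  expect_true(all(vapply(tr$frames, function(f) all(is.finite(f$coords)), logical(1))))
  # bonds stay near the rest length under WCA + springs
  bb <- select_role(tr$topology, "backbone")
  last <- tr$frames[[length(tr$frames)]]
  co <- hydroshell:::unwrap_path(last$coords[bb, ], last$box)
  blen <- sqrt(rowSums((co[-1, ] - co[-nrow(co), ])^2))
  expect_true(all(blen > 0.5 * 3.4 & blen < 1.8 * 3.4))
  expect_error(run_toy_langevin(dt = 2, friction = 1), "unstable")
  expect_error(run_toy_langevin(density = 0.95), "density")
})
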