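test_that("generators are deterministic under a fixed seed", {
  a <- gen_kinetics(139, 0.145, seed = 5)
  b <- gen_kinetics(139, 0.145, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, gen_kinetics(139, 0.145, seed = 6)))
  m1 <- gen_melt(79.1, seed = 5); m2 <- gen_melt(79.1, seed = 5)
  expect_identical(m1$ratio, m2$ratio)
  t1 <- gen_trajectory(n_frames = 20, seed = 5)
  t2 <- gen_trajectory(n_frames = 20, seed = 5)
  expect_identical(t1, t2)
  s1 <- gen_eis_timeseries(10, duration_h = 0.1, dt_min = 6, seed = 5)
  s2 <- gen_eis_timeseries(10, duration_h = 0.1, dt_min = 6, seed = 5)
  expect_identical(s1[[2]]$impedance, s2[[2]]$impedance)
})

test_that("seeded generation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(3)
  set.seed(123)
  invisible(gen_kinetics(139, 0.145, seed = 99))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("gen_eis_timeseries: noiseless pipeline returns the rate exactly", {
  sp <- gen_eis_timeseries(rate_um_h = 21, duration_h = 9, dt_min = 15,
                           noise = 0, seed = 1)
  series <- fit_eis_series(sp)
  r <- degradation_rate(series, window = c(3, 8))
  expect_equal(r$rate_um_h, 21, tolerance = 1e-6)
  # rate 0: all sweeps identical without noise
  sp0 <- gen_eis_timeseries(0, duration_h = 0.2, dt_min = 6, noise = 0)
  expect_equal(sp0[[1]]$impedance, sp0[[3]]$impedance)
  # floor engages with a warning when the film would vanish
  expect_warning(gen_eis_timeseries(21, duration_h = 20, dt_min = 60,
                                    noise = 0),
                 "floor")
})

test_that("gen_kinetics: noiseless values lie on the law; duplicates present", {
  kin <- gen_kinetics(139, 0.145, cv = 0, n_rep = 2, seed = 1)
  expect_equal(kin$rate_nmol_g_s,
               inverse_mm_rate(kin$enzyme_um, 139, 0.145))
  expect_equal(sort(unique(kin$replicate)), 1:2)
  # blanks carry no noise
  kin2 <- gen_kinetics(139, 0.145, cv = 0.05, seed = 2)
  expect_true(all(kin2$rate_nmol_g_s[kin2$enzyme_um == 0] == 0))
  expect_error(gen_kinetics(139, 0.145, cv = -0.1), ">= 0")
})

test_that("gen_titration is monotone, starts at zero, and calibrates", {
  cfg <- reactor_config()
  sim <- gen_titration(cfg, target_pct = 90, target_time_h = 31.8)
  expect_equal(sim$naoh_mol[1], 0)
  expect_true(all(diff(sim$naoh_mol) >= 0))
  i <- which(sim$percent >= 90)[1]
  expect_lt(abs(stats::approx(sim$percent[(i - 1):i],
                              sim$time_h[(i - 1):i], 90)$y - 31.8), 0.02)
  expect_error(gen_titration(cfg, final_fraction = 0.8, target_pct = 90,
                             target_time_h = 30),
               "exceeds")
})

test_that("gen_trajectory frames classify back to their labels exactly", {
  occ <- c(in_oxyanion = 0.45, near_active_site = 0.25, other = 0.30)
  traj <- gen_trajectory(occ, n_frames = 300, seed = 71)
  labs <- vapply(traj, classify_frame, "")
  expect_identical(labs, unname(attr(traj, "labels")))
  # occupancy converges to the generator setting (binomial tolerance)
  big <- gen_trajectory(occ, n_frames = 2000, seed = 72)
  frac <- state_fractions(big)
  expect_lt(abs(unclass(frac)[["in_oxyanion"]] - 0.45), 0.03)
  expect_error(gen_trajectory(c(in_oxyanion = 0.7, other = 0.7), 10),
               "sum")
})

test_that("gen_salt_bridge_trajectory respects its contact labels", {
  traj <- gen_salt_bridge_trajectory(0.45, 400, seed = 73)
  occ <- salt_bridge_occupancy(traj, 148, 233, cutoff = 4.0)
  expect_equal(as.numeric(occ), mean(attr(traj, "contacts")))
  # degenerate probabilities
  expect_equal(as.numeric(salt_bridge_occupancy(
    gen_salt_bridge_trajectory(1, 50, seed = 74), 148, 233)), 1)
  expect_equal(as.numeric(salt_bridge_occupancy(
    gen_salt_bridge_trajectory(0, 50, seed = 75), 148, 233)), 0)
})

test_that("gen_perturbed_structure honors target RMSD on large structures", {
  base <- toy_structure(n = 500, seed = 81)
  pert <- gen_perturbed_structure(base, target_rmsd = 0.6, seed = 82)
  expect_equal(attr(pert, "expected_rmsd"), 0.6, tolerance = 1e-12)
  expect_equal(kabsch_superpose(base, pert)$rmsd, 0.6, tolerance = 0.12)
  # pure rigid motion: RMSD zero but coordinates moved
  rigid <- gen_perturbed_structure(base, jitter_sd = 0, seed = 83)
  expect_gt(max(abs(rigid$x - base$x)), 1)
  expect_equal(kabsch_superpose(base, rigid)$rmsd, 0, tolerance = 1e-9)
})
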