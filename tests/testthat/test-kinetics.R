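test_that("standard curve fits and inverts", {
  conc <- seq(0, 1, by = 0.1)
  # perfect line A = 0.9 c
  cv <- suppressWarnings(fit_standard_curve(conc, 0.9 * conc)) # lm perfect-fit note
  expect_equal(cv$slope, 0.9, tolerance = 1e-12)
  expect_equal(quantify_tpa(0.45, cv), 0.5, tolerance = 1e-12)
  expect_equal(quantify_tpa(cv$intercept, cv), 0, tolerance = 1e-12)
  expect_warning(quantify_tpa(cv$intercept - 0.05, cv), "negative")
  expect_error(fit_standard_curve(c(0, 1), c(0, 1)), "at least 3")
  expect_error(fit_standard_curve(rep(0.5, 5), rnorm(5)), "zero variance")
})

test_that("noisy standard-curve slope is recovered within 2 SE", {
  conc <- seq(0, 1, by = 0.1)
  ok <- petkit:::with_seed(41, replicate(50, {
    a <- 0.05 + 0.9 * conc + rnorm(11, 0, 0.01)
    cv <- fit_standard_curve(conc, a)
    abs(cv$slope - 0.9) <= 2 * cv$slope_se
  }))
  expect_gte(mean(ok), 0.9)
})

test_that("inverse-MM law midpoint and point values", {
  # v at [E] = inv_KM is half of inv_Vmax
  expect_equal(inverse_mm_rate(0.145, 139, 0.145), 139 / 2)
  # direct evaluation: 139 * 0.29 / (0.145 + 0.29)
  expect_equal(inverse_mm_rate(0.29, 139, 0.145), 92.66667,
               tolerance = 1e-6)
  expect_equal(inverse_mm_rate(0, 139, 0.145), 0)
})

test_that("fit_inverse_mm recovers noiseless parameters exactly", {
  grid <- c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.45, 0.6)
  for (pars in list(c(139, 0.145), c(83, 0.117), c(124, 0.164),
                    c(60.5, 0.178))) {
    v <- inverse_mm_rate(grid, pars[1], pars[2])
    fit <- fit_inverse_mm(grid, v)
    expect_equal(fit$inv_Vmax, pars[1], tolerance = 1e-7)
    expect_equal(fit$inv_KM, pars[2], tolerance = 1e-7)
  }
})

test_that("fit validates its inputs", {
  expect_error(fit_inverse_mm(c(0, 0.1, 0.2), c(0, 1, 2)),
               "4 distinct")
  grid <- c(0, 0.1, 0.2, 0.3, 0.4)
  expect_error(fit_inverse_mm(grid, rep(0, 5)), "all rates are zero")
})

test_that("fit is invariant under replicate ordering and zero-anchor flag works", {
  kin <- gen_kinetics(139, 0.145, cv = 0.05, n_rep = 2, seed = 17)
  f1 <- fit_inverse_mm(kin$enzyme_um, kin$rate_nmol_g_s)
  perm <- petkit:::with_seed(18, sample(nrow(kin)))
  f2 <- fit_inverse_mm(kin$enzyme_um[perm], kin$rate_nmol_g_s[perm])
  expect_equal(f1$inv_KM, f2$inv_KM, tolerance = 1e-9)
  f3 <- fit_inverse_mm(kin$enzyme_um, kin$rate_nmol_g_s,
                       include_zero = FALSE)
  expect_equal(f3$n, sum(kin$enzyme_um > 0))
})

test_that("fitted curve is monotone, saturating, and through the origin", {
  kin <- gen_kinetics(120, 0.2, cv = 0.05, seed = 19)
  fit <- fit_inverse_mm(kin$enzyme_um, kin$rate_nmol_g_s)
  E <- seq(0, 5, by = 0.05)
  v <- fit$fitted_fn(E)
  expect_equal(v[1], 0)
  expect_true(all(diff(v) > 0))
  expect_lt(max(v), fit$inv_Vmax)
})

test_that("parameter recovery: low bias and ~2 SE coverage over seeds", {
  # the 100-dataset duplicate design; relative weighting matches the
  # constant-CV noise, giving ~95% nominal 2-SE coverage
  res <- t(vapply(1:100, function(s) {
    kin <- gen_kinetics(139, 0.145, cv = 0.05, n_rep = 2, seed = 1000 + s)
    fit <- fit_inverse_mm(kin$enzyme_um, kin$rate_nmol_g_s)
    c(km = fit$inv_KM, vx = fit$inv_Vmax,
      cov_km = abs(fit$inv_KM - 0.145) <= 2 * fit$se[["inv_KM"]],
      cov_vx = abs(fit$inv_Vmax - 139) <= 2 * fit$se[["inv_Vmax"]])
  }, numeric(4)))
  expect_lt(abs(stats::median(res[, "km"]) - 0.145) / 0.145, 0.02)
  expect_lt(abs(stats::median(res[, "vx"]) - 139) / 139, 0.02)
  expect_gte(mean(res[, "cov_km"]), 0.9)
  expect_gte(mean(res[, "cov_vx"]), 0.9)
})
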