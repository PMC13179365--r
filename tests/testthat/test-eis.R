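test_that("randles_impedance matches its closed forms and limits", {
  p <- randles_params(100, 1e6, 5.805e-12)
  # low-frequency limit: capacitor open, Z -> R_s + R_ct
  expect_equal(Re(randles_impedance(p, 1e-6)), 100 + 1e6, tolerance = 1e-6)
  # high-frequency limit: capacitor shorts, Z -> R_s
  expect_equal(Re(randles_impedance(p, 1e12)), 100, tolerance = 1e-3)
  # corner frequency omega = 1/(R_ct C): Z = R_s + R_ct (1 - i)/2
  fc <- 1 / (2 * pi * 1e6 * 5.805e-12)
  expect_equal(randles_impedance(p, fc), complex(real = 500100,
                                                 imaginary = -500000),
               tolerance = 1e-12)
  expect_error(randles_impedance(p, -1), "> 0")
  expect_error(randles_params(0, 1, 1), "> 0")
})

test_that("model imaginary part is non-positive at all frequencies", {
  set.seed(7)
  for (k in 1:20) {
    p <- randles_params(10^runif(1, 0, 3), 10^runif(1, 3, 7),
                        10^runif(1, -12, -9))
    f <- 10^runif(25, 0, 7)
    expect_true(all(Im(randles_impedance(p, f)) <= 0))
  }
})

test_that("fit_randles recovers noiseless parameters to < 1e-6 relative", {
  freqs <- exp(seq(log(1e3), log(1e6), length.out = 51))
  set.seed(11)
  for (k in 1:5) {
    truth <- randles_params(10^runif(1, 1, 3), 10^runif(1, 5, 6.5),
                            10^runif(1, -12, -11))
    Z <- randles_impedance(truth, freqs)
    fit <- fit_randles(impedance_spectrum(freqs, Z))
    expect_lt(abs(fit$R_s - truth$R_s) / truth$R_s, 1e-6)
    expect_lt(abs(fit$R_ct - truth$R_ct) / truth$R_ct, 1e-6)
    expect_lt(abs(fit$C_film - truth$C_film) / truth$C_film, 1e-6)
  }
})

test_that("fit_randles tolerates 1% noise within ~3% and is order-invariant", {
  freqs <- exp(seq(log(1e3), log(1e6), length.out = 51))
  truth <- randles_params(100, 1e6, 5.805e-12)
  # Monte-Carlo (scaled down from the 100-seed design study to 20 here)
  errs <- petkit:::with_seed(21, replicate(20, {
    Z <- randles_impedance(truth, freqs)
    Z <- complex(real = Re(Z) * (1 + 0.01 * rnorm(51)),
                 imaginary = Im(Z) * (1 + 0.01 * rnorm(51)))
    fit <- fit_randles(impedance_spectrum(freqs, Z))
    abs(fit$C_film - truth$C_film) / truth$C_film
  }))
  expect_lt(stats::median(errs), 0.03)
  # reordering frequency points leaves the fit unchanged
  Z <- petkit:::with_seed(5, {
    Z0 <- randles_impedance(truth, freqs)
    complex(real = Re(Z0) * (1 + 0.01 * rnorm(51)),
            imaginary = Im(Z0) * (1 + 0.01 * rnorm(51)))
  })
  perm <- petkit:::with_seed(6, sample(51))
  f1 <- fit_randles(impedance_spectrum(freqs, Z))
  f2 <- fit_randles(impedance_spectrum(freqs[perm], Z[perm]))
  expect_equal(f1$C_film, f2$C_film, tolerance = 1e-10)
})

test_that("underdetermined spectra are rejected", {
  p <- randles_params(100, 1e6, 5.805e-12)
  f2 <- c(1e3, 1e6)
  expect_error(impedance_spectrum(f2, randles_impedance(p, f2)),
               "at least 6")
})

test_that("capacitance/thickness conversion inverts exactly", {
  geom <- film_geometry()  # eps_r 3.3, 44.7 mm^2
  # 225 um <-> 5.805 pF (value printed to 4 digits)
  expect_equal(capacitance_to_thickness(5.805e-12, geom), 225,
               tolerance = 1e-4)
  C225 <- thickness_to_capacitance(225, geom)
  expect_equal(capacitance_to_thickness(C225, geom), 225, tolerance = 1e-12)
  # inverse proportionality
  expect_equal(capacitance_to_thickness(2 * C225, geom), 112.5,
               tolerance = 1e-12)
  expect_error(capacitance_to_thickness(-1e-12, geom), "> 0")
})

test_that("degradation_rate is exact on linear series and shift-invariant", {
  t <- seq(0, 20, by = 0.05)
  d <- 225 - 21 * t
  d <- pmax(d, 5)
  r <- degradation_rate(t, d, window = c(3, 8))
  expect_equal(r$rate_um_h, 21, tolerance = 1e-10)
  # constant thickness -> zero rate
  r0 <- degradation_rate(t, rep(100, length(t)), window = c(3, 8))
  expect_equal(r0$rate_um_h, 0, tolerance = 1e-12)
  # invariance under time shift and thickness offset
  r1 <- degradation_rate(t + 5, d, window = c(8, 13))
  r2 <- degradation_rate(t, d + 40, window = c(3, 8))
  expect_equal(r1$rate_um_h, r$rate_um_h, tolerance = 1e-10)
  expect_equal(r2$rate_um_h, r$rate_um_h, tolerance = 1e-10)
  expect_error(degradation_rate(t, d, window = c(19, 30)), "outside")
})

test_that("degradation_rate recovers a noisy linear rate within tolerance", {
  # 3-min sampling, sigma 0.5 um, rate 21: expect 21 +/- 0.3 (Monte-Carlo)
  t <- seq(0, 20, by = 0.05)
  est <- petkit:::with_seed(31, replicate(20, {
    d <- pmax(225 - 21 * t, 5) + rnorm(length(t), 0, 0.5)
    d <- pmax(d, 1)
    degradation_rate(t, d, window = c(3, 8))$rate_um_h
  }))
  expect_true(all(abs(est - 21) < 0.3))
})
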