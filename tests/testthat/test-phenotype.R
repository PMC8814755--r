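# Phenotype extraction: sizing inversion, velocity, strain, wCDI and the
# linearized Kelvin-Voigt recovery fit.

test_that("sizing inversion round-trips the blockade relation", {
  geom <- channel_geometry()
  f11 <- blockade_fraction(11e-6, geom$sizing, geom)
  expect_equal(diameter_from_blockade(f11, geom$sizing, geom), 11e-6,
               tolerance = 1e-9)

  set.seed(40)
  d <- runif(200, 7.5e-6, 13e-6)
  f <- blockade_fraction(d, geom$sizing, geom)
  back <- diameter_from_blockade(f, geom$sizing, geom)
  expect_lt(max(abs(back - d) / d), 1e-9)

  expect_error(diameter_from_blockade(0, geom$sizing, geom), "range")
  expect_error(diameter_from_blockade(0.9, geom$sizing, geom), "range")
  # small fractions invert to small diameters (continuity at zero)
  expect_lt(diameter_from_blockade(1e-8, geom$sizing, geom), 1e-6)
})

test_that("velocity is segment length over sizing duration", {
  geom <- channel_geometry()
  s <- list(t_start = 0, t_end = 800e-6 / 12e-3)  # 66.7 ms
  expect_equal(compute_velocity(s, geom), 12e-3)
  s2 <- list(t_start = 0, t_end = 2 * (800e-6 / 12e-3))
  expect_equal(compute_velocity(s2, geom), 6e-3)
  expect_error(compute_velocity(list(t_start = 1, t_end = 1), geom),
               "positive")
})

test_that("strain follows (d0 - wc) / d0 with the contraction width as dc", {
  geom <- channel_geometry()
  expect_error(compute_strain(7e-6, geom), "deformation")
  g2 <- channel_geometry(contraction = channel_segment(5e-6, 2000e-6))
  expect_equal(compute_strain(10e-6, g2), 0.5)
  # the 7 um contraction applied to ~10.8 um cells gives the operating
  # strain of ~0.35 (inversion: d0 = wc / (1 - eps))
  d0 <- 7e-6 / 0.65
  expect_equal(compute_strain(d0, geom), 0.35)
})

test_that("wCDI reproduces direct arithmetic and its proportionalities", {
  g <- channel_geometry(h_channel = 10e-6)
  expect_equal(compute_wcdi(10e-6, 10e-3, 0.2, g), 1.0)

  geom <- channel_geometry()
  expected <- (2000e-6 / (12e-3 * 12.9e-6)) * (11e-6 / 0.160)
  expect_equal(compute_wcdi(11e-6, 12e-3, 0.160, geom), expected)
  expect_equal(expected, 0.888, tolerance = 0.001)

  base <- compute_wcdi(11e-6, 12e-3, 0.160, geom)
  expect_equal(compute_wcdi(11e-6, 12e-3, 0.320, geom), base / 2)
  expect_equal(compute_wcdi(22e-6, 12e-3, 0.160, geom), base * 2)
  expect_error(compute_wcdi(0, 12e-3, 0.1, geom), "positive")
})

test_that("wCDI is invariant under a global change of length/time units", {
  # same physics expressed in mm and ms instead of m and s
  geom_si <- channel_geometry()
  geom_mm <- channel_geometry(h_channel = 12.9e-3,
                              sizing = channel_segment(13e-3, 800e-3),
                              contraction = channel_segment(7e-3, 2000e-3),
                              node = channel_segment(85e-3, 50e-3),
                              recovery = rep(list(channel_segment(13e-3, 290e-3)), 10))
  w_si <- compute_wcdi(11e-6, 12e-3, 0.160, geom_si)      # m, m/s, s
  w_mm <- compute_wcdi(11e-3, 0.012, 160, geom_mm)        # mm, mm/ms, ms
  expect_equal(w_si, w_mm)
})

test_that("the linearized fit is exact on noiseless exponentials", {
  # current-scale decays: for small tau the late levels cancel against
  # i_inf, so rounding is amplified; the fit must stay floating-point
  # limited (<< any physical noise) across the whole band
  t_mid <- seq(0.025, 0.475, by = 0.05)
  for (tau in c(0.02, 0.1, 0.3, 0.8, 2.0)) {
    lev <- 1e-7 + 3e-8 * exp(-t_mid / tau)
    fit <- fit_recovery(recovery_table(t_mid, lev), i_inf = 1e-7, t0 = 0)
    expect_true(fit$valid)
    expect_equal(fit$tau, tau, tolerance = 1e-5)
    expect_equal(fit$i0_amp, 3e-8, tolerance = 1e-5)
    expect_gt(fit$r_squared, 0.9999)
  }
  # decays around a zero floor carry no cancellation: exact to machine
  # precision across the whole band, including very short tau
  set.seed(41)
  for (tau in c(0.005, 0.02, 0.8, 2.0, runif(20, 0.005, 2))) {
    lev <- 5 * exp(-t_mid / tau)
    fit <- fit_recovery(recovery_table(t_mid, lev), i_inf = 0, t0 = 0)
    expect_equal(fit$tau, tau, tolerance = 1e-12)
    expect_equal(fit$i0_amp, 5, tolerance = 1e-12)
  }
})

test_that("degenerate recovery inputs are flagged invalid, not errors", {
  t_mid <- c(0.05, 0.15, 0.25)
  lev <- 1e-7 + 3e-8 * exp(-t_mid / 0.1)
  fit <- fit_recovery(recovery_table(t_mid, lev), i_inf = 1e-7, t0 = 0)
  expect_false(fit$valid)
  expect_equal(fit$n_points, 3L)

  # fully recovered cell: all levels at i_inf
  flat <- fit_recovery(recovery_table(seq(0.05, 0.45, by = 0.1),
                                      rep(1e-7, 5)), i_inf = 1e-7, t0 = 0)
  expect_false(flat$valid)

  # increasing deficit (positive slope) is unidentifiable
  t5 <- seq(0.05, 0.45, by = 0.1)
  rising <- fit_recovery(recovery_table(t5, 1e-7 + 1e-9 * t5),
                         i_inf = 1e-7, t0 = 0)
  expect_false(rising$valid)
})

test_that("the linearized estimator agrees with a grid-search NLS oracle", {
  t_mid <- seq(0.025, 0.475, by = 0.05)
  for (tau in c(0.02, 0.1, 0.3, 0.8)) {
    lev <- 1e-7 + 3e-8 * exp(-t_mid / tau)
    fit <- fit_recovery(recovery_table(t_mid, lev), i_inf = 1e-7, t0 = 0)
    oracle <- tau_grid_oracle(t_mid, lev, 1e-7)
    expect_lt(abs(fit$tau - oracle), 1e-3 + 1e-9)
  }
})

test_that("the linearized estimator tracks unconstrained NLS on noisy data", {
  set.seed(42)
  t_mid <- seq(0.025, 0.475, by = 0.05)
  tau <- 0.3; amp <- 3e-8; i_inf <- 1e-7
  rel <- replicate(1000, {
    lev <- i_inf + amp * exp(-t_mid / tau) + rnorm(10, 0, 0.05 * amp)
    fit <- fit_recovery(recovery_table(t_mid, lev), i_inf = i_inf, t0 = 0)
    nl <- tryCatch(stats::nls(lev ~ i_inf + a * exp(-t_mid / tt),
                              start = list(a = amp, tt = 0.25)),
                   error = function(e) NULL)
    if (is.null(nl) || !fit$valid) return(NA_real_)
    tau_nl <- coef(nl)[["tt"]]
    abs(fit$tau - tau_nl) / tau_nl
  })
  expect_lt(median(rel, na.rm = TRUE), 0.06)
})

test_that("end-to-end phenotypes match simulated ground truth", {
  sim <- simulate_cells(5, noise_sigma = 0, seed = 43)
  res <- analyze_trace(sim$trace)
  expect_equal(nrow(res$features), 5L)
  tr <- match_truth(res$features, res$events, sim$truth)
  f <- res$features
  expect_lt(max(abs(f$d0 - tr$d0) / tr$d0), 1e-6)
  expect_lt(max(abs(f$t_cont - tr$t_cont)), 0.4e-3)
  expect_lt(max(abs(f$tau - tr$tau) / tr$tau), 0.01)
  expect_lt(max(abs(f$wcdi - tr$wcdi_true) / tr$wcdi_true), 0.01)
  expect_true(all(f$strain > 0 & f$strain < 1))
  expect_true(all(f$fit_valid))
  # CI brackets the point estimate
  expect_true(all(f$tau_ci_low <= f$tau & f$tau <= f$tau_ci_high))
})
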