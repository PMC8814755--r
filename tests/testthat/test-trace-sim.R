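# Forward model: blockade physics, per-cell schedules, cohort sampling and
# trace synthesis.

test_that("blockade fraction matches direct volume-blockade arithmetic", {
  geom <- channel_geometry()
  expect_identical(blockade_fraction(0, geom$sizing, geom), 0)

  # independent recomputation of the Deblois-Bean relation for an 11 um
  # sphere in the 13 x 800 um sizing segment at 12.9 um height
  de <- 2 * sqrt(13e-6 * 12.9e-6 / pi)
  d <- 11e-6
  expected <- (d^3 / (de^2 * 800e-6)) / (1 - 0.8 * (d / de)^3)
  expect_equal(blockade_fraction(d, geom$sizing, geom), expected,
               tolerance = 1e-12)
  expect_equal(expected, 1.18e-2, tolerance = 0.01)

  expect_error(blockade_fraction(de, geom$sizing, geom), "occlusion")
  expect_error(blockade_fraction(-1e-6, geom$sizing, geom), "non-negative")
})

test_that("blockade fraction is strictly increasing in diameter", {
  geom <- channel_geometry()
  de <- effective_diameter(geom$sizing, geom)
  d <- seq(1e-8, de * (1 - 1e-6), length.out = 1000)
  f <- blockade_fraction(d, geom$sizing, geom)
  expect_true(all(diff(f) > 0))
})

test_that("event schedule follows the Kelvin-Voigt relaxation of subpulse depths", {
  geom <- channel_geometry()
  acq <- acquisition_config()
  base <- list(entry_time = 1.5, d0 = 11e-6, u_flow = 8e-3, t_cont = 0.2,
               tau = 0.1, deficit = 0.3)
  ds_depth <- acq$baseline_current *
    blockade_fraction(11e-6, geom$sizing, geom)

  # already-recovered cell: every recovery depth equals the sizing depth
  s0 <- simulate_event(modifyList(base, list(deficit = 0)), geom, acq)
  expect_equal(s0$depth[s0$kind == "recovery"], rep(ds_depth, 10))
  expect_equal(s0$depth[s0$kind == "sizing"], ds_depth)

  # tau at the generation bound: depths nearly constant at (1 - deficit)
  sinf <- simulate_event(modifyList(base, list(tau = 2.0)), geom, acq)
  rec_inf <- sinf$depth[sinf$kind == "recovery"]
  expect_equal(rec_inf, rep(0.7 * ds_depth, 10), tolerance = 0.15)

  # closed-form spot check with midpoint times recomputed independently
  # from the geometry: t_k = k * node_dt + (k - 1/2) * rec_dt after exit
  s1 <- simulate_event(base, geom, acq)
  node_dt <- geom$node$length / base$u_flow
  rec_dt <- geom$recovery[[1]]$length / base$u_flow
  k <- 1:10
  t_k <- k * node_dt + (k - 0.5) * rec_dt
  expect_equal(s1$depth[s1$kind == "recovery"],
               ds_depth * (1 - 0.3 * exp(-t_k / 0.1)), tolerance = 1e-12)
  expect_equal(s1$depth[s1$kind == "contraction"], 3 * ds_depth)
  expect_equal(diff(s1[s1$kind == "contraction", c("t_start", "t_end")][1, ]
                    |> as.numeric()), 0.2)
})

test_that("cohort sampling is reproducible and honours degenerate distributions", {
  p <- group_params("g")
  c1 <- sample_cohort(p, 50, seed = 42)
  c2 <- sample_cohort(p, 50, seed = 42)
  expect_identical(c1, c2)

  pz <- group_params("z", d0_sdlog = 0, t_cont_sdlog = 0, tau_sdlog = 0,
                     u_flow_sd = 0)
  cz <- sample_cohort(pz, 200, seed = 1)
  expect_equal(length(unique(cz$d0)), 1L)
  expect_equal(length(unique(cz$tau)), 1L)
  expect_true(all(cz$d0 > channel_geometry()$contraction$width))
})

test_that("sampled tau medians preserve the programmed group ratio", {
  pa <- group_params("a", tau_median = 0.3)
  pb <- group_params("b", tau_median = 0.1)
  ta <- sample_cohort(pa, 200, seed = 11)$tau
  tb <- sample_cohort(pb, 200, seed = 12)$tau
  expect_equal(median(ta) / median(tb), 3, tolerance = 0.15)
  expect_true(all(ta >= 0.005 & ta <= 2))
})

test_that("trace synthesis superposes scheduled events on baseline + drift + noise", {
  # zero cells: pure baseline + noise, and nothing to detect
  acq <- acquisition_config(noise_sigma = 2e-9, seed = 3)
  empty <- simulate_trace(list(), acq, duration = 12)
  expect_equal(nrow(empty$truth), 0L)
  expect_equal(mean(empty$trace$samples), acq$baseline_current,
               tolerance = 1e-3)
  res <- analyze_trace(empty$trace)
  expect_equal(nrow(res$events), 0L)

  # noiseless: the trace equals the schedule exactly
  acq0 <- acquisition_config(noise_sigma = 0, seed = 4)
  sim <- simulate_trace(list(list(params = group_params("g"), n = 3)), acq0)
  x <- sim$trace$samples
  tt <- trace_times(sim$trace)
  for (i in seq_len(nrow(sim$schedule))) {
    row <- sim$schedule[i, ]
    inside <- tt >= row$t_start + 1e-4 & tt < row$t_end - 1e-4
    expect_equal(unique(acq0$baseline_current - x[inside]), row$depth,
                 tolerance = 1e-12)
  }
  gaps <- x[tt < sim$truth$entry_time[1] - 1e-3]
  expect_true(all(gaps == acq0$baseline_current))
})

test_that("identical seeds give bit-identical traces", {
  co <- list(list(params = group_params("g"), n = 4))
  s1 <- simulate_trace(co, acquisition_config(seed = 99))
  s2 <- simulate_trace(co, acquisition_config(seed = 99))
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$truth, s2$truth)
})
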