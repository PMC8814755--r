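# Pulse detection, subpulse segmentation and event QC.

test_that("no events are reported on flat noisy traces", {
  set.seed(7)
  tr <- raw_trace(rnorm(60 * 50000, 1e-5, 5e-9), 50000)
  ds <- preprocess_trace(tr)
  bl <- estimate_baseline(ds)
  ev <- detect_pulses(ds, bl)
  expect_equal(nrow(ev), 0L)
})

test_that("detection recovers event boundaries from a simulated trace", {
  sim <- simulate_cells(3, noise_sigma = noise_for_snr(10), seed = 31)
  res <- analyze_trace(sim$trace)
  expect_equal(nrow(res$events), 3L)
  expect_true(all(res$events$qc_code == "ok"))
  # each detected boundary within 2 downsampled samples (0.8 ms) of schedule
  per <- 2 / 2500
  for (i in 1:3) {
    sch <- sim$schedule[sim$schedule$cell_id == sim$truth$cell_id[i], ]
    expect_lt(abs(res$events$t_start[i] - min(sch$t_start)), per)
    expect_lt(abs(res$events$t_end[i] - max(sch$t_end)), per)
  }
})

test_that("noiseless events decompose into exactly 12 subpulses with exact depths", {
  sim <- simulate_cells(2, noise_sigma = 0, seed = 32)
  res <- analyze_trace(sim$trace)
  for (i in 1:2) {
    sp <- res$subpulses[res$subpulses$event_id == i, ]
    expect_equal(nrow(sp), 12L)
    expect_equal(sp$kind, c("sizing", "contraction", rep("recovery", 10)))
    expect_equal(sp$order[sp$kind == "recovery"], 1:10)
    sch <- sim$schedule[sim$schedule$cell_id == sim$truth$cell_id[i], ]
    sch <- sch[order(sch$t_start), ]
    expect_equal(sp$depth, sch$depth, tolerance = 1e-9)
  }
})

test_that("overlapping transits merge into events that QC flags as coincidence", {
  sim <- simulate_cells(20, noise_sigma = noise_for_snr(20), seed = 5,
                        overlap_fraction = 0.2)
  res <- analyze_trace(sim$trace)
  qc <- table(res$events$qc_code)
  expect_true(qc[["coincidence"]] >= 1)
  # conservation: accepted events never exceed simulated cells, and every
  # non-overlapped cell is recovered
  expect_lte(sum(res$events$qc_code == "ok"), 20)
  expect_equal(sum(res$events$qc_code == "ok") +
                 2 * sum(res$events$qc_code == "coincidence"), 20)
})

test_that("an event cut off by the end of the trace is flagged truncated", {
  sim <- simulate_cells(2, noise_sigma = 0, seed = 33)
  sch2 <- sim$schedule[sim$schedule$cell_id == sim$truth$cell_id[2], ]
  cut <- floor((min(sch2$t_start) + 0.25) * 50000)
  clipped <- raw_trace(sim$trace$samples[1:cut], 50000)
  res <- analyze_trace(clipped)
  expect_equal(nrow(res$events), 2L)
  expect_equal(res$events$qc_code, c("ok", "truncated"))
})

test_that("QC rejects events whose recovery depths decrease beyond tolerance", {
  sim <- simulate_cells(1, noise_sigma = 0, seed = 34)
  ds <- preprocess_trace(sim$trace)
  bl <- estimate_baseline(ds)
  ev <- detect_pulses(ds, bl)
  sp <- segment_subpulses(ev[1, ], ds, bl, channel_geometry())
  expect_equal(qc_event(ev[1, ], sp, channel_geometry(),
                        noise_scale = bl$noise_scale,
                        n_samples = length(ds$samples))$code, "ok")
  # inject a decreasing recovery amplitude well beyond 3 sigma
  bad <- sp
  bad$depth[bad$kind == "recovery" & bad$order == 5] <-
    0.5 * bad$depth[bad$kind == "recovery" & bad$order == 4]
  verdict <- qc_event(ev[1, ], bad, channel_geometry(),
                      noise_scale = bl$noise_scale,
                      n_samples = length(ds$samples))
  expect_equal(verdict$code, "low_snr")
})

test_that("subpulse depth errors scale with noise over the plateau interior", {
  sig <- noise_for_snr(20)
  sim <- simulate_cells(25, noise_sigma = sig, seed = 35)
  res <- analyze_trace(sim$trace)
  expect_true(all(res$events$qc_code == "ok"))
  bl_scale <- estimate_baseline(preprocess_trace(sim$trace))$noise_scale
  sp <- res$subpulses
  sch <- sim$schedule[order(sim$schedule$t_start), ]
  expect_equal(nrow(sp), nrow(sch))
  err <- abs(sp$depth - sch$depth)
  bound <- 5 * bl_scale / sqrt(sp$n_interior)
  expect_gt(mean(err <= bound), 0.98)
})
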