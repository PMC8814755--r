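# Shared fixtures and independent oracles, built in code at test time.

# Brute-force grid-search nonlinear least-squares oracle for the recovery
# time constant: for each candidate tau the amplitude is profiled out in
# closed form, so the search is exhaustive over tau alone and independent of
# the linearized estimator it checks.
tau_grid_oracle <- function(t, level, i_inf,
                            tau_grid = seq(0.001, 2, by = 0.001)) {
  y <- level - i_inf
  sse <- vapply(tau_grid, function(tau) {
    b <- exp(-t / tau)
    a <- sum(y * b) / sum(b * b)
    sum((y - a * b)^2)
  }, numeric(1))
  tau_grid[which.min(sse)]
}

# minimal recovery-subpulse table for direct fit_recovery() calls
recovery_table <- function(t_mid, level, width = 0.02) {
  data.frame(t_start = t_mid - width / 2, t_end = t_mid + width / 2,
             level = level)
}

# one-group simulation helper with known truth, ordered by entry time
simulate_cells <- function(n, noise_sigma = 0, seed = 1, tau_median = 0.15,
                           overlap_fraction = 0, params = NULL, ...) {
  if (is.null(params)) params <- group_params("g", tau_median = tau_median)
  acq <- acquisition_config(noise_sigma = noise_sigma, seed = seed)
  sim <- simulate_trace(list(list(params = params, n = n)), acq,
                        overlap_fraction = overlap_fraction, ...)
  sim$truth <- sim$truth[order(sim$truth$entry_time), ]
  sim
}

# match feature rows to ground-truth rows by event start vs entry time
match_truth <- function(features, events, truth) {
  idx <- vapply(features$event_id, function(eid) {
    t1 <- events$t_start[events$event_id == eid]
    which.min(abs(truth$entry_time - t1))
  }, integer(1))
  truth[idx, , drop = FALSE]
}
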