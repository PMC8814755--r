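#' Acquisition settings for simulated traces
#'
#' @param sample_rate Sampling rate (Hz); instruments of this class digitize at
#'   50 kHz before software filtering and downsampling.
#' @param baseline_current Open-channel baseline current (A).
#' @param noise_sigma Per-sample Gaussian noise standard deviation (A).
#' @param drift_slope Linear baseline drift (A/s).
#' @param seed Integer seed for all randomness in the simulation, or `NULL`
#'   to use the current RNG state.
#' @return An object of class `mnps_acquisition`.
#' @export
acquisition_config <- function(sample_rate = 50000,
                               baseline_current = 10e-6,
                               noise_sigma = 6e-9,
                               drift_slope = 0,
                               seed = NULL) {
  stopifnot(sample_rate > 0, baseline_current > 0, noise_sigma >= 0,
            is.finite(drift_slope))
  structure(list(sample_rate = sample_rate,
                 baseline_current = baseline_current,
                 noise_sigma = noise_sigma,
                 drift_slope = drift_slope,
                 seed = seed),
            class = "mnps_acquisition")
}

#' Relative current blockade of a sphere in a sensing segment
#'
#' Volume-blockade model for resistive-pulse sizing: a sphere of diameter `d`
#' in a segment of length `L` and effective circular diameter
#' `D_e = 2 * sqrt(width * h / pi)` drops the current by the fraction
#' \deqn{\Delta I / I = \frac{d^3}{D_e^2 L} \left[1 - 0.8 (d / D_e)^3\right]^{-1}}
#' (Deblois-Bean relation with the standard shape correction). The function is
#' strictly increasing in `d` on `[0, D_e)` and zero at `d = 0`, so it can be
#' inverted uniquely by [diameter_from_blockade()].
#'
#' @param d Sphere diameter (m); may be a vector. Must satisfy `0 <= d < D_e`.
#' @param segment The sensing segment (a `channel_segment`).
#' @param geometry The channel geometry (supplies the height).
#' @return Blockade fraction(s) \eqn{\Delta I / I}, dimensionless.
#' @seealso [diameter_from_blockade()]
#' @export
#' @examples
#' geom <- channel_geometry()
#' blockade_fraction(11e-6, geom$sizing, geom)
blockade_fraction <- function(d, segment, geometry) {
  de <- effective_diameter(segment, geometry)
  if (any(!is.finite(d)) || any(d < 0))
    stop("`d` must be finite and non-negative", call. = FALSE)
  if (any(d >= de))
    stop(sprintf(paste0("diameter %.3g m >= effective pore diameter %.3g m: ",
                        "unphysical full occlusion"), max(d), de),
         call. = FALSE)
  (d^3 / (de^2 * segment$length)) / (1 - 0.8 * (d / de)^3)
}

#' Group-level distributions for a simulated cohort
#'
#' Describes one biological group as sampling distributions over per-cell
#' ground truth. Diameter, contraction transit time and recovery time constant
#' are lognormal (parameterized by median and log-sd); pre-contraction velocity
#' is normal. Defaults are a generic leukaemia-like cell population; see
#' [apl_cohort_presets()] for a stiff/viscous versus soft/fast pair.
#'
#' @param name Group label.
#' @param d0_median,d0_sdlog Free-diameter lognormal median (m) and log-sd.
#' @param t_cont_median,t_cont_sdlog Contraction transit-time lognormal median
#'   (s) and log-sd.
#' @param tau_median,tau_sdlog Recovery time-constant lognormal median (s) and
#'   log-sd. Sampled values are constrained to the generation band
#'   `[0.005, 2]` s by redrawing.
#' @param u_flow_mean,u_flow_sd Pre-contraction velocity normal mean and sd
#'   (m/s).
#' @param event_rate Cell arrival rate (cells/s); entry times are spaced at
#'   `1 / event_rate`.
#' @param deficit Fraction in `[0, 1)` by which the freshly released
#'   bullet-shaped cell under-blocks relative to a sphere; the under-blockade
#'   decays as `exp(-t / tau)` during recovery.
#' @return An object of class `mnps_group`.
#' @export
group_params <- function(name = "group",
                         d0_median = 11e-6, d0_sdlog = 0.06,
                         t_cont_median = 0.20, t_cont_sdlog = 0.20,
                         tau_median = 0.20, tau_sdlog = 0.35,
                         u_flow_mean = 8e-3, u_flow_sd = 5e-4,
                         event_rate = 0.5,
                         deficit = 0.3) {
  stopifnot(d0_median > 0, d0_sdlog >= 0, t_cont_median > 0, t_cont_sdlog >= 0,
            tau_median > 0, tau_sdlog >= 0, u_flow_mean > 0, u_flow_sd >= 0,
            event_rate > 0, deficit >= 0, deficit < 1)
  structure(list(name = as.character(name),
                 d0_median = d0_median, d0_sdlog = d0_sdlog,
                 t_cont_median = t_cont_median, t_cont_sdlog = t_cont_sdlog,
                 tau_median = tau_median, tau_sdlog = tau_sdlog,
                 u_flow_mean = u_flow_mean, u_flow_sd = u_flow_sd,
                 event_rate = event_rate,
                 deficit = deficit),
            class = "mnps_group")
}

#' Preset group parameters contrasting a stiff/viscous and a soft/fast line
#'
#' Two ready-made [group_params()] sets emulating the contrast between an
#' ATRA-resistant APL line (stiffer: longer contraction transit, hence lower
#' wCDI; more viscous: ~3x longer recovery time) and an ATRA-sensitive line.
#' Median contraction times of 250 ms vs 150 ms keep transit in the
#' 150--200 ms design band of the contraction segment, and recovery medians of
#' 300 ms vs 100 ms sit inside the 20--800 ms range such devices resolve.
#'
#' @return Named list with elements `resistant` and `sensitive`.
#' @export
apl_cohort_presets <- function() {
  list(resistant = group_params("resistant",
                                t_cont_median = 0.25, tau_median = 0.30),
       sensitive = group_params("sensitive",
                                t_cont_median = 0.15, tau_median = 0.10))
}

# Generation band for tau: cohorts are redrawn into this interval.
TAU_GENERATION_BAND <- c(0.005, 2.0)

redraw_until <- function(n, rfun, ok, what, max_tries = 1000L) {
  x <- rfun(n)
  bad <- !ok(x)
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not draw valid values for ", what,
           ": distribution parameters violate cell invariants", call. = FALSE)
    x[bad] <- rfun(sum(bad))
    bad <- !ok(x)
  }
  x
}

#' Sample per-cell ground truth for one group
#'
#' Draws `n` cells from the group distributions, redrawing any draw that
#' violates the physical invariants (diameter above the contraction width and
#' below the channel's free-passage bound; `tau` within the generation band;
#' positive velocity). Entry times are spaced `1 / event_rate` apart starting
#' at `t_first`, so events never overlap; setting `overlap_fraction > 0`
#' deliberately moves that fraction of cells to 0.15 s after their predecessor
#' to create coincident transits for QC tests.
#'
#' @param params A [group_params()] object.
#' @param n Number of cells (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param geometry Channel geometry used for the diameter invariants.
#' @param overlap_fraction Fraction of cells (after the first) given
#'   overlapping entry times.
#' @param t_first Entry time of the first cell (s).
#' @return A data.frame with one row per cell: `cell_id`, `group`,
#'   `entry_time`, `d0`, `u_flow`, `t_cont`, `tau`, `deficit` (SI units).
#' @export
sample_cohort <- function(params, n, seed = NULL,
                          geometry = channel_geometry(),
                          overlap_fraction = 0, t_first = 1.5) {
  stopifnot(inherits(params, "mnps_group"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d_min <- geometry$contraction$width
  d_max <- 0.95 * min(geometry$sizing$width, geometry$h_channel)
  if (params$d0_median <= d_min || params$d0_median >= d_max)
    stop("d0_median must lie between the contraction width and the ",
         "free-passage bound of the channel", call. = FALSE)
  d0 <- redraw_until(n, function(m) stats::rlnorm(m, log(params$d0_median),
                                                  params$d0_sdlog),
                     function(x) x > d_min & x < d_max, "d0")
  t_cont <- redraw_until(n, function(m) stats::rlnorm(m, log(params$t_cont_median),
                                                      params$t_cont_sdlog),
                         function(x) x > 0, "t_cont")
  tau <- redraw_until(n, function(m) stats::rlnorm(m, log(params$tau_median),
                                                   params$tau_sdlog),
                      function(x) x >= TAU_GENERATION_BAND[1] &
                        x <= TAU_GENERATION_BAND[2], "tau")
  u <- redraw_until(n, function(m) stats::rnorm(m, params$u_flow_mean,
                                                params$u_flow_sd),
                    function(x) x > 0, "u_flow")
  entry <- t_first + (seq_len(n) - 1) / params$event_rate
  if (overlap_fraction > 0 && n >= 2) {
    k <- max(1L, round(overlap_fraction * n))
    idx <- sort(sample(2:n, min(k, n - 1L)))
    for (i in idx) entry[i] <- entry[i - 1L] + 0.15
  }
  data.frame(cell_id = seq_len(n), group = params$name, entry_time = entry,
             d0 = d0, u_flow = u, t_cont = t_cont, tau = tau,
             deficit = params$deficit, stringsAsFactors = FALSE)
}

#' Subpulse schedule for one cell transit
#'
#' Forward-models the 12-subpulse anatomy of a cell transiting the channel:
#' a sizing subpulse of duration `sizing_length / u_flow` and depth
#' `I_baseline * blockade_fraction(d0, sizing)`; a contraction subpulse of
#' duration `t_cont` and depth `contraction_amp` times the sizing depth;
#' and one recovery subpulse per recovery segment whose depth follows the
#' Kelvin-Voigt relaxation
#' `depth(t) = depth_sphere * (1 - deficit * exp(-t / tau))`, evaluated at the
#' subpulse midpoint measured from the contraction exit. Node intervals sit at
#' exact baseline between subpulses, each lasting `node_length / u_flow`.
#'
#' @param truth One-row data.frame (or list) with fields `entry_time`, `d0`,
#'   `u_flow`, `t_cont`, `tau`, `deficit` as produced by [sample_cohort()].
#' @param geometry Channel geometry.
#' @param acq Acquisition configuration (supplies the baseline current).
#' @param contraction_amp Contraction depth as a multiple of the sizing depth
#'   (> 1; its exact value is not used quantitatively downstream).
#' @return Data.frame schedule: `kind` (sizing/contraction/recovery), `order`,
#'   `t_start`, `t_end` (absolute s, half-open), `depth` (A).
#' @export
simulate_event <- function(truth, geometry, acq, contraction_amp = 3) {
  truth <- as.list(truth)
  stopifnot(truth$u_flow > 0, truth$t_cont > 0, truth$tau > 0,
            truth$deficit >= 0, truth$deficit < 1, contraction_amp > 1)
  if (truth$d0 <= geometry$contraction$width)
    stop("cell diameter must exceed the contraction width (strain > 0)",
         call. = FALSE)
  u <- truth$u_flow
  ib <- acq$baseline_current
  node_dt <- geometry$node$length / u
  depth_sphere <- ib * blockade_fraction(truth$d0, geometry$sizing, geometry)

  t <- truth$entry_time
  rows <- vector("list", 2L + geometry$n_recovery)
  siz_dt <- geometry$sizing$length / u
  rows[[1]] <- list(kind = "sizing", order = 0L, t_start = t,
                    t_end = t + siz_dt, depth = depth_sphere)
  t <- t + siz_dt + node_dt
  rows[[2]] <- list(kind = "contraction", order = 0L, t_start = t,
                    t_end = t + truth$t_cont,
                    depth = contraction_amp * depth_sphere)
  t <- t + truth$t_cont
  t_exit <- t
  for (k in seq_len(geometry$n_recovery)) {
    rec_dt <- geometry$recovery[[k]]$length / u
    t <- t + node_dt
    t_mid <- t + rec_dt / 2
    depth_k <- depth_sphere *
      (1 - truth$deficit * exp(-(t_mid - t_exit) / truth$tau))
    rows[[2L + k]] <- list(kind = "recovery", order = k, t_start = t,
                           t_end = t + rec_dt, depth = depth_k)
    t <- t + rec_dt
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$kind <- as.character(out$kind)
  out
}

#' Noise level corresponding to a target raw-trace SNR
#'
#' Convenience inverse of the signal model: returns the per-sample Gaussian
#' `noise_sigma` such that the sizing-subpulse depth of a cell of diameter
#' `d_typical` equals `snr` times the noise sd.
#'
#' @param snr Target signal-to-noise ratio (sizing depth / per-sample sd).
#' @param geometry Channel geometry.
#' @param baseline_current Baseline current (A).
#' @param d_typical Reference diameter (m).
#' @return Noise sd (A).
#' @export
noise_for_snr <- function(snr, geometry = channel_geometry(),
                          baseline_current = 10e-6, d_typical = 11e-6) {
  stopifnot(snr > 0)
  baseline_current * blockade_fraction(d_typical, geometry$sizing, geometry) / snr
}

#' Simulate a full current trace for one or more cohorts
#'
#' Samples the cohorts, lays every cell's subpulse schedule onto a shared
#' timeline (cells from all groups interleaved at a uniform spacing of
#' `1 / event_rate`, averaged over groups), and synthesizes the trace as
#' baseline + linear drift + i.i.d. Gaussian noise with each scheduled subpulse
#' subtracted as a current deficit. The returned ground-truth table carries the
#' per-cell parameters plus the true whole-cell deformability index.
#'
#' @param cohorts List of `list(params = group_params(), n = count)` entries,
#'   or a single such entry.
#' @param acq Acquisition configuration; its `seed` (if non-`NULL`) seeds both
#'   cohort sampling and the noise.
#' @param geometry Channel geometry.
#' @param contraction_amp Contraction depth multiple (see [simulate_event()]).
#' @param overlap_fraction Fraction of cells given overlapping entry times.
#' @param t_first Entry time of the first cell (s); the leading quiet stretch
#'   gives the baseline estimator support.
#' @param end_margin Quiet time appended after the last event (s).
#' @param duration Optional total duration (s); must cover all events.
#' @return List with `trace` (an `mnps_trace`), `truth` (ground-truth
#'   data.frame with `wcdi_true` column) and `schedule` (all subpulse
#'   schedules, with `cell_id` and `group`).
#' @export
simulate_trace <- function(cohorts, acq = acquisition_config(),
                           geometry = channel_geometry(),
                           contraction_amp = 3, overlap_fraction = 0,
                           t_first = 1.5, end_margin = 1.0, duration = NULL) {
  if (!is.null(cohorts) && inherits(cohorts$params, "mnps_group"))
    cohorts <- list(cohorts)
  if (!is.null(acq$seed)) set.seed(acq$seed)

  truths <- list()
  for (co in cohorts) {
    if (co$n > 0)
      truths[[length(truths) + 1L]] <-
        sample_cohort(co$params, co$n, seed = NULL, geometry = geometry)
  }
  truth <- if (length(truths)) do.call(rbind, truths) else NULL

  if (!is.null(truth) && nrow(truth) > 0) {
    # interleave groups on a shared timeline with uniform spacing
    rates <- vapply(cohorts, function(co) co$params$event_rate, numeric(1))
    spacing <- 1 / mean(rates)
    ord <- sample.int(nrow(truth))
    truth <- truth[ord, , drop = FALSE]
    truth$cell_id <- seq_len(nrow(truth))
    truth$entry_time <- t_first + (seq_len(nrow(truth)) - 1) * spacing
    if (overlap_fraction > 0 && nrow(truth) >= 2) {
      k <- max(1L, round(overlap_fraction * nrow(truth)))
      idx <- sort(sample(2:nrow(truth), min(k, nrow(truth) - 1L)))
      for (i in idx)
        truth$entry_time[i] <- truth$entry_time[i - 1L] + 0.15
    }
    rownames(truth) <- NULL
    sched <- lapply(seq_len(nrow(truth)), function(i) {
      s <- simulate_event(truth[i, ], geometry, acq, contraction_amp)
      s$cell_id <- truth$cell_id[i]
      s$group <- truth$group[i]
      s
    })
    schedule <- do.call(rbind, sched)
    lc <- geometry$contraction$length
    truth$wcdi_true <- (lc / (truth$u_flow * geometry$h_channel)) *
      (truth$d0 / truth$t_cont)
    t_last <- max(schedule$t_end)
  } else {
    truth <- data.frame(cell_id = integer(), group = character(),
                        entry_time = numeric(), d0 = numeric(),
                        u_flow = numeric(), t_cont = numeric(),
                        tau = numeric(), deficit = numeric(),
                        wcdi_true = numeric(), stringsAsFactors = FALSE)
    schedule <- data.frame(kind = character(), order = integer(),
                           t_start = numeric(), t_end = numeric(),
                           depth = numeric(), cell_id = integer(),
                           group = character(), stringsAsFactors = FALSE)
    t_last <- t_first
  }

  total <- if (is.null(duration)) t_last + end_margin else duration
  if (total < t_last)
    stop("requested `duration` does not cover the scheduled events",
         call. = FALSE)
  n <- ceiling(total * acq$sample_rate)
  tvec <- (seq_len(n) - 1) / acq$sample_rate
  x <- acq$baseline_current + acq$drift_slope * tvec
  if (acq$noise_sigma > 0)
    x <- x + stats::rnorm(n, 0, acq$noise_sigma)
  if (nrow(schedule) > 0) {
    r <- acq$sample_rate
    for (i in seq_len(nrow(schedule))) {
      j1 <- ceiling(schedule$t_start[i] * r + 1 - 1e-9)
      j2 <- ceiling(schedule$t_end[i] * r + 1 - 1e-9) - 1L
      if (j2 > n) stop("event extends beyond the trace window", call. = FALSE)
      if (j2 >= j1) x[j1:j2] <- x[j1:j2] - schedule$depth[i]
    }
  }
  trace <- raw_trace(x, acq$sample_rate, start_time = 0,
                     meta = list(simulated = TRUE, seed = acq$seed,
                                 baseline_current = acq$baseline_current,
                                 noise_sigma = acq$noise_sigma,
                                 drift_slope = acq$drift_slope))
  list(trace = trace, truth = truth, schedule = schedule)
}
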