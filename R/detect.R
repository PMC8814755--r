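# Pulse detection and subpulse segmentation on conditioned traces.
# Index convention: half-open [start, end), 1-based; time = start_time +
# (index - 1) / sample_rate.

detection_threshold <- function(baseline, k, abs_threshold = NULL) {
  thr <- k * baseline$noise_scale
  if (thr <= 0) {
    thr <- if (!is.null(abs_threshold) && abs_threshold > 0) abs_threshold
           else 1e-3 * stats::median(baseline$baseline)
  }
  thr
}

# maximal runs of TRUE as (start, end) half-open index pairs
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' Detect cell-transit pulses in a conditioned trace
#'
#' Finds maximal runs where the current deficit (baseline minus trace) exceeds
#' `k` robust noise units, merges runs separated by sub-threshold gaps shorter
#' than the node dwell horizon (nodes return the current to near baseline
#' *within* a transit), and discards runs shorter than a minimum duration so
#' isolated noise excursions are never reported as events. If the trace is
#' noiseless (`noise_scale == 0`) an absolute threshold is used instead,
#' defaulting to 0.1% of the median baseline.
#'
#' @param trace Conditioned `mnps_trace`.
#' @param baseline An `mnps_baseline` for the same trace.
#' @param k Threshold in robust-noise units (default 5).
#' @param merge_gap Maximum sub-threshold gap merged into one event (s);
#'   should exceed the node length divided by the slowest plausible velocity.
#' @param min_duration Minimum event duration (s).
#' @param abs_threshold Absolute deficit threshold (A) used when
#'   `noise_scale == 0`.
#' @return Data.frame of events: `event_id`, `start`, `end` (half-open sample
#'   indices), `t_start`, `t_end` (s); sorted and non-overlapping.
#' @export
detect_pulses <- function(trace, baseline, k = 5, merge_gap = 0.025,
                          min_duration = 0.05, abs_threshold = NULL) {
  stopifnot(inherits(trace, "mnps_trace"), inherits(baseline, "mnps_baseline"))
  n <- length(trace$samples)
  if (length(baseline$baseline) != n)
    stop("baseline length does not match trace length", call. = FALSE)
  deficit <- baseline$baseline - trace$samples
  thr <- detection_threshold(baseline, k, abs_threshold)
  above <- deficit > thr
  if (!any(above))
    return(data.frame(event_id = integer(), start = integer(),
                      end = integer(), t_start = numeric(),
                      t_end = numeric()))
  runs <- logical_runs(above)
  gap_samples <- merge_gap * trace$sample_rate
  if (nrow(runs) > 1L) {
    merged <- list(runs[1L, ])
    for (i in 2L:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[i, "start"] - last["end"] < gap_samples) {
        last["end"] <- runs[i, "end"]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  dur <- (runs[, "end"] - runs[, "start"]) / trace$sample_rate
  runs <- runs[dur >= min_duration, , drop = FALSE]
  if (nrow(runs) == 0L)
    return(data.frame(event_id = integer(), start = integer(),
                      end = integer(), t_start = numeric(),
                      t_end = numeric()))
  tt <- function(i) trace$start_time + (i - 1) / trace$sample_rate
  data.frame(event_id = seq_len(nrow(runs)),
             start = as.integer(runs[, "start"]),
             end = as.integer(runs[, "end"]),
             t_start = tt(runs[, "start"]),
             t_end = tt(runs[, "end"]))
}

# refine a plateau edge to sub-sample precision by linear interpolation of the
# half-depth crossing; def/times span the whole trace, [lo, hi] bound the
# search to this plateau's neighbourhood.
refine_left_edge <- function(def, times, a, lo, target) {
  i <- a
  while (i > lo && def[i - 1L] >= target) i <- i - 1L
  while (i < length(def) && def[i] < target) i <- i + 1L
  j <- i - 1L
  if (j < lo || j < 1L || !(def[i] > def[j]))
    return(times[min(max(i, 1L), length(times))])
  tt <- times[j] + (target - def[j]) / (def[i] - def[j]) * (times[i] - times[j])
  min(max(tt, times[j]), times[i])
}

refine_right_edge <- function(def, times, b, hi, target) {
  i <- b
  while (i < hi && def[i + 1L] >= target) i <- i + 1L
  while (i > 1L && def[i] < target) i <- i - 1L
  j <- i + 1L
  if (j > hi || j > length(def) || !(def[i] > def[j]))
    return(times[min(max(i, 1L), length(times))])
  tt <- times[i] + (def[i] - target) / (def[i] - def[j]) * (times[j] - times[i])
  min(max(tt, times[i]), times[j])
}

#' Decompose a detected pulse into its subpulses
#'
#' Splits an event at its near-baseline node intervals into depth plateaus.
#' Each plateau's depth is the mean current deficit over its interior (a
#' fraction of samples trimmed at each edge to exclude the filter-smeared
#' transitions), and its boundaries are refined to sub-sample precision by
#' linearly interpolating the half-depth crossings. The first plateau is
#' labelled `sizing`, the deepest `contraction`, and every plateau after the
#' deepest `recovery` 1..n in time order; any additional plateau before the
#' contraction is labelled `extra` (a symptom of coincident cells, flagged by
#' [qc_event()]).
#'
#' @param event One row of the [detect_pulses()] table.
#' @param trace Conditioned `mnps_trace`.
#' @param baseline Matching `mnps_baseline`.
#' @param geometry Channel geometry (supplies the expected recovery count).
#' @param k,abs_threshold Threshold controls, as in [detect_pulses()].
#' @param edge_trim Fraction of plateau samples trimmed at each edge before
#'   averaging (at least 2 samples).
#' @return Data.frame of subpulses: `event_id`, `kind`, `order`, `t_start`,
#'   `t_end` (refined, s), `depth` (A), `level` (A, in-segment current),
#'   `n_interior` (samples averaged).
#' @export
segment_subpulses <- function(event, trace, baseline, geometry, k = 5,
                              abs_threshold = NULL, edge_trim = 0.1) {
  stopifnot(inherits(trace, "mnps_trace"), inherits(baseline, "mnps_baseline"))
  a <- event$start
  b <- event$end - 1L  # inclusive last sample
  n_tr <- length(trace$samples)
  # operate on a local window around the event to avoid full-trace copies
  lo0 <- max(1L, a - 50L)
  hi0 <- min(n_tr, b + 50L)
  win <- lo0:hi0
  deficit <- baseline$baseline[win] - trace$samples[win]
  times <- trace$start_time + (win - 1) / trace$sample_rate
  a <- a - lo0 + 1L
  b <- b - lo0 + 1L
  thr <- detection_threshold(baseline, k, abs_threshold)
  seg <- deficit[a:b] > thr
  runs <- logical_runs(seg)
  if (nrow(runs) == 0L)
    return(empty_subpulses())
  runs[, "start"] <- runs[, "start"] + a - 1L
  runs[, "end"] <- runs[, "end"] + a - 1L  # half-open in local indices

  m <- nrow(runs)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    p1 <- runs[i, "start"]
    p2 <- runs[i, "end"] - 1L
    len <- p2 - p1 + 1L
    trim <- min(max(2L, floor(edge_trim * len)), (len - 1L) %/% 2L)
    i1 <- p1 + trim
    i2 <- p2 - trim
    if (i2 < i1) { i1 <- p1; i2 <- p2 }
    depth <- mean(deficit[i1:i2])
    spread <- if (i2 > i1) stats::sd(deficit[i1:i2]) else 0
    level <- mean(trace$samples[(i1:i2) + lo0 - 1L])
    lo <- if (i == 1L) max(a - 1L, 1L) else runs[i - 1L, "end"]
    hi <- if (i == m) min(b + 1L, length(deficit)) else runs[i + 1L, "start"] - 1L
    t1 <- refine_left_edge(deficit, times, p1, lo, depth / 2)
    t2 <- refine_right_edge(deficit, times, p2, hi, depth / 2)
    out[[i]] <- data.frame(event_id = event$event_id, kind = NA_character_,
                           order = 0L, t_start = t1, t_end = t2,
                           depth = depth, level = level,
                           spread = spread, n_interior = i2 - i1 + 1L)
  }
  sp <- do.call(rbind, out)
  i_deep <- which.max(sp$depth)
  sp$kind[1L] <- "sizing"
  sp$kind[i_deep] <- "contraction"
  if (i_deep < m) {
    rec <- (i_deep + 1L):m
    sp$kind[rec] <- "recovery"
    sp$order[rec] <- seq_along(rec)
  }
  sp$kind[is.na(sp$kind)] <- "extra"
  sp
}

empty_subpulses <- function() {
  data.frame(event_id = integer(), kind = character(), order = integer(),
             t_start = numeric(), t_end = numeric(), depth = numeric(),
             level = numeric(), spread = numeric(), n_interior = integer(),
             stringsAsFactors = FALSE)
}

#' Quality-control verdict for a segmented event
#'
#' An event is accepted (`ok`) only if its segmentation shows the full
#' subpulse anatomy: exactly one sizing, one contraction and `n_recovery`
#' recovery subpulses; the contraction is the unique deepest plateau; recovery
#' depths are non-decreasing within a 3-sigma tolerance (the Kelvin-Voigt
#' relaxation only increases the blockade); and the sizing depth corresponds
#' to a physically attainable sphere in the sizing segment. Failure modes map
#' to diagnostic codes: `truncated` (event touches a trace end),
#' `coincidence` (extra plateaus or a non-unique deepest plateau, the
#' signature of merged cell transits), `missing_subpulses` (too few plateaus),
#' and `low_snr` (non-monotone recovery or unphysical sizing depth).
#'
#' @param event One row of the [detect_pulses()] table.
#' @param subpulses Output of [segment_subpulses()] for this event.
#' @param geometry Channel geometry.
#' @param noise_scale Robust noise sd (A) of the conditioned trace.
#' @param n_samples Trace length in samples (used for the truncation check).
#' @return A list with `code` (one of `ok`, `missing_subpulses`,
#'   `coincidence`, `truncated`, `low_snr`) and `detail` (character).
#' @export
qc_event <- function(event, subpulses, geometry, noise_scale = 0,
                     n_samples = Inf) {
  flag <- function(code, detail = "") list(code = code, detail = detail)
  if (event$start <= 1L || event$end > n_samples)
    return(flag("truncated", "event touches the trace boundary"))
  m <- nrow(subpulses)
  expected <- 2L + geometry$n_recovery
  # a merged (coincident) transit shows non-flat plateaus: runs that mix the
  # depth levels of two superposed cells
  mixed <- any(subpulses$spread >
                 3 * noise_scale + 0.02 * max(subpulses$depth))
  if (m > expected || (m != expected && mixed))
    return(flag("coincidence",
                sprintf("%d plateaus where %d expected", m, expected)))
  if (m < expected)
    return(flag("missing_subpulses",
                sprintf("%d plateaus where %d expected", m, expected)))
  if (any(subpulses$kind == "extra"))
    return(flag("coincidence", "plateau between sizing and contraction"))
  dep <- sort(subpulses$depth, decreasing = TRUE)
  if (m >= 2L && dep[2] > 0.75 * dep[1])
    return(flag("coincidence", "contraction plateau not uniquely deepest"))
  if (mixed)
    return(flag("coincidence", "non-flat plateau interior"))
  rec <- subpulses[subpulses$kind == "recovery", , drop = FALSE]
  if (nrow(rec) >= 2L) {
    for (i in seq_len(nrow(rec) - 1L)) {
      tol <- 3 * noise_scale *
        sqrt(1 / rec$n_interior[i] + 1 / rec$n_interior[i + 1L]) +
        1e-9 * rec$depth[i]
      if (rec$depth[i + 1L] < rec$depth[i] - tol)
        return(flag("low_snr",
                    sprintf("recovery depth decreases at subpulse %d", i + 1L)))
    }
  }
  siz <- subpulses[subpulses$kind == "sizing", , drop = FALSE]
  frac <- siz$depth / (siz$depth + siz$level)
  de <- effective_diameter(geometry$sizing, geometry)
  max_frac <- blockade_fraction(0.999 * de, geometry$sizing, geometry)
  if (!is.finite(frac) || frac <= 0 || frac >= max_frac)
    return(flag("low_snr", "sizing depth outside the physical range"))
  flag("ok")
}
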