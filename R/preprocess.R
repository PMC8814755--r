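#' Centered moving-average low-pass filter
#'
#' Replaces each sample by the mean of a centered window of `window` samples;
#' at the trace edges the window shrinks so the output has the same length as
#' the input. For even `window` the window extends one sample further to the
#' right than to the left.
#'
#' @param trace An `mnps_trace`.
#' @param window Window length in samples (integer >= 1).
#' @return A filtered `mnps_trace` at the same sampling rate.
#' @export
moving_average <- function(trace, window = 20L) {
  stopifnot(inherits(trace, "mnps_trace"))
  window <- as.integer(window)
  n <- length(trace$samples)
  if (is.na(window) || window < 1L)
    stop("`window` must be an integer >= 1", call. = FALSE)
  if (window > n)
    stop("`window` exceeds the trace length", call. = FALSE)
  hl <- (window - 1L) %/% 2L
  hr <- window %/% 2L
  cs <- cumsum(trace$samples)
  out <- numeric(n)
  i1 <- hl + 1L
  i2 <- n - hr
  if (i2 >= i1) {
    # full windows: sum x[(i-hl)..(i+hr)] = cs[i+hr] - cs[i-hl-1]
    out[i1] <- cs[i1 + hr] / window
    if (i2 > i1) {
      idx <- (i1 + 1L):i2
      out[idx] <- (cs[idx + hr] - cs[idx - hl - 1L]) / window
    }
  }
  for (i in seq_len(min(hl, n)))  # shrinking left edge
    out[i] <- cs[min(n, i + hr)] / (min(n, i + hr))
  if (hr >= 1L && n > 1L) {
    for (i in (max(i2, 0L) + 1L):n) {  # shrinking right edge
      lo <- max(1L, i - hl)
      out[i] <- (cs[n] - if (lo > 1L) cs[lo - 1L] else 0) / (n - lo + 1L)
    }
  }
  raw_trace(out, trace$sample_rate, trace$start_time,
            c(trace$meta, list(filter_window = window)))
}

#' Downsample a trace by block averaging
#'
#' Consecutive blocks of `factor` samples are replaced by their mean (an
#' anti-aliasing decimation consistent with the moving-average filter that
#' precedes it). The new sampling rate is `sample_rate / factor` and the new
#' start time is shifted to the center of the first block so downstream
#' boundary estimates stay aligned with the raw timeline. A trailing partial
#' block is dropped.
#'
#' @param trace An `mnps_trace`.
#' @param factor Integer decimation factor >= 1 (20 takes 50 kHz to 2.5 kHz).
#' @return A downsampled `mnps_trace`.
#' @export
downsample <- function(trace, factor = 20L) {
  stopifnot(inherits(trace, "mnps_trace"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(trace)
  n <- length(trace$samples)
  m <- n %/% factor
  if (m < 1L) stop("trace shorter than one block", call. = FALSE)
  x <- matrix(trace$samples[seq_len(m * factor)], nrow = factor)
  out <- colMeans(x)
  raw_trace(out, trace$sample_rate / factor,
            trace$start_time + (factor - 1) / (2 * trace$sample_rate),
            c(trace$meta, list(downsample_factor = factor)))
}

# The shrinking median windows runmed uses near the trace ends are easily
# dominated by an event that runs into an end; replace those regions with a
# linear extrapolation of the nearest fully supported medians (exact for
# constant and linearly drifting baselines).
extrapolate_ends <- function(med, k) {
  m <- length(med)
  h <- k %/% 2L
  if (h < 2L || m <= 3L * h) return(med)
  p1 <- h + 1L
  p2 <- min(m, p1 + h)
  sl <- (med[p2] - med[p1]) / (p2 - p1)
  med[1:h] <- med[p1] + sl * ((1:h) - p1)
  q1 <- m - h
  q0 <- max(1L, q1 - h)
  sr <- (med[q1] - med[q0]) / (q1 - q0)
  med[(q1 + 1L):m] <- med[q1] + sr * (((q1 + 1L):m) - q1)
  med
}

#' Robust rolling-median baseline and noise-scale estimate
#'
#' Estimates the open-channel baseline with a centered rolling median whose
#' window is much longer than any single cell transit, making it robust to the
#' asymmetric negative excursions cells produce. The noise scale is
#' `1.4826 * MAD` of the residual (trace minus baseline) computed on
#' non-excursion samples: samples whose residual exceeds 4 robust sd in either
#' direction are excluded before the final MAD.
#'
#' @param trace An `mnps_trace` (typically filtered and downsampled).
#' @param window Rolling-median window in samples (odd; default the odd number
#'   nearest to 2 s of samples). Must be shorter than the trace.
#' @param stride Evaluate the rolling median every `stride`-th sample and
#'   interpolate linearly in between (the baseline varies on much slower
#'   scales than the sampling); default targets a ~100 Hz evaluation grid.
#'   Use `stride = 1` for an exact per-sample rolling median.
#' @param exclude Optional event table (with `start`/`end` half-open sample
#'   indices, e.g. from [detect_pulses()]). Samples inside these spans are
#'   bridged by linear interpolation before the median is taken, removing the
#'   small downward bias events otherwise impose on a noisy baseline; used by
#'   the pipeline's second baseline pass.
#' @return A list of class `mnps_baseline`: `baseline` (numeric vector, same
#'   length as the trace) and `noise_scale` (A).
#' @export
estimate_baseline <- function(trace, window = NULL, stride = NULL,
                              exclude = NULL) {
  stopifnot(inherits(trace, "mnps_trace"))
  n <- length(trace$samples)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    keep <- rep(TRUE, n)
    for (i in seq_len(nrow(exclude))) {
      s <- max(1L, exclude$start[i] - 2L)
      e <- min(n, exclude$end[i] + 1L)
      keep[s:e] <- FALSE
    }
    if (any(keep) && any(!keep)) {
      # bridge each event span linearly between locally averaged anchors so
      # anchor noise does not propagate into the in-event baseline
      filled <- trace$samples
      anchor <- function(lo, hi) {
        idx <- seq.int(max(1L, lo), min(n, hi))
        idx <- idx[keep[idx]]
        if (length(idx)) stats::median(trace$samples[idx]) else NA_real_
      }
      for (i in seq_len(nrow(exclude))) {
        s <- max(1L, exclude$start[i] - 2L)
        e <- min(n, exclude$end[i] + 1L)
        la <- anchor(s - 250L, s - 1L)
        ra <- anchor(e + 1L, e + 250L)
        if (is.na(la)) la <- ra
        if (is.na(ra)) ra <- la
        if (is.na(la)) next
        filled[s:e] <- seq(la, ra, length.out = e - s + 1L)
      }
      est <- estimate_baseline(raw_trace(filled, trace$sample_rate,
                                         trace$start_time),
                               window = window, stride = stride)
      res <- trace$samples - est$baseline
      s0 <- stats::mad(res[keep])
      if (s0 > 0) {
        ok <- keep & res > -4 * s0 & res < 4 * s0
        est$noise_scale <- if (any(ok)) stats::mad(res[ok]) else s0
      } else est$noise_scale <- 0
      if (est$noise_scale < 1e-9 * stats::median(abs(est$baseline)))
        est$noise_scale <- 0
      return(est)
    }
  }
  if (is.null(window)) window <- round(2 * trace$sample_rate)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window >= n) window <- if (n %% 2L == 0L) n - 1L else n
  if (window < 3L) window <- 3L
  if (n <= window && n < 3L)
    stop("trace too short for baseline estimation", call. = FALSE)
  if (is.null(stride)) stride <- max(1L, floor(trace$sample_rate / 100))
  stride <- as.integer(stride)
  if (stride > 1L && window %/% stride >= 5L && n %/% stride >= 7L) {
    idx <- unique(c(seq.int(1L, n, by = stride), n))
    kc <- window %/% stride
    if (kc %% 2L == 0L) kc <- kc + 1L
    coarse <- extrapolate_ends(stats::runmed(trace$samples[idx], kc,
                                             endrule = "med"), kc)
    base <- stats::approx(idx, coarse, xout = seq_len(n), rule = 2)$y
  } else {
    base <- extrapolate_ends(stats::runmed(trace$samples, window,
                                           endrule = "med"), window)
  }
  res <- trace$samples - base
  s0 <- stats::mad(res)
  if (s0 > 0) {
    keep <- res > -4 * s0 & res < 4 * s0
    if (!any(keep))
      stop("no baseline support: every sample is an excursion", call. = FALSE)
    ns <- stats::mad(res[keep])
  } else {
    ns <- 0
  }
  # snap floating-point dust to zero so noiseless traces take the absolute
  # detection threshold rather than a meaninglessly small k-sigma one
  if (ns < 1e-9 * stats::median(abs(base))) ns <- 0
  structure(list(baseline = as.numeric(base), noise_scale = ns),
            class = "mnps_baseline")
}

#' Standard conditioning chain: filter then downsample
#'
#' @param trace Raw `mnps_trace` (e.g. 50 kHz).
#' @param filter_window Moving-average window in raw samples.
#' @param downsample_factor Block-mean decimation factor.
#' @return Conditioned `mnps_trace` (e.g. 2.5 kHz).
#' @export
preprocess_trace <- function(trace, filter_window = 20L,
                             downsample_factor = 20L) {
  downsample(moving_average(trace, filter_window), downsample_factor)
}
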