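#' Uniformly sampled current trace
#'
#' Container for a single-channel current-versus-time series. Sample `i`
#' (1-based) is taken at `start_time + (i - 1) / sample_rate`.
#'
#' @param samples Numeric vector of current samples (A); must be finite.
#' @param sample_rate Sampling rate (Hz), positive scalar.
#' @param start_time Time of the first sample (s).
#' @param meta Named list of acquisition provenance (free-form).
#' @return An object of class `mnps_trace`.
#' @export
raw_trace <- function(samples, sample_rate, start_time = 0, meta = list()) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be a finite numeric vector", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number (Hz)", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 start_time = as.numeric(start_time),
                 meta = meta),
            class = "mnps_trace")
}

#' Sample times of a trace
#'
#' @param trace An `mnps_trace`.
#' @return Numeric vector of times (s), one per sample.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1) / trace$sample_rate
}

#' @export
print.mnps_trace <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("mnps_trace: %d samples at %g Hz (%.3f s), start %.4f s\n",
              n, x$sample_rate, n / x$sample_rate, x$start_time))
  invisible(x)
}

#' @export
length.mnps_trace <- function(x) length(x$samples)
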