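# Mechanical phenotype extraction: size, velocity, strain, wCDI and the
# Kelvin-Voigt recovery time constant.

#' Invert the volume-blockade relation to recover a sphere diameter
#'
#' Solves `blockade_fraction(d) = depth_fraction` for `d` by bracketed
#' root-finding on `(0, D_e)`; the blockade relation is strictly monotone so
#' the root is unique. Convergence tolerance is ~1e-12 relative.
#'
#' @param depth_fraction Relative current drop \eqn{\Delta I / I} (scalar or
#'   vector), strictly inside the attainable range of the segment.
#' @param segment The sensing segment the blockade was measured in.
#' @param geometry Channel geometry.
#' @return Diameter(s) (m).
#' @seealso [blockade_fraction()]
#' @export
diameter_from_blockade <- function(depth_fraction, segment, geometry) {
  de <- effective_diameter(segment, geometry)
  d_hi <- de * (1 - 1e-9)
  f_max <- blockade_fraction(d_hi, segment, geometry)
  one <- function(df) {
    if (!is.finite(df) || df <= 0 || df >= f_max)
      stop(sprintf("depth fraction %.3g outside the attainable range (0, %.3g)",
                   df, f_max), call. = FALSE)
    stats::uniroot(function(d) blockade_fraction(d, segment, geometry) - df,
                   interval = c(0, d_hi), tol = de * 1e-13,
                   maxiter = 200L)$root
  }
  vapply(depth_fraction, one, numeric(1))
}

#' Pre-contraction cell velocity from the sizing subpulse
#'
#' @param sizing One-row data.frame (or list) with `t_start` and `t_end` of
#'   the sizing subpulse (s).
#' @param geometry Channel geometry.
#' @return Velocity `u_flow = sizing_length / duration` (m/s).
#' @export
compute_velocity <- function(sizing, geometry) {
  dur <- sizing$t_end - sizing$t_start
  if (!is.finite(dur) || dur <= 0)
    stop("sizing subpulse duration must be positive", call. = FALSE)
  geometry$sizing$length / dur
}

#' Compressive strain applied in the contraction segment
#'
#' `strain = (d0 - w_c) / d0`, where the deformed diameter is taken as the
#' contraction width `w_c` (the channel height exceeds typical cell diameters,
#' so deformation is width-limited).
#'
#' @param d0 Free cell diameter (m).
#' @param geometry Channel geometry.
#' @return Dimensionless strain in (0, 1).
#' @export
compute_strain <- function(d0, geometry) {
  if (any(!is.finite(d0)) || any(d0 <= 0))
    stop("`d0` must be positive", call. = FALSE)
  wc <- geometry$contraction$width
  if (any(d0 <= wc))
    stop("cell diameter does not exceed the contraction width: ",
         "no deformation (should have been size-gated)", call. = FALSE)
  (d0 - wc) / d0
}

#' Whole-cell deformability index
#'
#' \deqn{wCDI = \frac{l_c}{u_{flow} h_{channel}} \cdot \frac{d_0}{t_{cont}}}
#' with `l_c` the contraction-segment length. Dimensionless and invariant
#' under a global change of units; higher values indicate softer cells
#' (inversely related to cortical tension), and the `d0 / t_cont` ratio
#' removes the trivial cell-size effect on transit time.
#'
#' @param d0 Free diameter (m).
#' @param u_flow Pre-contraction velocity (m/s).
#' @param t_cont Contraction transit time (s).
#' @param geometry Channel geometry.
#' @return Dimensionless wCDI (vectorized over its numeric arguments).
#' @export
compute_wcdi <- function(d0, u_flow, t_cont, geometry) {
  if (any(d0 <= 0) || any(u_flow <= 0) || any(t_cont <= 0))
    stop("all wCDI inputs must be positive", call. = FALSE)
  (geometry$contraction$length / (u_flow * geometry$h_channel)) *
    (d0 / t_cont)
}

#' Recovery time constant by linearized Kelvin-Voigt creep fit
#'
#' A cell released from the contraction behaves as a Kelvin-Voigt solid under
#' a step change in stress: its strain, and hence the measured in-segment
#' current, relaxes exponentially, `I(t) = I_inf + A exp(-t / tau)`. With the
#' fully recovered current `I_inf` fixed (from the sizing subpulse; sizing and
#' recovery segments share width and height), the model is linearized as
#' `ln(I(t) - I_inf) = ln(A) - t / tau` and fitted by ordinary least squares
#' over the recovery-subpulse levels, with `t` the subpulse midpoint measured
#' from the contraction exit. The time constant is `tau = -1 / slope`; its 95%
#' confidence interval follows from the slope's standard error by the delta
#' method with a t-distribution on `n - 2` degrees of freedom.
#'
#' Points with `level <= I_inf` (log undefined: the cell appears fully
#' recovered there) are excluded. Fits with fewer than `min_points` usable
#' points or a non-negative slope are returned with `valid = FALSE` rather
#' than raising an error.
#'
#' @param recovery Data.frame of recovery subpulses with `t_start`, `t_end`
#'   and `level` columns (as from [segment_subpulses()]).
#' @param i_inf Fully recovered in-segment current (A).
#' @param t0 Contraction exit time (s); time origin of the relaxation.
#' @param min_points Minimum usable points for a valid fit (>= 4 so the CI has
#'   at least 2 degrees of freedom).
#' @param tau_band Sanity band (s); estimates outside it keep `valid = TRUE`
#'   but are flagged by `in_band = FALSE` for review.
#' @return A list of class `mnps_recovery_fit`: `tau`, `tau_ci95` (length-2),
#'   `i_inf`, `i0_amp`, `n_points`, `r_squared`, `valid`, `in_band`.
#' @export
fit_recovery <- function(recovery, i_inf, t0, min_points = 4L,
                         tau_band = c(0.005, 2.0)) {
  invalid <- function(n) {
    structure(list(tau = NA_real_, tau_ci95 = c(NA_real_, NA_real_),
                   i_inf = i_inf, i0_amp = NA_real_, n_points = n,
                   r_squared = NA_real_, valid = FALSE, in_band = NA),
              class = "mnps_recovery_fit")
  }
  if (is.null(recovery) || nrow(recovery) == 0L) return(invalid(0L))
  t_k <- (recovery$t_start + recovery$t_end) / 2 - t0
  lev <- recovery$level
  usable <- is.finite(lev) & lev > i_inf
  if (sum(usable) < min_points) return(invalid(sum(usable)))
  t_k <- t_k[usable]
  y <- log(lev[usable] - i_inf)
  n <- length(y)
  fit <- stats::lm.fit(cbind(1, t_k), y)
  a <- unname(fit$coefficients[1])
  b <- unname(fit$coefficients[2])
  if (!is.finite(b) || b >= 0) return(invalid(n))
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  sxx <- sum((t_k - mean(t_k))^2)
  se_b <- sqrt(rss / (n - 2L) / sxx)
  tau <- -1 / b
  se_tau <- se_b / b^2
  tcrit <- stats::qt(0.975, df = n - 2L)
  ci <- c(tau - tcrit * se_tau, tau + tcrit * se_tau)
  structure(list(tau = tau, tau_ci95 = ci, i_inf = i_inf,
                 i0_amp = exp(unname(a)), n_points = n, r_squared = r2,
                 valid = TRUE,
                 in_band = tau >= tau_band[1] && tau <= tau_band[2]),
            class = "mnps_recovery_fit")
}

#' @export
print.mnps_recovery_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Kelvin-Voigt recovery fit: tau = %.1f ms (95%% CI %.1f-%.1f), r2 = %.3f, n = %d\n",
                x$tau * 1e3, x$tau_ci95[1] * 1e3, x$tau_ci95[2] * 1e3,
                x$r_squared, x$n_points))
  else
    cat(sprintf("Kelvin-Voigt recovery fit: invalid (%d usable points)\n",
                x$n_points))
  invisible(x)
}

#' Assemble the full mechanical phenotype of one accepted event
#'
#' Converts a QC-accepted event's subpulses into the per-cell phenotype:
#' free diameter from the sizing depth (blockade inversion), velocity from the
#' sizing duration, contraction transit time from the contraction duration,
#' strain and wCDI, and the recovery time constant via [fit_recovery()] with
#' `I_inf` set to the sizing-subpulse level (a fully recovered cell blocks the
#' recovery segments exactly as it blocked the sizing segment). A recovery fit
#' that fails stays `valid = FALSE` without aborting the event.
#'
#' @param subpulses Subpulse table of one accepted event.
#' @param geometry Channel geometry.
#' @param min_points,tau_band Passed to [fit_recovery()].
#' @return One-row data.frame: `event_id`, `d0`, `u_flow`, `t_cont`, `strain`,
#'   `wcdi`, `tau`, `tau_ci_low`, `tau_ci_high`, `i0_amp`, `r_squared`,
#'   `n_recovery_points`, `fit_valid`, `tau_in_band` (SI units).
#' @export
phenotype_event <- function(subpulses, geometry, min_points = 4L,
                            tau_band = c(0.005, 2.0)) {
  siz <- subpulses[subpulses$kind == "sizing", , drop = FALSE]
  con <- subpulses[subpulses$kind == "contraction", , drop = FALSE]
  rec <- subpulses[subpulses$kind == "recovery", , drop = FALSE]
  if (nrow(siz) != 1L || nrow(con) != 1L)
    stop("phenotype_event() requires exactly one sizing and one contraction ",
         "subpulse (QC-accepted event)", call. = FALSE)
  frac <- siz$depth / (siz$depth + siz$level)
  d0 <- diameter_from_blockade(frac, geometry$sizing, geometry)
  u <- compute_velocity(siz, geometry)
  t_cont <- con$t_end - con$t_start
  strain <- compute_strain(d0, geometry)
  wcdi <- compute_wcdi(d0, u, t_cont, geometry)
  fit <- fit_recovery(rec, i_inf = siz$level, t0 = con$t_end,
                      min_points = min_points, tau_band = tau_band)
  data.frame(event_id = subpulses$event_id[1], d0 = d0, u_flow = u,
             t_cont = t_cont, strain = strain, wcdi = wcdi,
             tau = fit$tau, tau_ci_low = fit$tau_ci95[1],
             tau_ci_high = fit$tau_ci95[2], i0_amp = fit$i0_amp,
             r_squared = fit$r_squared, n_recovery_points = fit$n_points,
             fit_valid = fit$valid, tau_in_band = fit$in_band)
}
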