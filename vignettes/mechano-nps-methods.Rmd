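---
title: "Mechano-NPS signal analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-NPS signal analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnps)
```

## The measurement

Mechano-node-pore sensing (mechano-NPS) measures the DC current across a
segmented microfluidic channel. A cell transiting the channel partially
blocks the current, and because the channel alternates between narrow
sensing segments and wide nodes, one transit produces a single pulse
composed of discrete subpulses:

1. a **sizing subpulse** in a 13 x 800 um segment, whose depth encodes the
   cell's free diameter and whose duration gives its velocity;
2. a much deeper **contraction subpulse** in the 7 x 2000 um constriction,
   whose duration `t_cont` reflects stiffness (a softer cell transits
   faster);
3. ten **recovery subpulses** in 13 x 290 um segments, whose depths grow
   back toward the sizing depth as the deformed (bullet-shaped) cell relaxes
   to a sphere.

The channel height is 12.9 um and the nodes are 85 um wide, so a cell in a
node barely blocks current; nodes delimit the subpulses. Signals are
digitized at 50 kHz, low-pass filtered with a moving average, and
downsampled to 2.5 kHz before analysis.

`mnps` implements both directions of this measurement: a forward simulator
producing traces with known per-cell ground truth, and the analysis chain
that turns a trace into per-cell mechanical phenotypes and cohort
statistics.

## Phenotype definitions

With `d0` the free diameter, `u_flow` the pre-contraction velocity, `w_c`
the contraction width, `l_c` its length and `h` the channel height:

* strain: `epsilon = (d0 - w_c) / d0`. We take the deformed diameter to be
  the contraction **width** because the channel height (12.9 um) exceeds
  typical cell diameters, so compression is width-limited. At the default
  operating point (`d0 ~ 11 um`, `w_c = 7 um`) this gives the
  `epsilon ~ 0.35` such devices are designed for.
* whole-cell deformability index:
  `wCDI = (l_c / (u_flow * h)) * (d0 / t_cont)`. It is dimensionless,
  higher for softer cells (it is inversely related to cortical tension), and
  the `d0 / t_cont` ratio removes the trivial tendency of large cells to
  transit slowly.
* recovery time constant `tau`: see below.

## Sizing model

The literature the device descends from relates subpulse depth to particle
volume without fixing a formula, so the package adopts the standard
Deblois–Bean volume-blockade relation with the usual shape correction,

\[
\Delta I / I = \frac{d^3}{D_e^2 L}\left[1 - 0.8\,(d/D_e)^3\right]^{-1},
\qquad D_e = 2\sqrt{w h / \pi},
\]

where `D_e` maps the rectangular cross-section (width `w`, height `h`) to
the equal-area circle. The relation is strictly increasing in `d`, so
`diameter_from_blockade()` inverts it by bracketed root-finding to ~1e-12
relative precision. Simulator and inverter share the same relation, which
makes sizing self-consistent by construction; the package makes no claim
about the absolute calibration of this formula on a physical device.

## Recovery model and the linearized Kelvin–Voigt fit

A cell released from the constriction is modelled as a homogeneous
Kelvin–Voigt solid under a step change in compressive stress: its strain
relaxes exponentially with time constant `tau`, and through the
volume-blockade transform so does the measured in-segment current,

\[
I(t) = I_\infty + A\,e^{-t/\tau}, \qquad A > 0 .
\]

`fit_recovery()` estimates `tau` exactly as the field does: fix `I_inf`,
linearize by `ln(I(t) - I_inf) = ln A - t/\tau`, and run ordinary least
squares over the recovery-subpulse levels. The slope's standard error gives
a 95% confidence interval for `tau` by the delta method with a
t-distribution on `n - 2` degrees of freedom.

Choices the source material leaves open, fixed here once:

* **`I_inf` per cell** is taken from the sizing-subpulse level. Sizing and
  recovery segments share width and height, and a fully recovered cell
  blocks them identically, so this avoids fitting a third parameter.
* **Time coordinate**: `t_k` is the recovery-subpulse midpoint minus the
  contraction exit time. Midpoints minimize the bias of averaging the depth
  over a segment.
* **Exclusions**: points with `level <= I_inf` have no defined logarithm
  (the cell appears fully recovered there) and are dropped; a valid fit
  needs at least 4 points so the CI retains 2 degrees of freedom. A
  non-negative slope yields `valid = FALSE` rather than an error.
* **Sanity band**: estimates outside [5 ms, 2 s] stay valid but are flagged
  (`tau_in_band = FALSE`); devices of this geometry resolve roughly
  20–800 ms, and the band adds margin on both sides.

On noiseless exponentials the linearized fit is exact to floating-point
rounding; when the decay amplitude is orders of magnitude below `I_inf`
(short `tau`, late sampling), cancellation amplifies double rounding to
~1e-8–1e-5 relative, which is still far below any physical noise. Tests
cross-check the estimator against an independent grid-search nonlinear
least-squares oracle and against `nls()`.

## The synthetic-data generator

The simulator is first-class, tested code: it is the only way to exercise
the detector and estimators against known truth without instrument data.
Per cell it draws a diameter, velocity, contraction transit time, recovery
time constant and entry time, builds the 12-subpulse schedule, and
superposes the scheduled current deficits on
`baseline + drift * t + N(0, sigma^2)` noise.

Defaults, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| baseline current | 10 uA | sub-3 V DC operating point of such devices |
| sampling | 50 kHz, filter window 20, downsample 20x | matches the instrument chain |
| d0 | lognormal, median 11 um, sdlog 0.06 | leukaemia-like cell line, strain ~0.36 |
| u_flow | N(8 mm/s, 0.5) | gives ~100 ms sizing dwell and ~0.4 s recovery sampling |
| t_cont | lognormal, median 250 ms (stiff) / 150 ms (soft), sdlog 0.2 | the constriction is sized for 150–200 ms dwell; the pair programs a 0.6x wCDI contrast |
| tau | lognormal, median 300 ms (stiff) / 100 ms (soft), sdlog 0.35 | inside the 20–800 ms observable band; 3x contrast |
| deficit | 0.3 | the source material states only that the freshly released bullet under-blocks relative to the sphere; 0.3 is a free choice, decaying as `exp(-t/tau)` |
| contraction depth | 3x sizing depth | only its *duration* is used quantitatively; the depth merely has to dominate |
| event rate | 0.5 cells/s | keeps transits under ~40% duty inside the 2 s baseline window |
| noise | 6 nA (~SNR 20 for an 11 um cell) | routine good acquisition; `noise_for_snr()` maps SNR to sigma |

What the generator does **not** emulate: 1/f and line-frequency noise,
bullet-shape electrostatics (the under-blockade is a single multiplicative
deficit), velocity changes inside the constriction, cell–cell interactions
beyond scheduled coincidences, and pressure-to-velocity physics (velocities
are sampled, not derived from the inlet pressure). Passing tests therefore
demonstrate correctness of the *analysis chain* under the stated noise
model, not instrument-level fidelity.

## Detection and segmentation

The conditioned trace is thresholded on the deficit `baseline - I(t)` at
`k = 5` robust noise units (`1.4826 * MAD` of non-excursion residuals);
sub-threshold gaps shorter than 25 ms (a node dwell at the slowest
plausible velocity) are merged, and runs shorter than 50 ms are discarded,
which makes isolated noise spikes incapable of forming an event. On a
noiseless trace the threshold falls back to an absolute 0.1% of baseline.

The **baseline** is a centered rolling median (window 2 s), evaluated on a
~100 Hz coarse grid and interpolated — the baseline varies much more slowly
than the sampling. Two refinements matter in practice: the shrinking median
windows `runmed()` uses at the trace ends are replaced by a linear
extrapolation of the nearest fully supported medians (otherwise an event
touching a trace end swallows the local baseline), and after a first
detection pass the baseline is re-estimated with detected events bridged by
linearly interpolating between locally averaged anchors. Without the second
pass, events occupying ~35% of a window bias the noisy median low by
~0.8 sigma, which propagates into every depth estimate.

Within an event, above-threshold runs separated by node intervals are the
subpulses. Depths are trimmed interior means (10% of samples, minimum 2,
per edge — the moving-average filter smears each transition over about one
downsampled sample), and boundaries are refined to sub-sample precision by
linearly interpolating the half-depth crossings; this is what lets `t_cont`
round-trip to well under one downsampled sample period (0.4 ms).

QC accepts an event only with the full 12-subpulse anatomy, a uniquely
deepest contraction plateau, recovery depths non-decreasing within 3 sigma,
and a physically attainable sizing depth. Merged coincident transits are
recognized by supernumerary plateaus, a non-unique deepest plateau, or
non-flat plateau interiors (the interior standard deviation of a genuine
plateau is the noise scale; a merged run mixes levels), and rejected as
`coincidence` — matching the device's intent that coincident cells be
discarded, not deconvolved.

## Cohort statistics

`compare_two()` is the pooled-variance (Student) two-sample t test —
pooled, not Welch, because that is the procedure the mechanophenotyping
literature reports; Welch is available behind `var_equal = FALSE`.
`tukey_all_pairs()` implements Tukey–Kramer simultaneous comparisons on the
studentized range (`ptukey`), the unequal-`n` variant, since real cohort
sizes are never balanced; with two groups it delegates to the t test.
Bonferroni correction divides alpha when multiple planned t tests are
declared (`m_tests`). `posthoc_power()` computes exact noncentral-t power
at the observed Cohen's d and the minimum effect reaching power 0.80 by
root-finding; tests cross-check it against `power.t.test(strict = TRUE)`.
`notched_summary()` uses linear-interpolation quartiles and the McGill
notch `median +/- 1.57 IQR / sqrt(n)` as the 95% CI of the median.

These implementations are deliberately independent of `t.test()`,
`TukeyHSD()` and `power.t.test()`, which serve as cross-checking oracles in
the test suite.

## Numerical and scale choices

* All internal units are SI (m, s, A); output tables use the human-scale
  units named in their column headers (um, mm/s, ms).
* Downsampled sample times are anchored at raw-block centers so boundary
  estimates remain on the raw timeline.
* Seeded runs are byte-reproducible; every output table carries an MD5 hash
  of the validated configuration, so any parameter change is visible in the
  outputs.
* Problem sizes used by the test suite and the acceptance script — 50-cell
  noiseless round trips, 1000-event detection runs, 10-minute noise-only
  traces, 1000-rep estimator Monte-Carlos, 10 000-rep null simulations, and
  20 seeded 400-cell cohort-contrast runs — were chosen to pin each
  property with comfortable Monte-Carlo margin at desk scale.

## Known limitations

* The sizing relation is a geometric idealization; absolute diameters on a
  real device would need bead calibration.
* `wCDI` is not converted to cortical tension; that calibration lives in
  the prior literature on the method and is out of scope.
* The recovery fit assumes the cell re-blocks the shared-width segments
  exactly as in the sizing segment once recovered; systematic sizing/
  recovery segment mismatches would bias `I_inf` and hence `tau`.
* Truly coincident cells are rejected, not deconvolved.
* Group comparisons assume per-cell independence; replicate/device effects
  present in real experiments are not modelled.
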