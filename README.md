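# mnps — mechano-node-pore sensing simulation and analysis

Single-cell mechanophenotyping for resistive-pulse instruments. In
mechano-node-pore sensing (mechano-NPS), a cell transiting a segmented
microfluidic channel produces one current pulse built from subpulses: a
sizing subpulse (free diameter `d0` and velocity `u_flow`), a deep
contraction subpulse in a 7 um constriction (transit time `t_cont`,
reflecting stiffness), and ten recovery subpulses whose depths relax back
toward the sizing depth as the deformed cell recovers its spherical shape.

From one trace, `mnps` extracts per cell:

- **strain** `epsilon = (d0 - w_c) / d0` (~0.35 at the default geometry),
- **whole-cell deformability index**
  `wCDI = (l_c / (u_flow * h_channel)) * (d0 / t_cont)` —
  dimensionless, higher = softer, size-corrected,
- **recovery time constant** `tau` from the Kelvin–Voigt creep model
  `I(t) = I_inf + A exp(-t / tau)`, fitted by linear least squares on
  `ln(I - I_inf)` with a delta-method 95% CI (`tau` spans roughly
  20–800 ms on this geometry),

and at cohort level: pooled-variance Student t tests, Tukey–Kramer
all-pairs range tests, Bonferroni correction, notched-median box summaries,
and post hoc power analysis (exact noncentral t, plus the minimum effect
size reaching power 0.80).

Because raw instrument data are rarely at hand, the package includes a
forward simulator (`simulate_trace()`) that generates 50 kHz traces with
known per-cell ground truth — baseline drift, Gaussian noise, and
group-level distributions that emulate a stiff/viscous versus soft/fast
cell-line contrast — so the whole chain is testable end to end.

## Worked example

Simulate two 40-cell cohorts (a stiff/viscous "resistant" group and a
soft/fast "sensitive" group), run the full pipeline, and compare groups:

```r
library(mnps)
cfg <- default_config()
cfg$cohorts[[1]]$n <- 40L   # resistant-like
cfg$cohorts[[2]]$n <- 40L   # sensitive-like
res <- run_pipeline(cfg, out_dir = "demo_out")

aggregate(cbind(wcdi, tau_ms = tau * 1e3) ~ group, res$features, median)
#>       group      wcdi   tau_ms
#> 1 resistant 0.8572213 295.6003
#> 2 sensitive 1.4394586 106.4551

res$comparisons[, c("group_a", "group_b", "metric", "statistic",
                    "p_value", "significant", "effect_size", "power")]
#>     group_a   group_b metric statistic      p_value significant effect_size power
#> 1 sensitive resistant   wcdi  10.11324 7.647108e-16        TRUE    2.261389     1
#> 2 sensitive resistant    tau -12.75609 8.909277e-21        TRUE   -2.852348     1

notched_summary(res$features$wcdi[res$features$group == "resistant"])
#> median 0.8572 [notch 0.8159, 0.8986], IQR 0.7846-0.9513, n = 40
```

The sensitive group's median wCDI is ~1.7x the resistant group's (softer)
and its recovery time ~3x shorter (less viscous) — exactly the contrast the
generator programmed, recovered through trace synthesis, detection,
segmentation, QC and fitting. `run_pipeline()` also writes `events.tsv`,
`subpulses.tsv`, `features.tsv`, `comparisons.tsv`, `power_report.tsv` and
a run log into `out_dir`, each stamped with the MD5 hash of the exact
configuration.

A thin command-line front end wrapping the same functions lives at
`inst/cli/mnps.R` (`simulate`, `detect`, `phenotype`, `compare`, `run`
subcommands).

## Documentation

The methods vignette (`vignettes/mechano-nps-methods.Rmd`) documents the
models, the estimators, every tunable parameter with units and defaults,
what the synthetic-data generator does and does not emulate, and the
package's numerical design choices.
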