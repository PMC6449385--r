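# dbstheta

Analysis pipeline for within-subject deep brain stimulation (DBS) ON/OFF
experiments built around a conflict task with emotional distractors —
from trial-level behavior to induced prefrontal theta power,
cluster-permutation statistics, and a subject-level clinical biomarker.

## The science

Stimulation of the ventral internal capsule / ventral striatum is used
for severe depression and OCD, and one proposed mechanism is enhanced
*cognitive control*. This package implements the statistical chain that
tests that idea in a within-subject ON/OFF crossover:

1. **Behavior.** Conflict (interference) trials slow responses by
   roughly a couple hundred milliseconds; if DBS sharpens control, it
   should *speed* responses by tens of milliseconds without hurting
   accuracy. Because reaction times are positive and right-skewed,
   effects are estimated with a gamma GLM with an identity link —
   coefficients stay in milliseconds — with per-subject intercepts and
   forward stepwise AIC model selection.
2. **Induced theta.** Cognitive control is associated with theta-band
   (4–8 Hz) bursts over prefrontal cortex that are *not* phase-locked to
   the stimulus. The pipeline subtracts each condition's evoked response
   from every trial, decomposes what remains with Morlet wavelets
   (25 log-spaced frequencies, 2–50 Hz, 3 cycles), normalizes to a
   pre-stimulus baseline in dB, and averages into bands.
3. **Inference.** Single-trial band power is regressed on the design at
   every time point; contiguous suprathreshold runs (≥50 ms) of the
   t statistic form clusters scored by their mass, and significance comes
   from within-subject permutation of the predictor with
   Benjamini–Hochberg correction across regions.
4. **Controls.** Resting-state recordings are compared ON vs OFF with a
   multitaper spectrum and a Mann–Whitney test — theta that changes only
   during task engagement is not a passive stimulation artifact.
5. **Biomarker.** Each subject's integrated ON−OFF theta change is
   correlated with clinical improvement (Fisher-Z test, Huber robust
   line, bootstrap intervals) and evaluated as a responder classifier by
   ROC/AUC.

The core behavioral model, in field notation:

RT_ij ~ Gamma(shape ν, mean μ_ij),
μ_ij = α_j + β_interference·x_int + β_dbs·x_dbs + …

with subject intercepts α_j and effects in milliseconds.

A synthetic-data module (`sim_config()`, `simulate_trials()`,
`simulate_rts()`, `simulate_epochs()`, `simulate_resting()`,
`simulate_cohort_biomarker()`) emulates the entire design — gamma RTs
with additive effects, 1/f background plus evoked waveforms plus
random-phase theta bursts, exchangeable resting states, and a latent
theta–clinic linkage — so every stage is testable end-to-end with no
external data. See `vignette("methods")` for models, assumptions, and
numerical choices.

## Worked example

Simulate a compact demo cohort and run the full pipeline:

```r
library(dbstheta)

cfg <- demo_config(seed = 1)
report <- run_all(cfg, n_perm = 200, n_boot = 200, skip = "erp")
print(report)
```

```
<dbstheta_report>
  behavior: 830 trials after QC; terms: trial_number, interference, dbs 
    trial_number         -0.4 ms  (t =   -1.1, p = 0.293)
    interference        262.0 ms  (t =   17.5, p = 2.95e-58)
    dbs                 -41.6 ms  (t =   -3.0, p = 0.00297)
  clusters: 15 found, 6 significant after FDR
  100.0% of significant interference theta mass in the decision period
  resting theta ON vs OFF: U = 1400, p = 0.036
  biomarker (VLPFC, 0.53-0.87 s): r = 0.80 (p = 0.060), AUC = 0.78 [0.20, 1.00]
```

The printed block reads: the stepwise gamma GLM keeps the true main
effects, with the 6-subject demo cohort's estimates (262 ms, −41.6 ms)
scattered around the generating +224 ms interference and −34 ms DBS
values; the theta cluster stage finds significant interference and DBS
clusters concentrated in the decision period; and the biomarker stage
reports the theta–clinic correlation and responder AUC for the
simulated cohort. The resting control generates *no* ON/OFF difference,
so its p-value is uniform — at this seed it lands at 0.036, the kind of
nominal false positive expected in one run out of twenty.

Individual stages are plain functions, e.g.:

```r
trials <- simulate_rts(simulate_trials(cfg), cfg)
qc     <- qc_filter(trials)
fit    <- fit_gamma_glm(qc$trials, c("interference", "dbs"))
ep     <- simulate_epochs(qc$trials, cfg)
tfr    <- db_normalize(morlet_tfr(subtract_erp(ep)))
bp     <- band_average(tfr)
```

A command-line wrapper lives at `inst/cli/dbstheta-pipeline.R`
(subcommands `simulate`, `behavior`, `spectral`, `cluster`, `biomarker`,
`run-all`; YAML config overrides; logs to stderr and `<out>/run.log`).

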