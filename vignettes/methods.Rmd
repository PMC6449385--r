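---
title: "Methods: conflict-task EEG and the DBS theta biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conflict-task EEG and the DBS theta biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dbstheta)
```

This vignette documents the statistical model behind each stage of the
`dbstheta` pipeline, the assumptions those models make, the numerical
choices in the implementation, and the scope and limits of the synthetic
data generator used to validate everything. Code chunks are illustrative
and not evaluated at build time.

## 1. Experimental design being modelled

The pipeline targets a within-subject deep brain stimulation (DBS) ON/OFF
crossover experiment built around a conflict (interference) task with
emotional distractor images. Each subject completes one block per DBS
state. A block interleaves control and interference trials (72 + 72 by
default) under a sequencing constraint: no attribute — interference
status, distractor valence category, or response finger — may repeat on
three consecutive trials. Scalp/source activity is epoched around image
onset (stimulus-locked) or the button press (response-locked), and
resting recordings bracket the task for a stimulation control analysis.

All module defaults are study-level constants of this design (trial
counts, sampling rate `1450/3` Hz, frequency grid, baseline window,
artifact threshold, cluster rules), not free parameters; they are chosen
once and never adapted to any particular dataset.

## 2. Behavioral model

### 2.1 Gamma GLM with identity link

Reaction times are positive, right-skewed, and shifted additively by
experimental factors, so RT is modelled as gamma-distributed with an
identity link:

$$\mathrm{RT}_{ij} \sim \mathrm{Gamma}\!\left(\nu,\;
  \mu_{ij}/\nu\right), \qquad
  \mu_{ij} = \alpha_{j} + \beta_\mathrm{int}\,x^\mathrm{int}_{ij}
  + \beta_\mathrm{dbs}\,x^\mathrm{dbs}_{ij} + \cdots$$

where $j$ indexes subjects and $\alpha_j$ is a per-subject intercept.
The identity link keeps coefficients in milliseconds: an interference
effect of $+224$ ms means interference trials are on average 224 ms
slower at fixed DBS state, and a DBS effect of $-34$ ms means
stimulation speeds responses by 34 ms.

Assumptions: a common shape parameter across trials (variance
proportional to $\mu^2$, i.e. constant coefficient of variation),
additivity of effects on the mean in natural units, and conditional
independence of trials given subject and design.

### 2.2 Fixed vs random subject intercepts

`fit_gamma_glm()` defaults to per-subject *fixed* intercepts via
`stats::glm` (`engine = "glm"`); `engine = "glmer"` fits the
corresponding Gaussian random intercept with `lme4`. The fixed-intercept
route is the default because gamma models with an identity link are
numerically delicate (the linear predictor must stay positive), and
`glm` with `mustart = y` converges robustly where `glmer` occasionally
stalls. With balanced within-subject designs, both estimators of the
condition effects coincide in expectation, and the test suite checks
they agree materially on synthetic cohorts. This is a package design
decision, stated here so users know what the default is and why.

Predictors are internally rescaled to $[0, 1]$ before fitting (a linear
reparameterization that improves conditioning) and coefficients mapped
back to natural units, so reported estimates are per-unit in the
original scales (per-condition contrast in ms, per-rating-point in ms,
and so on).

### 2.3 Quality control

`qc_filter()` removes, in order: trials without a response, error
trials, the trial immediately following an error (post-error slowing
contaminates the RT distribution), and per-subject outliers. The outlier
rule fits a gamma density to each subject's remaining RTs (in seconds,
via `MASS::fitdistr`) and removes trials whose density falls below
`likelihood_cutoff = 0.005`; this trims both the extreme fast guesses
and the extreme slow lapses under one likelihood criterion instead of
fixed cutoffs. Subjects with fewer than `min_trials = 10` usable trials
skip the density step with a warning rather than fitting a meaningless
density.

### 2.4 Model selection and error rates

`stepwise_aic()` performs forward selection over
`interference, dbs, valence, arousal, interference:dbs` on top of the
nuisance term `trial_number`, respecting marginality (an interaction is
only eligible once both parents are included) and breaking AIC ties
deterministically by candidate order. Accuracy is compared between DBS
states with a conditional binomial test (`binomial_error_test()`): given
the total error count, errors are binomially distributed over states
under the null of equal rates, which avoids asymptotic approximations at
the low error rates typical of this task (~1.7%).

## 3. Spectral pipeline

### 3.1 Induced power via ERP subtraction

Phase-locked (evoked) activity is removed before time-frequency
analysis: `subtract_erp()` computes the mean waveform per
subject × DBS state × interference condition (`compute_erp()`) and
subtracts it from each trial of that cell. What remains is the induced,
non-phase-locked signal — the quantity of interest for oscillatory
burst analyses. The identity tested in the suite: for a purely evoked
synthetic cohort, post-subtraction induced band power sits at the
baseline level.

### 3.2 Morlet decomposition

`morlet_tfr()` convolves each trial with complex Morlet wavelets on a
grid of 25 log-spaced frequencies from 2 to 50 Hz with 3 cycles per
wavelet (`morlet_freq_grid()`), a resolution/variance trade-off suited
to low-frequency burst detection. Numerical choices:

- wavelets are unit-energy normalized, so power scales are comparable
  across frequencies;
- convolution runs through FFTs with `nextn()` padding;
- epochs are reflect-padded to suppress edge ringing; additionally each
  frequency carries a validity mask excluding $\pm(\text{cycles}/2)/f$
  seconds at the epoch edges, where the wavelet support leaves the data;
- bands average power over theta 4–8 Hz, alpha 8–15 Hz, beta 15–30 Hz
  (`band_average()`).

### 3.3 dB baseline normalization

`db_normalize()` converts power to dB relative to the mean baseline
power in $(-0.5, -0.1)$ s, computed per subject × DBS state × frequency
so that between-subject and between-state scale differences cannot
masquerade as effects. The window ends at $-0.1$ s to keep wavelet
leakage from post-stimulus activity out of the baseline.

One subtlety: the *trial-mean power* in the baseline window is exactly
the reference, so the dB of the trial-averaged power is 0 there by
construction. The mean of per-trial dB values is *negative* (Jensen's
inequality: the log of a skewed power distribution has mean below the
log of the mean), and the package's invariants are therefore stated on
trial-averaged power, not averaged log power.

### 3.4 Time-domain ERP branch

`erp_pipeline()` provides the evoked counterpart: 4th-order Butterworth
low-pass at 15 Hz applied forward-backward (`signal::filtfilt`, zero
phase), decimation by 3, and window cropping; `erp_bootstrap_ci()`
resamples trials within subject, averages to subject means and then to
the grand average, and takes percentile intervals, respecting the
two-level structure of the data.

### 3.5 Source bundles

When activity is extracted from a cortical patch, vertex time courses
have arbitrary sign (dipole orientation flips across a sulcus) and a
plain average cancels. `pca_flip()` takes the first principal component
of the vertex × time matrix (via SVD), fixes its sign so the
largest-magnitude vertex loading is positive, and rescales so the mean
squared amplitude equals the mean vertex power — a sign-robust,
power-preserving patch summary.

## 4. Cluster-mass permutation statistics

Single-trial band power is analysed by sliding ordinary least squares
(`sliding_ols()`): at each time point, power across trials is regressed
on the standardized design (interference, DBS, valence, arousal, trial
number). Per-subject mean power is removed first (`subject_demean()`),
so the inference concerns within-subject modulation. The per-time t
statistics of a chosen predictor are thresholded at the two-sided
$t_{0.975}$ quantile; contiguous same-sign suprathreshold runs of at
least 50 ms form clusters, scored by their summed t ("mass").

Significance comes from a within-subject permutation scheme: the
predictor of interest is permuted across trials *within each subject*
(other columns fixed), the maximum absolute cluster mass is recorded per
permutation, and the p-value is $(1 + \#\{\text{null} \ge
\text{obs}\})/(n_\text{perm}+1)$, which cannot be zero and is exact
under exchangeability. Within-subject permutation respects the blocked
structure; subjects contributing fewer than two trials are excluded with
a warning. Across multiple regions/bands, cluster p-values are corrected
by Benjamini–Hochberg FDR (`fdr_stepdown()`). `cluster_mass_fraction()`
reports the percentage of (significant) cluster mass inside a time
window, e.g. the decision period from 400 ms to the mean RT.

Numerical choices: the OLS core uses a single QR/`chol2inv` factorization
of the design (shared across time points), rank deficiency is reported
with the offending column named, and the permutation loop scores null
masses with a cumulative-sum run-length scan rather than re-forming
cluster tables, which makes the 200–1000-permutation loops affordable on
one CPU.

## 5. Resting-state control

`resting_theta_compare()` guards against theta changes being a direct
stimulation artifact: 60 one-second epochs per DBS state are scored for
theta power with a multitaper spectrum (`multitaper_psd()`, DPSS tapers
with time-bandwidth `nw = 4`, `k = 7` tapers, spectrum reported to
30 Hz) and compared with a Mann–Whitney U test. DPSS tapers are computed
from the tridiagonal eigenproblem (numerically stable for long epochs)
and cached. The U test assumes independent epochs; one-second epochs of
band power satisfy this only if the underlying theta envelope
decorrelates within about a second, which the synthetic generator's
envelope is designed to do (see §7).

## 6. Biomarker statistics

For each subject, the theta time course difference (DBS ON − OFF, in
dB) is integrated over the analysis window by the trapezoidal rule
(`integrate_theta_difference()`), giving one number per subject: the
integrated theta change. Linkage to clinical change uses:

- Pearson correlation with a Fisher-Z p-value
  (`pearson_fisher()`, `fisher_z_pvalue()`): $z = \operatorname{atanh}(r)
  \sqrt{n-3}$ against the standard normal. Worked check:
  $r = 0.76,\ n = 8 \Rightarrow p = 0.03$.
- A robust line (`robust_line()`): Huber M-estimation
  (`MASS::rlm`, tuning constant 1.345) so a single outlying subject
  cannot set the slope in an $n \approx 8{-}14$ cohort.
- Percentile bootstrap intervals (`bootstrap_ci()`) with *shared*
  resample indices (`bootstrap_draws()`) so intervals for different
  statistics are computed on identical resamples.
- Responder classification: clinical responders are defined by ≥50%
  improvement on the depression scale; `roc_auc()` computes AUC by the
  midrank (Mann–Whitney) identity, handling ties exactly, plus the full
  ROC curve.

## 7. Synthetic data generator: scope and limits

The generator (`sim_config()`, `simulate_trials()`, `simulate_rts()`,
`simulate_epochs()`, `simulate_resting()`,
`simulate_cohort_biomarker()`, `simulate_null_power()`) emulates the
full experimental design so every stage is testable without external
data. Its defaults *are* the modelled design's study-level conditions.
Key parameters (units,
default, rationale):

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 14 | cohort size |
| `n_control`, `n_interference` | 72, 72 | trials per block |
| `sampling_rate` | 1450/3 Hz | decimated acquisition rate |
| `rt_intercept` | 600 ms | baseline mean RT |
| `effect_interference` | +224 ms | interference slowing |
| `effect_dbs` | −34 ms | stimulation speed-up (ON − OFF) |
| `subject_sd` | 80 ms | between-subject intercept SD |
| `rt_shape` | 10 | gamma shape (CV ≈ 0.32) |
| `error_rate`, `miss_rate` | 1.7%, 0.5% | behavioral lapses |
| `theta_freq` | 6 Hz | burst carrier |
| `burst_onset`, `burst_duration` | 0.5 s, 0.3 s | burst timing |
| `theta_burst_gain_interference` | 3 dB | interference burst gain |
| `theta_burst_gain_dbs` | 2 dB | DBS burst gain (ON − OFF) |
| `theta_gain_subject_sd` | 1 dB | subject variability of the gain |
| `erp_amplitude` | 5 | evoked waveform scale |
| `noise_sd`, `noise_exponent` | 10, 1 | 1/f background |
| `biomarker_r` | 0.76 | theta–clinical linkage |

Mechanics worth knowing:

- **Trial sequences** are generated balanced and then repaired to satisfy
  the no-three-in-a-row constraint by a deterministic greedy swap search
  with plateau moves; `split_images()` divides a rated image set into
  two matched halves (rank-adjacent pairing refined by first-improvement
  local search on the matching objective).
- **Epochs** are 1/f background noise (FFT spectral shaping) plus a
  condition-locked evoked waveform plus Hanning-windowed theta bursts
  with *random phase per trial*, so bursts cancel in the ERP and survive
  ERP subtraction — exactly the induced/evoked dissociation the pipeline
  measures. Response-locked epochs re-center on the per-trial button
  press.
- **Resting traces** carry a theta component whose amplitude envelope is
  smoothed white noise decorrelating within ~1 s. This is a deliberate
  generator contract: ON and OFF resting states are exchangeable and
  1-s epochs are effectively independent, so the Mann–Whitney p-value is
  uniform under the null. A slowly wandering (1/f²) envelope would
  violate the epoch-independence assumption of the U test and is out of
  scope.
- **Null band power** (`simulate_null_power()`) produces temporally
  autocorrelated power with subject offsets and a balanced
  within-subject DBS assignment that has *no* effect — the input for
  family-wise-error calibration of the cluster stage (8 subjects × 100
  trials by default).

**Limits.** The generator does not model volume conduction, channel
covariance, eye/muscle artifacts (amplitude rejection is exercised by
injected spikes in tests), learning or fatigue trends beyond a linear
trial-number nuisance, or serial RT dependence beyond post-error
removal. Clinical scores follow a stylized linear-latent model. These
are deliberate: the generator validates the *statistics*, not the
biophysics.

## 8. Recovery experiments and their tuning

Two calibration experiments in the test suite run at package-chosen
problem sizes, selected once from pilot parameter-recovery runs and then
frozen:

- **Stepwise selection**: 100 synthetic cohorts of 8 subjects with full
  72 + 72 blocks; the suite requires the true main effects
  (interference, dbs) selected and the absent interaction excluded in at
  least 80% of cohorts.
- **Burst detection at tuned SNR**: the detection experiment defines its
  own signal-to-noise point, chosen by pilot recovery: DBS burst gain
  4 dB, subject gain SD 0.5 dB, 8 subjects × (18 + 18) trials,
  sampling rate 1450/12 Hz, theta-band wavelets only. At these settings
  the injected burst must be recovered as a significant positive cluster
  overlapping ≥80% of the true burst window in ≥80% of 50 cohorts. The
  study-level default gain stays at 2 dB; the tuned point characterizes
  where the machinery's power curve is, not what a study would see.
- **Family-wise error**: 500 null datasets from `simulate_null_power()`
  must give a false-cluster rate within [0.03, 0.07] at nominal 0.05.

## 9. Open question: burst shape

The generator uses Hanning-windowed constant-frequency bursts. Real
frontal theta events are heterogeneous — variable cycle counts,
frequency drift within a burst, and possible harmonic structure from
non-sinusoidal waveforms. Whether cluster detection rates transfer
quantitatively from Hanning bursts to, say, asymmetric sawtooth-like
bursts is untested here; the validity mask and band-averaging make the
pipeline insensitive to fine waveform shape in principle, but the
detection calibration in §8 is specific to the generator's burst model.
A future revision could parameterize burst shape and re-run the
recovery experiment across shapes.

## 10. Known limitations

- Gamma/identity GLMs can fail when a candidate model predicts
  non-positive means; the fitter reports this as an explicit error
  rather than silently switching links.
- The `glmer` engine can emit convergence warnings on small cohorts; the
  fit object records `converged = FALSE` and the default engine avoids
  the issue.
- Cluster inference controls error at the cluster level; cluster extent
  is descriptive, not an inferential statement about every contained
  time point.
- The epoch container is a plain-text matrix plus JSON sidecar
  (`write_epoch_array()`), chosen for dependency-free portability; it is
  not a binary hierarchical store and large arrays will be bulky on
  disk.
- `roc_auc()` intervals via the bootstrap can be degenerate for tiny
  cohorts with few responders; the pipeline reports `NA` bounds in that
  case rather than fabricating width.
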