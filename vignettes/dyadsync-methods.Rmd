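---
title: "Estimating conversation valence and arousal from dyadic autonomic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating conversation valence and arousal from dyadic autonomic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two people in conversation continuously influence each other's autonomic
nervous systems. `dyadsync` implements a complete pipeline for asking how much
of a conversation's perceived *valence* (unpleasant to pleasant) and *arousal*
(calm to energetic) — rated 1–9 on the Self-Assessment-Manikin scale after
each 2-minute conversation interval — can be recovered from four autonomic
channels recorded from both partners: the electrocardiogram (ECG),
electrodermal activity (EDA, in microsiemens), respiration, and skin
temperature.

The pipeline has five stages: (1) a synthetic dyad generator that produces
coupled two-person recordings with known ground truth; (2) signal
preparation — segmentation into intervals, R-peak, breath-peak and
skin-conductance-response (SCR) detection, and instantaneous-rate
computation; (3) feature extraction — 20 per-participant features and 9
inter-partner synchrony measures on 4 signal pairs (36 synchrony features)
per interval; (4) feature selection and regression; (5) crossvalidated
evaluation against a median baseline with paired statistical comparisons.

## The synthetic generator

Real dyadic recordings are not distributable with a package, so `dyadsync`
ships a generator whose output has the statistical structure the analysis
assumes. Each dyad gets latent valence and arousal trajectories over the ten
conversation intervals (stationary AR(1), unit marginal variance,
autocorrelation 0.6). Each participant's state is the dyad state plus an
AR(1) divergence term (`divergence_sd`, default 0.3), so partners report
similar but not identical impressions. Within an interval, a band-limited
driver process is mixed between partners with weight `coupling`
(default 0.6): participant drivers are `coupling * shared + (1 - coupling) *
individual`, re-standardized, which makes every synchrony-relevant statistic
monotone in `coupling`.

Channels are generated from the latent state:

* **ECG** — narrow unit pulses placed by integrating an instantaneous heart
  rate `70 + 10*arousal + 4*valence + 5*driver` beats/min. The waveform is
  deliberately schematic: downstream code consumes R-peak times, not
  morphology.
* **EDA** — a tonic level (`5 + 0.3*arousal + 0.25*valence` µS) with slow
  drift plus SCR bumps from an inhomogeneous Poisson process whose rate
  (default base 4/min) increases with arousal and the driver. The SCR kernel
  rises in 1.2 s and decays with a 3 s time constant, so generated events
  fall well inside the 5 s trough-to-peak detection criterion.
* **Respiration** — a sinusoid with instantaneous rate
  `15 + 3*arousal + valence + 2*driver` breaths/min.
* **Temperature** — a slow drift around `33 + 0.2*arousal + 0.15*valence`
  degrees.

Self-ratings are the participant's latent state plus Gaussian noise
(`label_noise_sd`, default 0.5), affinely mapped
(`center + scale * latent`, defaults 6.9/1.5 for valence and 6.1/1.9 for
arousal — mildly pleasant, mildly energetic conversations with wider arousal
spread), rounded half-up and clipped to 1–9. Observer ratings map the
dyad-mean latent state the same way. Participant characteristics (age,
gender, four trait scores) are drawn from truncated normal distributions
inside the instruments' declared ranges.

The default cohort is 41 dyads — 82 participants — with 12 intervals each
(2 baselines + 10 conversation intervals). The default sampling rate is
100 Hz rather than a hardware-grade 600 Hz: no extracted feature depends on
spectral content above ~50 Hz, and the rate is configurable. Identical
configuration and seed give bit-identical cohorts; each dyad has its own
deterministic substream.

**What the generator does not emulate:** realistic ECG morphology, motion
artifacts, sensor drift or detachment, respiratory sinus arrhythmia
structure in heart-rate variability, and any nonlinear coupling between the
latent affect and physiology. Tests that pass on this generator therefore
demonstrate that the pipeline recovers the structure it targets when that
structure is present — not that real recordings contain it.

## Signal preparation

Recordings are segmented by explicit interval boundaries; out-of-interval
samples (questionnaire breaks) are discarded. Channel filters are zero-phase
Butterworth with documented defaults (ECG high-pass 0.5 Hz, EDA low-pass
1 Hz, respiration band-pass 0.05–1 Hz, temperature low-pass 0.1 Hz); they
denoise, and their exact coefficients are immaterial to the contracts
downstream.

R-peaks are local maxima above an adaptive threshold (midway between median
and maximum), picked in amplitude order under a 0.25 s refractory period
(≈240 beats/min ceiling); breath peaks use the same scheme with a 1 s
refractory. Rather than manual inspection, implausible inter-beat intervals
(< 0.3 s or > 2 s) raise an automatic quality flag. SCRs follow a
trough-to-peak rule: a local maximum paired with the most recent preceding
local minimum counts when the rise is at least 0.05 µS and the peak occurs
within 5 s of the valley; both thresholds are parameters. Zero SCRs is a
valid result.

Instantaneous heart- and respiration-rate series are piecewise-constant
`60 / inter-event-interval` values resampled on a fixed grid (default 4 Hz),
extended by the edge intervals before the first and after the last event.
Piecewise-constant is the simplest scheme consistent with an instantaneous
rate "as a function of time"; the grid rate is configurable.

## Features

Per participant and interval, 20 features: nine ECG/HRV (mean/min/max heart
rate; SDNN; RMSSD; pNN50; low-frequency 0.04–0.15 Hz and high-frequency
0.15–0.40 Hz tachogram power; their ratio), two respiration (mean and SD of
the instantaneous rate series — the SD is over the evenly sampled series, a
convention stated here because breath-to-breath SD is an equally plausible
reading), six EDA (mean, final, final-minus-initial, SCR count, mean and SD
of SCR amplitudes), and three temperature (mean, final, final-minus-initial).
Band powers use a Lomb–Scargle spectrum on the unevenly sampled beat times,
avoiding resampling bias on 2-minute windows. Standard deviations use the
sample (n−1) denominator throughout. The LF/HF ratio is missing when HF
power is zero; amplitude statistics are missing below 1 (mean) or 2 (SD)
SCRs.

Synchrony is computed on four per-dyad pairs — EDA and temperature samples,
instantaneous heart rate and respiration rate — each decimated to the 4 Hz
analysis grid and z-scored per interval so distances are comparable across
dyads. Nine measures per pair:

* **DTW** — classic dynamic time warping with absolute-difference cost,
  unconstrained symmetric steps, normalized by the optimal warping-path
  length (diagonal-preferring traceback among minimal-cost paths, so
  `[0,0]` vs `[1,1]` scores exactly 1.0).
* **Derivative DTW** — DTW on the local-derivative transform
  `d[i] = ((x[i]−x[i−1]) + (x[i+1]−x[i−1])/2)/2` with endpoint replication;
  offsets cancel exactly.
* **Complexity-invariant DTW** — DTW times
  `max(CE_a, CE_b)/min(CE_a, CE_b)` with `CE(x) = sqrt(Σ diff(x)^2)`;
  the factor is 1 when both are zero and capped at 1e6 when exactly one is.
* **Nonlinear interdependence** — symmetric state-space measure on delay
  embeddings (dimension 3, delay 2 samples, 4 neighbors, Theiler window 8
  samples — typical values for slow autonomic series at 4 Hz; all
  configurable): `S(A|B)` averages the ratio of each point's true
  neighborhood size to the size induced by the partner's neighbor indices.
* **Coherence** — Welch magnitude-squared coherence (60 s Hann windows, 50%
  overlap) band-averaged over 0.01–0.5 Hz, the band that contains the
  autonomic rhythms these modalities carry within 2-minute windows.
* **Cross-correlation** — maximum absolute Pearson correlation over lags
  within ±10 s (physiological response latencies), sign discarded.
* **Cosine distance** — `1 − cos` of the angle between the two series as
  vectors.
* **Hausdorff** and **symmetric segment-path distance (SSPD)** — planar
  trajectory distances on points `(t·λ, value)`. These distances are
  meaningless without fixing relative axis units, so the time axis is scaled
  (λ) to map the interval's time span onto the z-scored value range;
  λ is configurable. SSPD averages each point's minimum distance to the
  other trajectory's segments, in both directions.

36 synchrony features per dyad-interval; a missing channel propagates as
missing values for that modality's nine features only.

## Designs, selection and estimators

Features are baseline-normalized per dyad (and participant) by subtracting
the first baseline interval's values, or the mean of both baselines.
Normalization is applied uniformly to all three estimation goals — for the
dyad-specific goal it is a constant within-unit shift and cannot hurt — and
a flag guards against double application.

Three goals: (1) dyad-specific estimation of self-reported ratings, one
model per participant, inputs = own 20 individual features + 36 synchrony
features (56 columns), the partner's individual features excluded;
(2) dyad-nonspecific estimation of self-reported ratings, trained on other
dyads, same 56 columns; (3) dyad-nonspecific estimation of observer ratings,
one row per dyad with both participants' individual features + synchrony
(76 columns). Characteristics (age, one-hot gender — three categories —
and four traits) can be appended for goals 2 and 3.

Crossvalidation follows the protocol exactly: goal 1 splits each
participant's ten intervals 8:1:1 (training/validation/test, ten folds,
validation = the cyclically next interval); goals 2 and 3 leave one dyad out
as test with the cyclically next dyad as validation (39:1:1 over 41 dyads,
33:1:1 over 35). For each fold every candidate — selector (MRMR or
Laplacian score) × number of kept features (default grid 5–10) — is fitted
per method on training rows only; the candidate minimizing validation RMS is
applied to the test unit. Ties break toward fewer features, then candidate
order. Every stochastic fit is seeded from (master seed, goal, fold,
method).

MRMR greedily maximizes relevance minus mean absolute correlation with the
already-selected set; relevance is the univariate F-statistic mapped to its
equivalent squared correlation `F/(F+n−2)` so both terms share a [0,1] scale
(with raw F the redundancy term could never exclude a duplicated feature).
Constant features rank last. The Laplacian score is computed on a
5-nearest-neighbor heat-kernel graph over standardized rows; features are
ranked ascending (locality-preserving first), constants last.

Four estimators share one train/predict contract (median imputation from
training columns, standardization by training statistics, predictions
clipped to the 1–9 scale):

* **MLP** — one hidden layer (default 10 tanh units, linear output) trained
  by Levenberg–Marquardt for up to 1,000 epochs. A conventional learning
  rate does not exist inside Levenberg–Marquardt; the package therefore
  treats the damping schedule as the step-size control and additionally
  offers a plain gradient mode where a literal learning rate of 0.1
  applies. Training stops early only on numerical convergence (relative
  error reduction below 1e-10 or damping overflow) — there is no
  validation-based early stopping; validation data only select among
  candidates.
* **Linear** — least squares, optionally lasso/ridge via `glmnet` with
  strengths selected on the validation unit from a small grid.
* **SVM** — Gaussian-kernel epsilon-regression via `e1071`, kernel width
  from the median pairwise-distance heuristic.
* **MBE** — the median baseline: dyad-specific, the median of the
  participant's other nine ratings; dyad-nonspecific, the pooled median of
  all other dyads' per-interval ratings (even counts average the two central
  values). Pooling intervals rather than per-participant medians is the
  plainest reading of the baseline's definition; a per-unit alternative is a
  one-line change in `mbe_dyad_nonspecific` input construction.

## Evaluation

Per-interval error is the signed difference between estimate and reported
rating; each unit (participant, or dyad for goal 3) is summarized by
mean-absolute and root-mean-square error over its ten intervals, with
`RMS ≥ MA` asserted on every summary. Methods are compared by one-way
repeated-measures ANOVA across methods with units as subjects, followed by
Holm–Šidák-adjusted paired t-tests. Secondary analyses rerun the MLP with
synchrony features removed (ablation) or characteristics added
(augmentation, dyad-nonspecific only) and compare per-unit errors with a
paired t-test when the paired differences pass Shapiro–Wilk normality at
α = 0.05, otherwise Wilcoxon. The most important features are reported as
the top five by Laplacian ranking on the full design, separately per target
and rater stream.

## Numerical choices and problem sizes

Levenberg–Marquardt starts at damping 1e-2, dividing by 10 after an
accepted step and multiplying by 10 (up to 1e12) after a rejected one;
initialization is seeded Gaussian with weight scale `1/sqrt(fan-in)`.
Zero-variance series are centered but not scaled and flagged degenerate;
zero-variance features standardize with divisor 1. The dyad-index substream
derivation keeps all derived seeds below 2^31.

The package's own test and acceptance runs use desk-scale problem sizes
chosen as a deliberate trade-off: cohorts are generated at 25–50 Hz (beat
timing at 50 Hz is accurate to 20 ms, well below the variability of the
generated inter-beat process), and the recovery checks run the
dyad-nonspecific MLP with 8 hidden units, 60 epochs and 6 MRMR-selected
features — enough capacity to recover an affine label structure while
keeping 20-replicate Monte-Carlo suites fast. The full-scale defaults
(100 Hz, 10 hidden units, 1,000 epochs, selector grids) remain the exported
defaults.

## Limitations

The generator is a stand-in, not a claim about any real cohort's
distributions. Exact numerical equivalence with other implementations of
the synchrony measures is not claimed — published parameterizations of DTW
constraints, embedding parameters and coherence bands vary, and this
package documents and exposes its own. Dyad-specific estimation trains on
eight rows with dozens of candidate features; overfitting is expected and
visible in training-versus-test error comparisons, which is itself a finding
the evaluation machinery surfaces rather than hides.
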