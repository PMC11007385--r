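---
title: "Methods: synthetic rodent polysomnography, spectral features and leave-rats-out classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic rodent polysomnography, spectral features and leave-rats-out classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somnopark implements an epoch-wise pipeline for rodent electrophysiology:
score each 10-s epoch of a 2-h frontal-ECoG / occipital-ECoG / EMG recording
as WAKE, NREM or REM, and recognize whether the animal carries a unilateral
6-OHDA lesion of the nigrostriatal pathway (a rat model of Parkinson's
disease), from three feature families per epoch: mean spectral power in
seven conventional bands per cortical site, the mean absolute amplitude of
the conditioned EMG, and the band-averaged corticomuscular coherence (CMC)
between each cortical site and the muscle. RBF-kernel support vector
machines are trained and evaluated under leave-animals-out protocols.
Because no public recordings accompany this problem, the package ships a
synthetic cohort generator whose epoch-level statistics reproduce the
qualitative physiology; every downstream stage is tested against it.

## The synthetic cohort generator

### State process

The hypnogram is a semi-Markov chain over {WAKE, NREM, REM}. Bout durations
are geometric at epoch granularity with configurable means
(`state_mean_dur_s`, defaults 60/160/80 s): the simplest process with
controllable bout structure, since no bout statistics are available to fit
anything richer. Bout-to-bout transition probabilities are *solved*, not
specified: given the mean durations and the target long-run occupancy
`state_stationary` (default 0.239/0.643/0.119, the WAKE/NREM/REM mix of a
sham cohort of 6480 epochs), visit rates per state must be proportional to
occupancy divided by mean duration, which fixes the two free branch
probabilities P(NREM→REM) and P(REM→WAKE). By default REM can only be
entered from NREM (`rem_after_nrem_only`), the physiologically normal
pattern; configurations whose duration/occupancy combination admits no
valid branch probabilities are rejected with an error rather than silently
renormalized.

### Waveform model

Each ECoG channel is a sum over the seven bands (delta 0.5–4 … high-gamma
40.5–60 Hz) of band-limited Gaussian sources with state-dependent RMS
amplitude, plus a white-noise floor. Band-limited noise is synthesized in
the frequency domain — a complex Gaussian spectrum masked to the band,
inverse transformed, and scaled to unit variance — which gives an exactly
flat in-band power density of $1/B$ per unit variance ($B$ the band width
in Hz). Flatness is what makes every band-power and coherence expectation
analytic, and the frequency-domain route is also the numerically safe one:
high-order IIR band-passes become unstable at the delta band's very low
normalized corner frequencies at 1 kHz sampling.

Amplitude envelopes follow the hypnogram and are cross-faded with a 0.1-s
raised-cosine ramp at every epoch boundary where the gain changes, so state
transitions do not inject broadband edge artifacts.

The EMG is broadband white noise scaled per state (defaults 3/1.5/0.5 for
WAKE/NREM/REM, giving the canonical monotone amplitude decline from WAKE to
REM). Corticomuscular coherence is produced by *shared sources*: the band
source that drives an ECoG channel is also injected into the EMG with
weight $c \cdot a$ (coupling times ECoG amplitude). For one band the
expected magnitude-squared coherence has the closed form

$$
C \;=\; \frac{(c\,S)^2}{\bigl(S + 2\sigma_{\mathrm{ECoG}}^2/f_s\bigr)
                       \bigl(c^2 S + 2\sigma_{\mathrm{EMG}}^2/f_s\bigr)},
\qquad S = a^2/B ,
$$

i.e. a signal-to-noise ratio on each side, with the white-noise terms
expressed as one-sided densities. Because broadband EMG noise is
spectrally dilute (density $2\sigma^2/f_s$ per Hz), *small* coupling
fractions already produce large in-band coherence; the default weights were
derived by inverting this formula so that the expected occipital theta CMC
is ≈ 0.3/0.05/0.7 and the frontal delta CMC ≈ 0.1/0.6/0.1 across
WAKE/NREM/REM — theta coherence peaking in REM and bottoming in NREM,
delta coherence peaking in NREM. The same closed form is the oracle in the
test suite (± 3 Monte-Carlo standard errors, with the first-order
$({1-C})^2/K$ small-sample bias of the $K$-window estimator added).

### Group (lesion) signatures

Lesioned animals multiply their *frontal* band amplitudes by `lesion_mod`:
alpha ×1.30 in WAKE/REM and ×0.85 in NREM, high-beta and low-gamma ×1.5 /
×1.45 in WAKE and REM, and high-gamma ×0.70 *uniformly in all three
states*. The uniformity of the high-gamma reduction is deliberate: per-rat
min–max normalization (below) is invariant to a whole-column scale factor,
so the high-gamma contrast survives only in the *unnormalized* power —
while the state-dependent alpha/high-beta/low-gamma shifts reshape the
within-rat distribution and stay visible after normalization. This is how
the pipeline reproduces the screening outcome that motivates the four
marker features (normalized frontal alpha, high-beta, low-gamma; raw
frontal high-gamma). Exact magnitudes are free parameters of the problem;
the presets were chosen once so that the screening statistics are decisive
at a few hundred epochs per state-group cell.

### Inter-animal heterogeneity

Identical animals make leave-rat-out evaluation trivially perfect, which no
real cohort shows. Each rat therefore draws log-normal factors per (site,
state, band) for its ECoG amplitudes and per state (at half the log-sd) for
its EMG scale, controlled by `rat_sd` (default 0.1). The default was set
analytically from the discrimination regime the pipeline is meant to
emulate: with four marker features carrying group log-effects near 0.4, a
per-rat log-sd of 0.1 leaves per-marker rat-level separations of ≈ 2.8 sd
(jointly > 5 sd), i.e. near-ceiling cross-animal PD recognition, while
still producing visible animal-to-animal spread in the state contrasts.
It was fixed once and not iterated against test outcomes.

### What the generator does not emulate

No waveform morphology (spindles, K-complexes, REM-without-atonia), no
movement or electrode artifacts, no ambiguous transitional epochs, and no
scorer disagreement — the ground-truth labels are exact. Consequently the
synthetic sleep-scoring task is *cleaner* than real recordings: the
protocols routinely reach accuracies and kappas at or near 1.0, above the
0.7–0.9 range typical of real rodent data. Passing the end-to-end checks
demonstrates that the pipeline recovers the structure the generator
encodes across unseen, heterogeneous animals; it does not certify
performance on real recordings. The binary lesion-recognition task, whose
difficulty is governed by the rat-level effect/heterogeneity ratio rather
than by label noise, lands in a realistic regime (fold accuracies in the
mid-90s, pooled AUC ≈ 0.99).

## Feature extraction

* **Notch.** 50 Hz line interference is removed from all three channels by
  a second-order IIR notch (quality factor 30) applied zero-phase
  (forward–backward), giving narrow rejection with pass-band change well
  under 1 dB a few Hz away.
* **EMG conditioning.** The EMG amplitude feature uses a 20–200 Hz
  4th-order Butterworth band-pass, zero-phase; the feature is the mean
  absolute value of the filtered epoch.
* **Epoching.** Half-open, 0-based 10-s windows; a trailing partial epoch
  is discarded.
* **Spectra.** Welch estimator with 1-s periodic-Hann windows at 50 %
  overlap: 19 windows per 10-s epoch and 1 Hz resolution. One-sided
  density normalization is checked by a Parseval identity (integrated PSD
  equals the variance within 1 % for white noise) and by the analytic
  white-noise level $2/f_s$. A PSD bin belongs to the band containing its
  centre; with 1 Hz bins the 0.5-Hz band edges never coincide with a
  centre, and a hypothetical tie would go to the lower band.
* **Band power.** The mean of the one-sided PSD bins inside each band
  (units amplitude²/Hz).
* **CMC.** Magnitude-squared coherence
  $C(f)=|S_{xy}|^2/(S_{xx}S_{yy})$ from the same Welch settings, averaged
  over each band's bins, one value per epoch per site per band. Coherence
  is computed against the *notch-filtered raw* EMG, not the 20–200 Hz
  band-passed EMG: the delta and theta coherence bands lie inside the EMG
  conditioning filter's stop band, where a band-passed EMG retains only
  spectral leakage and the coherence estimate degenerates. Per-epoch
  estimation (rather than longer stretches) keeps one coherence vector per
  classified epoch. An all-zero channel yields 0 in all bands with a
  warning, keeping batch extraction total.
* **Normalization.** Min–max scaling of every feature column to [0, 1]
  *within each animal*, for train and test animals alike. Per-rat scope
  uses no cross-animal statistics, so nothing leaks from training to
  held-out rats; it is also the scope that makes normalization do its
  stated job of absorbing inter-animal amplitude differences. A pooled
  alternative is available (`scope = "cohort"`). Constant columns map
  to 0. Columns listed in `keep_raw` (default: frontal high-gamma power)
  are retained unscaled under a `raw_` prefix.

## Feature screening

The screening tests are implemented from their standard formulas — pooled
midranks, tie corrections, asymptotic references — so each is verifiable
against enumeration oracles and base R: one-sample Kolmogorov–Smirnov
against a fitted normal (the gate for nonparametric testing),
Kruskal–Wallis with the tie-corrected $H$ against $\chi^2_{k-1}$, Dunn's
pairwise $z$ from the pooled ranks (Bonferroni-adjusted by default), and
the Mann–Whitney U with an exact dynamic-programming null distribution for
tie-free samples up to $n_x n_y \le 400$ and a tie- and
continuity-corrected normal approximation otherwise. All tests are
two-sided. A parametric (t/ANOVA) branch is intentionally absent: the
screening results this pipeline consumes are nonparametric.

`screen_pd_features()` compares sham vs lesion epochs per frontal feature
per state. Epoch-level comparison matches the scale at which the screening
figures are drawn, but epochs within an animal are not independent: with
heterogeneous animals, epoch-level p-values also pick up rat-level random
differences (pseudo-replication). The `aggregate = "rat"` switch collapses
to per-rat medians (n = number of animals) for a conservative reading.

## Classification

* **Model.** RBF-kernel SVM (libsvm via e1071), features fed as normalized
  [0, 1] columns without libsvm's internal rescaling.
* **Grids.** $C \in \{2^0,\dots,2^7\}$, $\gamma \in \{2^{-7},\dots,2^0\}$ —
  powers of two spanning the conventional tuning intervals.
* **Selection.** Exhaustive grid search by stratified 5-fold
  cross-validation on the training epochs; the highest mean validation
  accuracy wins, ties resolved toward the smallest $C$, then the smallest
  $\gamma$; the winner is refit on all training epochs. Training sets above
  `tune_max` epochs (default 4000) are stratified-subsampled *for tuning
  only*.
* **Multi-class.** One-vs-one with explicit vote aggregation; vote ties are
  broken by the summed signed pairwise decision values.
* **Protocols.** (i) *Sleep*: per site, a model trained on the sham
  training rats and one on the lesion training rats (all but one held-out
  rat per group, held-out choice seeded), each tested on both held-out
  rats — four confusion matrices. (ii) *PD*: animals paired by index after
  sorting ids (no pairing covariate exists for anything cleverer);
  leave-one-pair-out over the four marker features; per-fold accuracy and
  kappa as mean ± SD; ROC/AUC from the decision scores pooled over folds.
  (iii) *Integrated*: a single 6-class machine over (state × group) —
  chosen over a two-stage gate because the joint confusion matrix is the
  reported object — on the site-mode's band powers + EMG + the four
  markers; marginal 3-state and sham/lesion reports are obtained by
  collapsing the 6-class matrix. No class weighting is applied despite
  NREM dominance, matching the reference protocol.
* **Determinism.** One master seed; rat splits, fold assignments and
  subsampling seeds derive from it arithmetically; libsvm itself is
  deterministic. Identical seeds give byte-identical written reports.

## Evaluation

Confusion matrices are counted with a fixed class order; precision,
sensitivity and specificity are one-vs-rest per class; overall accuracy is
the trace ratio; Cohen's kappa uses the marginal-product chance term, with
the degenerate all-mass-in-one-cell case defined as 1 for perfect
agreement and 0 otherwise. Ratios with zero denominators are reported as
`NA` and listed in an `undefined` field — never coerced to 0, which would
silently distort fold averages. ROC/AUC exists only for the binary task;
the curve sweeps the unique scores with ties included simultaneously, and
the trapezoidal AUC equals the tie-corrected Mann–Whitney statistic
$U/(n_1 n_0)$ exactly (a test asserts the identity at $10^{-10}$).

## Problem sizes

The defaults describe the full design: 2-h recordings at 1 kHz, 10-s
epochs, 9 + 9 animals. The test suite exercises the statistics at reduced,
fixed scales chosen for routine runs — a 6 + 6 × 15-min cohort for
screening and protocol contracts, a 9 + 9 × 10-min cohort for the
end-to-end performance check — and the reproduction script
(`scripts/acceptance.R`) runs the complete pipeline on a 9 + 9 × 1-h
cohort with grid-search subsampling at 2000 epochs. At reduced scale the
scarce REM stratum (~12 % of epochs) supports strict significance claims
only for the stronger markers; the corresponding tests say so explicitly.

## Known limitations

* The generator's realism is epoch-statistical, not morphological; sleep
  scoring results on it are upper bounds, not forecasts, for real data.
* Epoch-level screening inherits pseudo-replication; use
  `aggregate = "rat"` for animal-level inference.
* The KS gate uses the asymptotic Kolmogorov distribution with estimated
  parameters (anticonservative, as is conventional when used as a routing
  gate rather than a reported test).
* EDF support covers the continuous, equal-rate, 16-bit subset of the
  format that the pipeline itself writes.
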