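# somnopark

Automatic sleep–wake scoring and parkinsonian-state recognition from
rodent electrocorticography (ECoG) and electromyography (EMG).

Sleep disturbance is an early non-motor sign of Parkinson's disease, and
rat models of the disease (unilateral 6-OHDA lesion of the nigrostriatal
pathway) show both disturbed sleep architecture and characteristic
cortical oscillation changes. Scoring 2-h polysomnographic recordings into
WAKE / NREM / REM by hand is slow; this package implements the full
automatic pipeline for people working with such recordings — and, because
animal recordings of this kind are rarely public, a synthetic cohort
generator that reproduces the epoch-level physiology so the whole pipeline
is testable end to end.

## What it computes

Each 10-s epoch of a frontal-ECoG / occipital-ECoG / EMG recording
(1 kHz) is described by 29 features:

* **Band power** — mean one-sided Welch PSD (1-s Hann windows, 50 %
  overlap) in the seven conventional rodent bands
  (δ 0.5–4, θ 4.5–8, α 8.5–12, low-β 12.5–20, high-β 20.5–30,
  low-γ 30.5–40, high-γ 40.5–60 Hz), per cortical site;
* **EMG amplitude** — mean |EMG| after 20–200 Hz band-passing;
* **Corticomuscular coherence (CMC)** — band-averaged magnitude-squared
  coherence C(f) = |S<sub>xy</sub>|² / (S<sub>xx</sub> S<sub>yy</sub>)
  between each cortical site and the EMG.

Features are min–max normalized to [0, 1] within each animal; the frontal
high-γ power is additionally kept unnormalized. Nonparametric screening
(Kolmogorov–Smirnov gate, Kruskal–Wallis + Dunn, Mann–Whitney U) ranks the
sham-vs-lesion contrasts and motivates the four **PD marker features**:
normalized frontal α, high-β, low-γ power and raw frontal high-γ power.

Three RBF-SVM classifier families (C ∈ 2⁰…2⁷, γ ∈ 2⁻⁷…2⁰, stratified
inner-CV grid search) are evaluated with animals — never epochs — held
out: per-site 3-state sleep scoring trained on one group and tested on
both, binary sham/lesion recognition under leave-one-pair-out, and an
integrated 6-class (state × group) model. Reports carry confusion
matrices, per-class precision/sensitivity/specificity, overall accuracy,
Cohen's κ, and ROC/AUC for the binary task.

## Worked example

```r
library(somnopark)

cfg      <- generator_config(duration_s = 900)          # 15-min recordings
cohort   <- generate_cohort(cfg, n_sham = 3, n_lesion = 3, seed = 42)
features <- normalize_features(extract_cohort_features(cohort))

head(screen_pd_features(features), 4)
#>                  feature state statistic      p_value
#> 1 raw_pow_frontal_hgamma  NREM   32835.0 1.217200e-60
#> 2     pow_frontal_lgamma  NREM   31128.0 4.842229e-49
#> 3      pow_frontal_hbeta  NREM   30596.5 1.094731e-45
#> 4 raw_pow_frontal_hgamma  WAKE    4611.0 4.051105e-23

sleep <- run_sleep_protocol(features, site = "occipital", seed = 1)
sleep$sham_train.sham_test
#> <somno_report>  sham train -> sham test (occipital)
#>       predicted
#> true   WAKE NREM REM
#>   WAKE   28    0   0
#>   NREM    0   44   0
#>   REM     1   17   0
#> accuracy 0.800, kappa 0.648

run_pd_protocol(features, seed = 1)
#> <somno_pd_result> 3 folds: accuracy 0.994 +/- 0.006, kappa 0.989 +/- 0.011, AUC 1.000
```

The screening table ranks sham-vs-lesion contrasts per state: the raw
high-γ reduction and the normalized high-β/low-γ elevations dominate, as
designed. The sleep report shows the typical failure mode of a too-small
cohort (two training animals): WAKE and NREM are clean while REM — the
rare state — collapses into NREM. The PD protocol, driven by rat-level
marker contrasts, is near-ceiling even at this scale. At the full design
(9 + 9 animals, 2-h recordings) both tasks are strong; see the methods
vignette (`vignettes/somnopark-methods.Rmd`) for what performance on the
synthetic surrogate does and does not imply about real recordings.

`run_all(run_config(...))` chains generate → extract → screen → train →
evaluate into an output directory with a checksummed manifest, and
`inst/cli/somnopark` exposes the same stages as shell verbs
(`generate`, `features`, `screen`, `train`, `evaluate`, `run-all`).

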