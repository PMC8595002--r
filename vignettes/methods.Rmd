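---
title: "Methods: multiscale PCA denoising, wavelet-packet features and ensemble classification of motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Motor imagery (MI) — the mental rehearsal of a movement — modulates the
sensorimotor mu (~8–12 Hz) and beta (~18–26 Hz) rhythms recorded over central
scalp sites (C3, Cz, C4). Imagining a right-hand versus a right-foot movement
produces spatially distinct event-related desynchronization (ERD): a drop in
band power over the corresponding cortical area. A brain–computer interface
must decide, from a single 3.5-second trial, which of the two tasks was
imagined.

`mieeg` implements a classical, fully inspectable pipeline for this decision:

1. **MSPCA denoising** — each trial's three channels are decomposed with a
   5-level Daubechies wavelet pyramid; at every scale the coefficient-by-
   channel matrix undergoes PCA across channels; only components with
   eigenvalue above the mean (Kaiser rule) are kept; channels are
   resynthesized. Cross-channel–correlated structure (the rhythms) survives;
   channel-independent noise is shrunk.
2. **Wavelet-packet features** — the denoised signal is decomposed by a
   complete 4-level wavelet packet tree into 16 subbands (natural filter-bank
   order). Each subband contributes its mean absolute value (MAV), average
   power, standard deviation, skewness and kurtosis (16 × 5 = 80), and the 15
   ratios of adjacent-subband MAVs complete a 95-dimensional feature vector
   per trial.
3. **Ensemble classification** — Rotation Forest (blockwise-PCA-rotated
   feature space per member, score averaging) or the Random Subspace method
   (random feature subsets per member, majority voting) over six base
   learners: SVM (cubic polynomial kernel, C = 100), 1-NN, random forest
   (100 trees), and three entropy decision trees (C4.5-like with gain ratio
   and pessimistic pruning; REP tree with reduced-error pruning on a held-out
   third; unpruned random tree).
4. **Evaluation** — stratified 10-fold cross-validation; accuracy
   `100·(tp+tn)/(tp+tn+fp+fn)`, F-measure `tp/(tp+(fp+fn)/2)`, and the
   trapezoidal/rank AUC, reported per subject and pooled over all subjects'
   trials.

## Numerical choices

**Wavelet transform and padding.** No wavelet library is assumed: the
Daubechies extremal-phase filters db1–db10 are tabulated to 17 significant
digits (obtained by spectral factorization of the maxflat half-band
polynomial; the orthonormality identities hold to < 2 × 10⁻¹²). The decimated
transforms use *periodized* filtering, which is exactly orthogonal when every
stage input has even length. Signals whose length is not a multiple of
2^level (e.g. 350 samples at level 4 or 5) are zero-padded to the next
multiple and trimmed after synthesis. Zero padding was chosen over symmetric
extension deliberately: padded zeros add no energy, so perfect
reconstruction, Parseval energy conservation, and energy non-expansion under
component dropping all hold to machine precision for *any* input length —
properties the test suite asserts at 10⁻⁸. The cost is a synthetic edge at
the pad boundary, which is immaterial for whole-segment statistics.

**PCA.** Covariance uses the n − 1 divisor; eigenvalues are sorted
non-increasing; with all components retained the reconstruction is exact.
The Kaiser retention rule keeps eigenvalues strictly above their mean; the
all-equal tie (no eigenvalue above the mean) falls back to keeping the first
component so the model is never empty. Coefficient-matrix means are restored
after reconstruction, preserving DC content. The deepest approximation band
is PCA-processed like the details by default (`process_approximation`),
because leaving it untouched would pass baseline noise through unchanged; the
stricter details-only reading is a configuration flag.

**Feature conventions.** Standard deviation uses n − 1 by default; kurtosis
is Pearson (normal → 3) with excess as an option; zero-variance subbands
return 0 for skewness and kurtosis so features are always finite; ratio
denominators carry an additive ε = 10⁻¹² guard. Homogeneity degrees are exact
and tested: MAV/std scale linearly with amplitude, power quadratically,
skewness/kurtosis/ratios are scale-free.

**Subband ordering** is natural (repeated low/high splitting), not
frequency-ordered. The adjacent-MAV ratios depend on this ordering, so it is
fixed and encoded in the canonical header (`sb01_mav … sb16_kurt,
ratio_01 … ratio_15`).

**Channel aggregation** is the largest open question of the method
description: 95 features are reported per 3-channel trial without saying how
channels combine. The default (`mean`) averages per-channel feature vectors;
`concat_signal` and `single_channel` are alternatives. Note a structural
consequence demonstrated by the synthetic generator: when the two classes
attenuate *mirror-image* channels equally (class 1 on C3, class 2 on C4), any
channel-symmetric aggregation produces identically distributed features for
both classes — cross-validated accuracy is then chance by construction, and
the acceptance suite's discriminative runs therefore analyse a single lateral
channel. On real recordings ERD is rarely perfectly symmetric, which is why
the channel-mean can still work there; on the idealized simulation it cannot,
and a green (or red) test must be read with that in mind.

**SVM details.** Features are standardized inside the learner; the kernel is
`(1 + u·v/p)³`; the soft-margin dual is solved as a ridge-stabilized QP;
ranking scores for AUC come from a logistic link fitted on training decision
values (labels use the raw decision sign). **k-NN** uses per-attribute
min–max range normalization by default — the convention of the instance-based
learners in the toolkit the method description reflects — with
`normalize = FALSE` giving the raw, rotation-equivariant metric.

**Cross-validation folds** are stratified by class; when subject codes are
present, each subject-by-class stratum is additionally spread evenly across
folds (per-fold class totals stay exact). This matters: with class-only
stratification, subject-cluster sampling noise pushes heavily overfitting
learners measurably *below* chance on label-independent data, which would be
misread as a defect. Fold aggregation pools confusion counts (not fold-metric
averages); AUC pools each instance's single held-out score. The pooled "ALL"
scheme mixes all subjects' trials before folding — the subject-independent
protocol of the source experiment design — and is *not* leave-one-subject-out.

**Tie-breaks.** Majority votes and score ties resolve to the lowest class
label; tree split ties resolve to the first (lowest-index) feature at the
best score. All randomness flows from explicit integer seeds; identical
(configuration, seed, data) reproduce bit-identical models, predictions and
output files.

## The synthetic generator: what it emulates, and what it does not

`generate_dataset()` emulates the trial layout of the motivating experiment:
5 subjects × 280 trials (140 per class), 3 channels, 100 Hz, 3.5 s — 1400
labelled segments. Each trial is a sustained mu + beta oscillation (per-trial
random frequency within band and random phase, beta at 0.8 relative
amplitude) shared across channels with spatial gains (1, 0.8, 1), summed with
independent 1/f^α Gaussian noise per channel, scaled so the rhythm-to-noise
power ratio on an unattenuated channel equals `snr_db` (default 5 dB — the
source signals' SNR is uncharacterized, so this is a declared free choice).
ERD is a sustained multiplicative *amplitude* attenuation `erd_factor` of the
rhythm on C3 (class 1) or C4 (class 2); band power scales with its square.
Per-subject lognormal gains (σ = 0.25) on rhythm and noise amplitude create
subject variability, so per-subject and pooled evaluation genuinely differ.

Not emulated: volume conduction/forward-model mixing, EOG/EMG artifacts,
time-locked (transient) ERD dynamics, non-stationarity across a session.
A green statistical test on this generator establishes that the pipeline
recovers sustained band-power differences at realistic SNR — not that it
reproduces the accuracy figures attainable on the real, restricted dataset.

`generate_null_dataset()` forces `erd_factor = 1` and assigns balanced labels
by random permutation, independent of signal content: the reference world in
which every classifier must sit inside the binomial 99% band around 50%.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| MSPCA wavelet | db4, level 5 | — | family stated by the method; order unstated, db4 balances support vs smoothness at 350 samples |
| retention rule | Kaiser | — | the convention of the MSPCA literature; `none` gives an exact identity, `fixed_k` is available |
| WPD wavelet | db4, level 4 | — | 16 subbands of ~3.1 Hz at 100 Hz sampling |
| `ratio_epsilon` | 1e-12 | — | makes all 15 ratios total and finite |
| SVM | cubic kernel, C = 100 | — | stated settings |
| k-NN | k = 1, range-normalized | — | stated k; normalization per toolkit convention |
| RF | 100 trees, mtry = √p | — | stated tree count |
| RoF | 10 members, group size 3, 75%/75% class-subset/subsample | — | member count, Q and the sampling fractions are unstated; Rodriguez-style defaults, echoed into provenance |
| RSM | 10 members, fraction 0.5 | — | B unstated; floor(0.5·95) = 47 features/member |
| simulation `snr_db` | 5 | dB | declared free choice (see above) |
| simulation `erd_factor` | 0.5 | amplitude | mid-range sustained ERD; power factor 0.25 |

## Known limitations

- Binary classification only (the two MI classes); no multiclass machinery.
- No best-basis packet selection; the tree is always complete to level 4.
- The delimited trial dump and EDF writer assume equal-length trials.
- EDF output quantizes to 16 bits and stores labels in an extra
  `TRIAL_LABEL` signal (plain EDF has no per-record annotations); subject
  codes ride in a JSON sidecar, so moving the `.edf` without its sidecar
  loses subject identity (labels survive).
- Behavioural equivalence with the original MATLAB/Weka implementations is
  not claimed anywhere: tree pruning heuristics, SVM probability links and
  ensemble sampling details follow the cited algorithm descriptions, not any
  toolkit's binary behaviour.
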