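---
title: "megconn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{megconn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`megconn` stratifies a four-group cohort (PTSD, trauma-exposed controls,
mTBI, non-trauma controls) from source-space MEG using two feature families —
band-limited regional power and amplitude-envelope-correlation (AEC)
connectivity — followed by univariate screening, nested cross-validated
recursive random-forest feature selection with SVM modelling (CV-SVM-rRF-FS),
PLS-DA verification, permutation testing and a single stratified holdout
evaluation. This vignette records the model assumptions, the tunable
parameters, the numerical choices, and the limits of what the synthetic
validation shows.

## The synthetic cohort model

Clinical MEG recordings cannot be redistributed, so the package's testbed is
a generative model of source-space ("virtual sensor") ROI time series with
known, planted group structure. Each of `n_regions` channels of a subject is

$$x_r(t) = s \left[ \sigma_n\, \eta_r(t) + \sum_b A_b\, m_b\, e_{r,b}(t)\,
\sin(2\pi f_b t + \phi_{r,b}) \right]$$

* $\eta_r$: 1/f ("pink") background noise with spectral exponent
  `noise_exponent` (default 1) and SD `noise_sd` (default 1), synthesised in
  the frequency domain and normalised per epoch.
* one oscillation per band at the band-centre frequency $f_b$, with baseline
  amplitude `base_amplitudes[b]` (defaults decline with frequency, mimicking
  the 1/f trend of real spectra) and a uniformly random phase per channel,
  band and epoch.
* $e_{r,b}(t)$: a slow positive random envelope,
  $\exp(\sigma_e z(t))$ with $z$ Gaussian noise low-pass filtered below
  `env_cutoff` (default 0.5 Hz) and `env_sigma` $= \sigma_e = 0.4$; resting
  envelope dynamics are slow, which is also what makes them AEC-detectable.
* $s$: a per-subject log-normal global amplitude factor
  (`subject_scale_sigma`, default 0.3). Source amplitude and SNR differ
  substantially between heads in real data; without this term the absence of
  a marker becomes an implausibly reliable classification cue, and
  between-subject feature noise is unrealistically small.
* planted effects: a `power_effect(band, roi, groups, magnitude)` multiplies
  $m_b$ for the target ROI/groups (amplitude ×2 means band power ×4); an
  `edge_effect(band, i, j, groups, coupling)` replaces both ROIs' envelopes by
  $(1-c)\,e_{\text{own}} + c\,e_{\text{shared}}$, so coupling $c = 1$ with
  zero noise makes the two envelopes identical up to scale, and AEC increases
  monotonically in $c$.

Generation is deterministic: every subject's seed derives from the cohort
seed via hashing, so identical `(config, effects, seed)` give bit-identical
cohorts, and disjoint seeds share the ground-truth map. Default group sizes
are 24/27/27/23 (the reference cohort; any map is allowed). The source
sampling rate and epoch count of the original acquisition are not part of
the reproduced material, so `fs = 600` Hz (chosen to resolve the 80–150 Hz
band) and `n_epochs = 6` of 10-s epochs are explicit, configurable
placeholders.

What the generator does **not** emulate: sensor-level physics, head models
and beamforming (generation starts at ROI level), spatially correlated
source leakage beyond what the orthogonalisation tests inject, non-sinusoidal
and cross-frequency waveform structure, artifacts, and within-band spectral
detail (each band carries one band-centre oscillation). Passing recovery
tests therefore demonstrate that the *pipeline* finds what the generative
model plants at realistic sizes and SNRs — not that clinical effects of this
size exist or would be found in real recordings.

## Feature derivation

**Regional power.** Welch PSD per 10-s epoch per ROI, averaged across
epochs: 2-s Hann segments with 50% overlap (0.5 Hz resolution, so the 1–3 Hz
delta band spans several bins), segments demeaned, one-sided density scaled
by $1/(f_s \sum w^2)$. Band power is the trapezoidal integral of the density
over $[lo, hi]$. Validated against closed forms: a sinusoid of amplitude $A$
integrates to $A^2/2$ over its band, unit-variance white noise is flat at
$2/f_s$ and band power scales with bandwidth. Power features are stored as
`log10` absolute band power by default (`log10 = FALSE` to disable): whether
the original analysis used absolute or relative power and which transform is
unstated, and the log tames the strong right-skew that the multiplicative
envelope/subject-scale model produces.

**AEC connectivity.** Per epoch: zero-phase band-pass → optional pairwise
symmetric orthogonalisation → analytic-signal envelopes → Pearson
correlation of envelopes for every ROI pair; epoch (and direction) averages
are taken on the Fisher-z scale and back-transformed, so stored values are
correlations in $[-1, 1]$. Choices:

* Filters are zero-phase FFT masks with raised-cosine transitions
  (transition width 15% of the edge frequency, floored at 0.25 Hz). An IIR
  design is numerically fragile for a 1–3 Hz band at 600 Hz (normalised edge
  ~3·10⁻³); the spectral mask is exactly zero-phase, removes DC, and
  suppresses content one octave outside the passband far beyond 40 dB.
* Leakage correction defaults to ON, since zero-lag mixing is the dominant
  artifact of source reconstruction; the variant used in the original
  analysis is not part of the reproduced material, so both modes are
  provided. Orthogonalisation of channel $j$ on channel $i$ subtracts the
  full OLS fit, so a channel orthogonalised on itself is exactly zero and
  the residual has zero sample correlation with the regressor; a constant
  regressor leaves the target unchanged. Both directions are computed and
  z-averaged (the operation is not symmetric). The analytic signal is linear,
  so residual envelopes are obtained as $|A_j - b\,A_i|$ from the channels'
  analytic signals, which keeps the 4005-pair computation affordable.
* Envelopes are low-pass smoothed at `env_smooth = 1` Hz and decimated to
  about four samples per cutoff cycle before correlation (envelope dynamics
  are slow; this cuts cost). `env_smooth = NULL` correlates raw envelopes —
  the right choice when the quantity of interest is the sampling error of
  AEC itself, as in the independent-noise checks, because smoothing discards
  degrees of freedom that broadband envelopes do contain.
* Degenerate inputs: correlations of zero-variance envelopes are defined as
  0; correlations are clipped at |r| = 0.999999 before the z-transform.

Edges are vectorised in canonical row-major upper-triangle order
(`aec_<band>_<i>_<j>`, $i<j$, 1-based), 4005 edges for 90 regions, with a
lossless inverse.

## Univariate screening

The four-group location test defaults to one-way ANOVA (F), computed
vectorised across features and verified against `stats::oneway.test`;
Kruskal–Wallis is the nonparametric switch. The exact test of the original
analysis lives in unreproduced supplementary material, so both are provided
and the choice is logged in the result. Zero-variance features are degenerate
and reported with p = 1 plus a warning; a feature with zero within-group
variance but distinct group means is a maximal effect (F = ∞, p = 0), not a
degeneracy. FDR control is Benjamini–Hochberg step-up (`stats::p.adjust`),
error on non-finite input. The two-step reduction keeps features with raw
p < `alpha_raw` (default 0.05 — the reduction level is not stated in the
reproduced material) computed on training subjects only; passing the holdout
ids makes leakage a hard error, and an empty selection is reported, not
silently repaired. Z-scoring, two-way hierarchical clustering (subjects:
Euclidean/Ward; features: correlation distance/average linkage — dendrogram
figures in the source material do not state linkages) and PCA views operate
on training-fitted statistics throughout.

## CV-SVM-rRF-FS

For each of `n_folds = 10` stratified outer folds of the *training* data
(every fold keeps at least one subject per group, enforced):

1. optional two-step raw-p screen on the fold-training part only;
2. recursive RF elimination: drop the lowest-importance `drop_frac = 0.2`
   of remaining features per round (ties in impurity importance broken by
   fixed feature order, so the ranking is a total order), recording the
   classification error at each size; the returned subset is the smallest
   whose error is within one standard error of the minimum;
3. SVM tuned on the fold-training part, scored on the fold's held-out part
   (per-group one-vs-rest and four-class accuracy).

Consensus features are those selected in at least 50% of folds (the source
material says only "consensus features"; half of ten folds is the natural
majority reading and is configurable). The final SVM is trained on all
training subjects restricted to the consensus set.

Error estimate inside the elimination: the default is the forest's
out-of-bag error with a binomial standard error — the standard
RF-elimination practice and an order of magnitude cheaper than refitting at
4005-edge scale; `error_estimate = "cv"` switches to an explicit stratified
inner CV with the fold count of the `inner_folds` argument. Forests use 500
trees by default (stability at ~100 subjects), seeded and single-threaded
for bit-reproducibility.

SVM tuning: stratified inner CV over linear and RBF kernels, cost
$10^{-1}..10^2$, RBF $\gamma \in \{0.25, 1, 4\}/p$; classes weighted
inversely to group size (23–27 is mildly unbalanced); ties prefer linear
over RBF, then smaller cost, then smaller $\gamma$ (parsimony). Features are
standardised with training statistics stored in the bundle; prediction on a
subject lacking a declared feature is an error, never an imputation. An
empty consensus yields an explicit no-model outcome. One-vs-rest decision
scores aggregate the signed pairwise decision values of the multiclass SVM.

PLS-DA (three components, matching the three-component score views used for
inspection) re-fits the consensus features as an independent classifier;
its stratified-CV accuracy gets a label-permutation p, and p ≥ 0.05 raises
the "SVM-only" flag: the feature set does not generalise beyond the SVM.

## Evaluation and inference

* **Split**: stratified 85/15 with largest-remainder rounding per group
  (101 subjects → 86/15), at least one holdout subject per group. The
  training partition hash travels with every fitted object; holdout
  evaluation fails hard on any overlap or hash mismatch, and mutating
  holdout features can change only the evaluation report, never the
  selection or the model (asserted by test).
* **Per-group accuracy**: the binarised "group vs rest" percentage over all
  evaluated subjects; in CV, mean ± SD across folds (whether the reference
  SDs are across folds or resamplings is unstated; across folds is used and
  labelled).
* **AUC**: one-vs-rest Mann–Whitney area with midrank ties (pROC), verified
  against brute-force pair counting.
* **Permutation test**: $p = (1 + \#\{s_{perm} \ge s_{obs}\})/(1 + n_{perm})$,
  valid by construction. The statistic is the mean four-class CV accuracy of
  the selection engine re-run from scratch on the permuted labels — screening
  and selection are repeated per permutation, never reused. Because a full
  10-fold rRF-FS per permutation is prohibitive, the permutation closure runs
  the same engine at reduced fold and tree counts (`perm_folds = 3`,
  `perm_trees = 100` by default); calibration only requires the statistic to
  be a fixed function of the data, which it is. Defaults: 1000 permutations
  for final models, 99–200 at validation scale.

## Validation scales

The shipped checks run at documented desk scales: spectral and envelope
oracles on 10-s-epoch single subjects at 100–250 Hz; null calibration on 200
effect-free cohorts of 4 × 20 subjects (6 regions, alpha band, 99
permutations each); recovery on ten replicates of 4 × 20 subjects with 20
regions, three alpha-power effects of magnitude 2.0 and two alpha-edge
couplings of 0.6, each marking one group — one power marker per clinical
contrast plus edge markers whose removal leaves a group unidentified, so
selection must keep both feature families. `scripts/acceptance.R` reruns the
recovery conditions end to end and the 90-region edge-count identity from a
single seed.

## Known limitations

* The generator's oscillations are band-centre sinusoids; spectral shape
  within a band, 1/f-knee structure and burstiness are not modelled.
* No phase-based connectivity (PLV, wPLI) and no dynamic connectivity; AEC
  only, as in the analysis the package reimplements.
* Cross-frequency feature fusion is out of scope (a noted future direction),
  as are covariate adjustment and mixed models.
* The cohort container is a CSV-per-subject directory with a JSON manifest —
  adequate for the cohort sizes involved; a hierarchical binary container
  would be preferable for much larger studies.
* Holdout reports at n ≈ 15 have coarse accuracy granularity (1/15 ≈ 6.7
  percentage points); per-group one-vs-rest accuracies on such sets should
  be read with that resolution in mind.
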