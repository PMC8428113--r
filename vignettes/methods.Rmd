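---
title: "Methods: simulating and decoding synchronization-coded working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding synchronization-coded working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Auditory working memory (WM) must hold sound content — here, the velocity
of a "dynamic ripple" sound — across a silent delay. One influential idea
is that the maintained content is not (only) carried by sustained local
firing but by *patterns of interregional phase synchronization*: each
memorized item corresponds to a specific configuration of phase
relations between subregions of auditory cortex (STC) and frontoparietal
areas. If that is true, a classifier fed with connectivity features
should be able to read out which of several items is being maintained,
while local oscillatory *power* patterns at the same sites need not be
informative. A complementary idea is the "activity-silent" trace: content
held in synaptic states becomes momentarily visible in power patterns
when a task-irrelevant impulse sound pings the network.

`syncdecode` implements this analysis arc as a tested pipeline and — the
part that makes it testable — a synthetic-cohort generator in which the
ground truth is known exactly: which sub-region pairs are coupled, in
which band, with which condition-specific phase lags, which power
patterns appear after an impulse, and how strongly behavior is linked to
coupling fidelity. Every downstream claim (decoding above chance,
family-wise error control, parameter recovery) is then checkable against
what was planted.

## The generative model

Each subject contributes epoched time series for `N` sub-ROIs
(subdivisions of anatomical regions) at 500 Hz, in six stimulus classes.
A sub-ROI signal is the sum of:

1. **1/f background noise** (power spectral slope −1, unit SD by
   default), independent per sub-ROI and epoch. Source-level MEG noise
   is not white; a 1/f slope is the conventional first-order stand-in.
2. **Planted couplings.** A coupling is a band-limited complex driver
   `z(t)` (a sum of 3–12 random-phase complex exponentials spanning the
   band) shared by a seed and a target sub-ROI. The seed receives
   `A·Re(z)`; the target receives `A·Re(z·e^{−iφ})`, where the lag
   `φ ~ vonMises(Δφ_c, κ)` is drawn per epoch around the
   condition-specific mean lag `Δφ_c`. Condition-specific lags make the
   *imaginary coherence* of the pair class-informative while leaving
   band power identical across classes — exactly the dissociation the
   analysis is designed to detect. κ (dimensionless concentration)
   controls coupling reliability: κ = 0 is no coupling, κ ≳ 10 is a
   strong regime in which a planted pair is recovered reliably
   (parameter-recovery tests use κ = 20), κ = ∞ gives `ImCoh =
   sin(Δφ)` exactly in the noiseless limit.
3. **Impulse power patterns** (maintenance epochs only). Half of the
   epochs are flagged as impulse trials; from the impulse latency
   (2.5 s into the delay) onward, a condition-specific set of
   `(sub-ROI, band, gain)` perturbations adds band-limited signal. This
   emulates the content-specific readout that an impulse sound elicits
   from activity-silent traces: power decoding works on impulse trials
   and stays at chance on the others.
4. **Sign flips.** Each subject × sub-ROI series is multiplied by ±1
   with probability 0.5, emulating the surface-normal sign ambiguity of
   source-space data. An optional leave-one-out correlation alignment
   (`align_signs()`) mirrors the conventional sign-alignment step; it
   needs mutually coherent sub-ROIs to work, which is also its known
   real-data limitation.

Per-subject **coupling fidelity** is drawn uniform on [0.6, 1] and
scales every coupling amplitude; behavior is `clip(intercept + slope ×
fidelity + noise, 0, 1)` with defaults (0.6, 0.3, SD 0.08) chosen so the
cohort mean proportion correct is 0.84 with an SD near 0.1, matching
typical performance in this paradigm. Cohort sizes default to the study
design: 17 subjects, 58 maintenance / 115 encoding epochs per condition
(optionally with SD 7/15 across subjects, which the epoch-equalization
step then removes), 2.5 s maintenance epochs from the memory cue,
encoding epochs from −0.5 to 1 s around sound onset.

All randomness flows from one master seed through
`derive_seed(master, tag, ...)`, a multiplicative hash onto
[1, 2³¹−2]; every stage (subject draws, per-epoch noise, quarter
partitions, decoder splits, permutations) owns a tagged sub-stream, so
runs are bit-reproducible and stages can be re-run in isolation.

## Stimuli and psychophysics

Ripple sounds superimpose log-spaced sinusoidal carriers (inclusive
grid, 20/octave from 200 to 1600 Hz → 61 carriers) with envelope
`s(g,t) = D₀ + D·cos(2π(ωt + Ωg) + ψ)`, `g = log2(f/f₀)`. The
just-noticeable difference in log2 ripple velocity is estimated by a
2-down/1-up staircase, which converges on the 70.7 %-correct point of
the psychometric function. The step schedule is not uniquely
standard, so the package fixes one: 8 reversals, estimate from the last
6, step halved after each of the first 2 reversals. A chance-level
observer drives the staircase to its upper bound and is flagged rather
than silently averaged.

## Spectral and connectivity estimation

**Morlet decomposition.** Each epoch is convolved with 7-cycle complex
Morlet wavelets, unit L2 norm (the normalization is not standardized
across packages; unit energy makes coefficient magnitudes comparable
across frequencies up to a known 1/f energy trend). Epochs are
zero-padded, and samples within half the wavelet support
(`n_cycles/(2f)` s) of either edge are masked invalid; window averages
exclude masked bins, which a poisoning test enforces.

**Frequency grid.** Five canonical bands (theta 3–7, alpha 8–12, beta
13–30, low gamma 31–60, high gamma 61–120 Hz) with log-spaced bins per
band: 5, 5, 18, 20, 21. The per-band counts are taken as authoritative
because a single global 73-bin log grid cannot reproduce them (they sum
to 69); this is the one place where the source design admits two
readings, and the per-band counts are the internally consistent one.

**Imaginary coherence.** `ImCoh(f,t) = Im[⟨SxS̄y⟩ₖ / √(⟨|Sx|²⟩ₖ⟨|Sy|²⟩ₖ)]`,
epoch-averaged at each bin, then averaged (signed, not rectified) over
the band's bins and the window's valid samples. Signed averaging is a
deliberate choice: the classifier can exploit the sign, and rectifying
would discard the lag direction. The sign convention is positive when
the second signal lags the first. Epochs are partitioned per condition
into 4 disjoint, equal, seeded quarters (remainder dropped); ImCoh per
quarter gives the 4 subsample rows per subject × condition. Windows are
half-open `[tmin, tmax)`: early 0.5–1.25 s, late 1.25–2 s (maintenance),
0–1 s (encoding).

**Multitaper power.** Single-epoch DPSS multitaper spectra (NW = 4, 7
tapers by default), one-sided density normalization so the spectrum
integrates to the variance. The Slepian tapers are computed from the
standard symmetric tridiagonal eigenproblem; above 1024 samples they
are computed on a 1024-point grid, spline-interpolated, and
re-orthonormalized (DPSS are smooth, so the interpolation error is far
below estimation noise).

## Decoding

All decoders z-score features with training-side statistics — the SVM
cost C = 1 is scale-sensitive and ImCoh features are small numbers —
and all splits are seeded.

* **Cross-subject connectivity decoding**: rows are subject × condition
  × subsample; 100 repeated stratified 75/25 row splits; linear SVM,
  C = 1. Row-level stratification is the default split unit because it
  reproduces the design's 306/102 train/test bookkeeping exactly
  (75 % of 17 subjects is not an integer); a subject-level scheme is
  provided for strict subject independence, and a test asserts no
  subject straddles a split under it. Multiclass is one-vs-one with
  voting; vote ties resolve to the lowest class index (the libsvm
  convention, stated here because library defaults differ).
* **Power-pattern decoding**: within-subject, RBF kernel with
  `gamma = 1/(H·var(training matrix))`, 4-fold CV over the subsamples
  (train 18 / test 6 rows per fold), accuracy averaged over folds then
  subjects.
* **Temporal-PCA decoding**: 0.5–12 Hz 4th-order Butterworth zero-phase
  band-pass, PCA fit on training folds only, at most 100 components,
  RBF SVM, stratified 10-fold CV.
* **Encoding→maintenance generalization**: train on encoding features,
  test on maintenance features, per subject, 4-fold over subsamples.
* **Behavioral SVR**: rows are subject × subsample (68 for 17
  subjects); per fold, PCA to 95 % variance on the 51 training rows,
  test rows projected with training loadings, linear SVR with C = 1.
  The SVR epsilon is not part of the published design; the default is
  0.1 × the training-behavior SD. RMSE is averaged over the 4 folds.

## Inference

* **Label-permutation nulls** shuffle the training labels within each
  split and score against true test labels (the alternative — permuting
  all labels — mixes test-side noise into the null; the training-side
  reading is implemented). Permutations are unique; each uses a reduced
  number of splits (10 of the 100 by default) for tractability, which
  widens the null slightly and is therefore conservative.
* **Max-stat correction** pools the per-permutation maximum across all
  tests (60 in the full design); `p = (1 + #exceedances)/(1 + n_perm)`,
  which can never return 0 and makes an observed value above the whole
  pooled null land at `1/(n_perm+1)`. Pooled p-values are monotone in
  the observed statistic and never smaller than per-test p-values.
* **Impulse contrast**: linear mixed model on chance-rescaled
  accuracies with subject random intercepts and fixed effects of
  impulse presence and log2 band center frequency; Bonferroni across 13
  statistics. Degrees of freedom use the residual convention (n − p),
  with Satterthwaite available; on balanced designs the fixed-effect
  estimates coincide with OLS, which a test asserts. A constant
  response (exact chance everywhere) short-circuits to a degenerate
  report instead of a singular fit. Stepwise growth by likelihood-ratio
  tests is available; the default is the full main-effects model.
* **Behavioral min-RMSE null**: behavior shuffled within each
  subsample; per permutation the minimum RMSE across all tests and both
  windows enters the pooled null; a test is significant only if its
  RMSE beats the 2.5th percentile in *both* windows.
* **Power variation**: one-sample t per band × window with sign-flip
  permutation (500 flips) and max-|t| pooling. This deliberately
  replaces threshold-free cluster enhancement: with five discrete bands
  and no cortical adjacency in scope, cluster enhancement has nothing
  to enhance, and band-level max-stat control is the faithful analogue.
  Zero-variance, zero-mean inputs report p = 1 with a degenerate flag.

## Calibration and recovery experiments

The package ships the calibration experiments as functions so they are
reproducible objects, not one-off scripts:
`maxstat_fwer_calibration()` estimates the family-wise false-positive
rate of the max-stat procedure on fully null feature-level replicates
(the null of connectivity features is label-exchangeable, so Gaussian
features are the exact null of the decoder+permutation machinery);
`svr_fwer_calibration()` does the same for the both-windows min-RMSE
rule.

The test suite runs these at documented reduced sizes chosen once:

* chance calibration: 20 null cohorts, 8 subjects, 2 sub-ROIs per ROI,
  40 epochs/condition, 2.5 s epochs at 500 Hz, one bin per band —
  pooled decoding accuracy within 0.02 of 1/6;
* FWER: 200 replicates × 4 tests × 100 permutations (max-stat);
  80 replicates × 2 tests × 50 permutations (SVR rule);
* recovery: 50 replicates, 6 subjects, 16 epochs/condition, 1.5 s
  epochs at 250 Hz, 2 target ROIs × 2 bands, one planted alpha coupling
  (κ = 20, amplitude 2 against unit noise) — recovered as the uniquely
  significant test, with power decoding on the same phase-only cohorts
  at chance;
* impulse contrast: 100 planted + 80 null replicates, 5 subjects, 12
  epochs/condition, 4 s epochs at 250 Hz, impulse at 2.5 s, decoding
  from the final 1.5 s.

The recovery experiment generates **sign-aligned** cohorts
(`sign_flip_prob = 0`). This is deliberate, not a convenience: in the
emulated pipeline, waveform signs are fixed from surface-normal anatomy
*before* connectivity estimation, so the connectivity features never see
random signs. Under random unaligned flips, a flipped subject's
signed-ImCoh pattern for class c coincides with the pattern of another
class (the condition lags are symmetric around zero), so cross-subject
decoding is confounded *by construction* — a property of unaligned
signed features, not of the estimator or the inference machinery. The
data-driven `align_signs()` step cannot substitute for anatomical
alignment here because it only resolves signs within a ROI, while the
pair sign depends on the across-ROI sign product.

The reduced sampling rates (250 Hz) and subject counts in the recovery
and impulse designs keep hundreds of replicates affordable while leaving
every band below Nyquist and the estimators unchanged.

## What the generator does and does not emulate

It emulates: condition-specific interregional phase coupling with
per-epoch reliability, 1/f background, sign ambiguity, epoch-count
variability, impulse-dependent power patterns, behavior linked to
coupling fidelity. It does **not** emulate: cortical geometry, field
spread/source leakage (ImCoh's raison d'être — zero-lag leakage — is
absent by construction, so the simulation cannot probe ImCoh's leakage
robustness, only its statistical behavior), realistic artifact
structure, or nonstationarities beyond the impulse. Passing tests
therefore validate the *pipeline's statistics* (calibration, recovery,
bookkeeping), not claims about real MEG data.

## Known limitations

* Ridge regularization aside, C = 1 with z-scored features is a fixed
  operating point; no hyperparameter search is in scope by design.
* The sign-alignment heuristic requires coherent sub-ROIs and can lock
  onto a minority sign in adversarial configurations.
* Permutation nulls with reduced splits-per-permutation trade a
  slightly wider null for speed; the full-splits null is available by
  configuration.
* `run_experiment()` at the full default design (17 subjects × 58
  epochs × 34 sub-ROIs × 69 bins) is hours of compute; the
  configuration schema exists precisely so that scaled designs are
  first-class rather than ad hoc edits.
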