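---
title: "Detecting aortic stenosis from chest-worn inertial signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aortic stenosis from chest-worn inertial signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiomech)
```

## The measurement problem

Aortic stenosis narrows the aortic valve opening. The left ventricle
compensates by contracting harder against a higher afterload, which changes
the mechanical signature of each heartbeat: isovolumetric phases lengthen,
ejection dynamics change, and the chest wall's micro-vibrations change with
them. A sternum-mounted IMU captures those vibrations as the
seismocardiogram (SCG, linear acceleration) and gyrocardiogram (GCG, angular
rate) on three axes each, sampled synchronously (256 Hz is typical). The
attraction of this modality is that it needs no ECG, no cuff, and no
clinician — but it demands careful signal processing, because the signals
are weak, quasi-periodic, and contaminated by motion.

`cardiomech` implements the full chain: artifact-robust preprocessing,
reference-free beat detection, GCG fiducial annotation, a
timing/variability/spectral feature space, classifier training with
optimized filter parameters, and exact Shapley attribution. This vignette
records the model choices, the tunable parameters, and the reasoning behind
every decision the design left open.

## Preprocessing

Channels are band-pass filtered with 4th-order Butterworth designs — 1–45 Hz
for SCG, 1–20 Hz for GCG, the bands that retain each modality's cardiac
content while rejecting baseline wander. Filtering is applied
forward-backward (zero phase): fiducial timing is the core measurand, and a
causal filter's group delay would bias every interval. The price is that the
effective attenuation order doubles; we document rather than compensate
this, since all signals pass through the same filters.

Motion artifacts are masked by a sliding RMS filter of length `M`
(`rms_window_ms`, literature default 500 ms) applied to the per-sample RMS
resultant of all six band-passed channels; samples where it exceeds twice
its median are removed, on all channels jointly. Two details are
reconstructions, because the procedure is usually described per recording
without specifying them:

* **Which signal feeds the RMS filter.** We use the joint six-axis
  resultant, so the mask is identical across channels and the axes stay
  synchronized. A per-channel mask would desynchronize the fusion step.
* **The threshold tie.** Samples exactly at twice the median are kept; the
  all-zero recording then degenerates gracefully (threshold 0, everything
  kept).

Clean segments are never spliced: chunking tiles `N`-second windows
(`chunk_s`, default 10 s; 50% overlap for the 4-class severity task) from
the start of each maximal clean run, discarding trailing partial windows and
runs shorter than `N`. Tiling anchored at the run start is our choice; no
anchoring rule is canonical.

## Beat detection

Each modality's three axes are fused by the per-sample root mean square,
giving a linear and an angular resultant. Each resultant is enveloped by the
magnitude of its Hilbert analytic signal and smoothed by a zero-phase
2nd-order 2-Hz low-pass. The two envelopes are then **normalized by their own
medians before summation**: they carry different physical units (m/s² vs
deg/s), and an unnormalized sum would be dominated by whichever modality's
numbers happen to be larger. The median was chosen over the maximum because
it is insensitive to a single residual artifact spike.

Peaks of the summed envelope are picked by an adaptive dual-threshold
detector in the Pan–Tompkins tradition, with the classical constants
(exponential level updates with weight 0.125, decision threshold
`NPK + 0.25 (SPK − NPK)`, 300-ms refractory period, search-back at 1.66
times the running beat interval accepting candidates above half threshold).
The method is standard for QRS detection; the constants are the classical
ones because nothing in this application argues for different values, and
all are config-exposed. Each fused peak is finally refined per axis to the
signed local maximum of the band-passed axis signal within ±25 ms — signed,
not absolute, because the annotated J peak is a positive deflection by
convention.

Because the envelopes are normalized, detection is exactly invariant to
global amplitude scaling of a chunk — a property the tests assert.

## Fiducial annotation and the P/MA features

Annotation runs on the GCG X and Y axes after a further 1–10 Hz band-pass.
The search rules are reconstructions (the fiducial definitions live in prior
art that gives pictures more than procedures), with all windows
config-exposed:

* **J**: the refined per-axis peak.
* **I**: nearest local minimum within 150 ms before J; **K**: nearest local
  minimum within 150 ms after J.
* **L**: first local maximum within 200 ms after K; **A**: last local
  maximum within 200 ms before I.
* **P**: the sample of maximum |first difference| × fs within the beat
  window; **MA** is that maximum. Since the gyroscope measures angular
  *rate*, the first difference is angular *acceleration*, which is what the
  feature's name says it measures; the magnitude is used so that axis
  polarity conventions cannot flip the feature.

The beat window spans from 40% of the local inter-beat interval before J to
60% after (the first beat of a chunk borrows the following interval), so
windows scale with heart rate and neighboring beats stay excluded. A beat
whose required extrema are missing, or whose times violate A < I < J < K < L,
is flagged invalid and excluded — never imputed. A chunk with fewer than
half its beats valid is dropped entirely.

Derived intervals: IVCT = J−I, LVET = K−J, IVRT = L−K, plus L−I, L−J, K−I,
P−I, P−J, K−P, L−P and MA itself — 11 per-beat parameters.

## The feature space

Per scope (one chunk, or one subject pooling all its valid beats), each of
the 11 parameters yields mean, median, standard deviation, skewness,
kurtosis, entropy, min, max: 88 GCG features. The NN series (differences of
consecutive valid J-peak times on GCG-Y, dropped where a beat is invalid or
a chunk boundary intervenes) yields 15 time-domain HRV features. Six axes ×
five Welch band powers give 30 frequency-domain features. Chunk-level
matrices carry 88 + 15 = 103 columns — chunks are too short for the spectral
bands — and subject-level matrices carry all 133. (The source literature
quotes a 123-feature subject-level total alongside block sizes that sum to
133; we follow the blocks.)

Numerical conventions, fixed so every statistic has a single unambiguous
oracle:

* Standard deviations divide by *n* (population form) everywhere, matching
  the published Poincaré formulas, which carry no sample correction.
* Skewness is m₃/m₂^1.5 and kurtosis m₄/m₂² (a normal scores 3; not
  excess-adjusted); degenerate zero-variance inputs score 0.
* **SD1/SD2 as printed.** The published SD1 is std(|ΔNN|/√2) — with the
  absolute value — and the published SD2 subtracts the constant 2·AVNN
  inside the same std. A standard deviation is shift-invariant, so SD2 as
  printed is *identically* SD1, and their ratio is 1 wherever defined. We
  implement the formulas verbatim (the tests assert the identity), and
  provide `sd2_convention = "conventional"` for the usual long-axis
  statistic std((NNᵢ + NNᵢ₊₁)/√2) for users who want the conventional
  Poincaré pair.
* **pNN50** divides by the total number of NN intervals, following the
  published wording; `pnn50_denominator = "diffs"` switches to the
  conventional denominator.
* **Entropies.** ENN is the Shannon entropy (bits) of the NN histogram at
  fixed bin width 1000/128 ms ≈ 7.8 ms (one sample at 128 Hz — a natural
  quantum for interval data and stable across scopes). SENN is defined as
  the self-information shared by consecutive intervals — the mutual
  information I(NNᵢ₊₁; NNᵢ) — and CENN as the conditional entropy
  H(NNᵢ₊₁ | NNᵢ), both from the same binned joint distribution; the
  decomposition H(marginal) = SENN + CENN then holds exactly and is
  asserted in the tests. These operational definitions are ours; the names
  are used in the HRV literature without formulas.
* **Spectral features** are computed on the raw (pre-band-pass) signal over
  artifact-free runs, because a 1-Hz high-pass would annihilate all three
  HRV bands (VLF 0.0033–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz). Welch
  estimation uses 120-s Hann segments at 50% overlap (config-exposed), the
  shortest segment that resolves the VLF band edge; runs shorter than two
  segments cannot support the estimate and are flagged missing, resolved by
  the explicit imputation policy (`impute_policy`, default per-column
  median). With the generator's default artifact rate, a 300-s recording
  often lacks a 240-s clean run, so subject-level discrimination rests on
  the GCG and time-HRV blocks — consistent with the ablation finding that
  GCG timing features dominate this problem.

## Modeling

The 80/20 train/test split is stratified by class; at chunk level whole
subjects are assigned to one side, because chunks of one subject are highly
correlated and splitting them across sides would leak identity. Ten-fold CV
drives a grid search per classifier family — decision tree (`rpart`), random
forest (`ranger`), gradient-boosted trees (`xgboost`), SVM (`e1071`) — over
depth/leaf/split/feature-fraction/criterion dimensions, learning rate for
boosting, cost/kernel/coefficient for the SVM, and class weights (inverse
class frequency as the "balanced" grid value) for every family. Selection
maximizes mean CV F1; at subject level the folds partition subjects, at
chunk level they partition chunks. Multi-class (severity) metrics are
macro-averaged, the conservative choice when classes are imbalanced; the
averaging is config-free but trivially changed at the metrics layer.

### Filter optimization

The RMS window `M` and chunk length `N` interact with everything downstream,
so they are optimized jointly: maximize mean 10-fold CV F1 of features
rebuilt from scratch at each probe, over M ∈ [100, 2000] ms, N ∈ [2, 25] s,
using training recordings only. The surrogate is a Gaussian process with a
Matérn-5/2 kernel on the unit-scaled box (lengthscale 0.3, nugget 10⁻⁶),
started from an 8-point Latin hypercube and driven by expected improvement
over a 512-point random candidate pool, default budget 40 evaluations — all
config-exposed, all seeded, and the entire trace is returned. Probe points
whose chain yields no usable chunks score 0 rather than erroring, so the
optimizer can explore aggressive (M, N) corners safely. An exhaustive
`sweep_filter_params()` over the same objective supports
performance-versus-M/N curves and serves as the oracle in the tests: the
optimizer must come within 0.02 F1 of a 5×5 grid scan.

### Shapley attribution

Feature scores use the exact enumeration of averaged marginal F1
contributions over all 2ⁿ subsets (guarded at n ≤ 15), with the value of the
empty set defined as 0 — an untrained model has no F1, and with this anchor
the efficiency axiom reads Σαᵢ = F1(full set). Hyperparameters are fixed
once on the full feature set rather than re-tuned per subset; re-tuning
inside 2ⁿ retrainings would be computationally indefensible and would
confound attribution with tuning noise. Beyond 15 features a
permutation-sampling estimator with per-feature Monte-Carlo standard errors
takes over; the tests require it to sit within 3 SE of the exact scores.
The comparison ranking uses each family's native importance (split gain for
boosted trees, impurity for forests) through the same interface.

## The synthetic generator

No public AS cohort with raw IMU signals exists, so the package ships a
generator that emulates exactly the signal properties the pipeline assumes,
with complete ground truth:

* **Beat template**: a sum of Gabor-like lobes (Gaussian envelope × cosine
  carrier, σ = 25 ms, 4 Hz) centred at the fiducials A = −210, I = −90,
  J = 0, K = +120, L = +240 ms with signs matching their extremum types.
  Both envelope and carrier have zero slope at the centre, so each lobe's
  extremum sits analytically at its fiducial time; σ and the carrier keep
  the template essentially band-limited below 10 Hz so the annotation
  filter moves extrema by at most ~1 sample. Only GCG X/Y carry the full
  annotated complex; the other axes carry reduced templates.
* **Disease encoding**: AS classes lengthen IVRT (L shifted +15/+35/+60 ms
  for mild/moderate/severe) and scale the beat template uniformly by
  1.3/1.6/2.0, which scales the maximum first difference — MA — by exactly
  the same factor while leaving the relative lobe geometry, and hence the
  annotation, identical across classes. This mirrors the direction of the
  clinically reported effects (longer relaxation, stronger maximum
  acceleration) without claiming clinical magnitudes. (Scaling only the J
  lobe was rejected: its filter ripple interferes with the L search and
  distorts IVRT in the scaled classes.)
* **Rhythm**: AR(1) inter-beat intervals, NNₜ₊₁ = μ + a(NNₜ − μ) + ε, with
  innovation variance chosen so the stationary SD equals `sdnn_target`
  (default 50 ms, a = 0.3, μ = 800 ms) — stationary, controllable in closed
  form, and feasibility-checked against the 300-ms refractory floor.
* **Noise and artifacts**: white noise at `noise_sd` (default 0.1) times the
  template RMS per channel; motion bursts as a Poisson process (default 0.5
  per minute) of 0.5–2 s amplified-noise segments on all channels at
  `artifact_gain` (default 8) times the template RMS, matching the
  removal model of the RMS mask.
* **Seeding**: one master seed; per-subject seeds derive deterministically
  from it, so cohorts reproduce byte for byte, and channel noise is drawn
  after the rhythm and artifact streams so that morphology-only config
  changes leave the rhythm identical.

What the generator does **not** emulate — respiration modulation, posture
changes, sensor drift, inter-subject template variability beyond the class
offsets, valve sounds — bounds what passing tests mean: they certify the
pipeline's correctness and its recovery of known ground truth, not clinical
performance. The cohort-level classification checks in particular are
*sanity ceilings* (the classes are separable by construction), not accuracy
claims about patients.

## Problem sizes used in the checks

The test suite and the acceptance script run, per the package's own choice
of scale: a 60-s single-subject recording for detection/annotation recovery
(≈68 beats); a 13.5-minute recording (~1000 beats) for SDNN recovery, where
the sampling error of a sample SD at 300 beats (≈2.4 ms at a 50-ms target)
would otherwise be of the same order as the 5% acceptance band; a
12-subject, 300-s-per-subject healthy-vs-severe cohort for end-to-end
classification; and a 4-subject, 120-s cohort for the optimizer-versus-grid
consistency check, whose conclusion (the optimizer matches an exhaustive
scan of the same objective) does not depend on cohort size.

## Known limitations

* The I/J/K/L/A search rules and the P-as-derivative-extremum choice are
  reconstructions of under-specified operational definitions; both are
  config-exposed and flagged here.
* The spectral HRV block measures band power of the *signals*, not of the
  NN tachogram; its physiological interpretation as "HRV" is inherited
  from the source methodology, not endorsed by it.
* Chunk-level CV folds partition chunks, not subjects (the train/test split
  does partition subjects), mirroring the published protocol; fold-level
  subject leakage inside CV is therefore possible by design at chunk level.
* SD2 as printed being identical to SD1 means the published 15-feature
  time-HRV block effectively contains one duplicated dispersion measure;
  the conventional alternative is one config switch away.
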