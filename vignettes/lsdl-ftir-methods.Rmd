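---
title: "Methods: amplitude-band decomposition of FTIR biofluid spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplitude-band decomposition of FTIR biofluid spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lsdlspectra)
```

## The model and its assumptions

An ATR-FTIR absorbance spectrum is treated as a 1-D series indexed by
array position on a fixed descending wavenumber grid; the "time" index
of every sequential feature is the array index, not the cm⁻¹ value.
The working hypothesis of amplitude-band decomposition is that class
information (here: cancer vs noncancer, or low- vs high-grade disease)
concentrates in one *amplitude* region of the signal, while the rest of
the spectrum contributes mostly subject-specific nuisance variability.

The linear series decomposition learner (LSDL) operationalizes this:
a threshold scheme (direction ∈ {upper, lower}, level t) reduces each
spectrum to the sub-signal of samples on one side of t, treated
downstream as a contiguous series (gaps closed — the decomposition
emits sub-signals, not masked series, and sequential features need
adjacency). An embedded search picks the scheme whose sub-signals
maximize class separability, and that single scheme is then applied to
every signal from the same source.

### The performance index

Candidate schemes are scored with the normalized Euclidean distance

$$J = \mathrm{ED}(p, q) / \sigma_m ,$$

with these resolved conventions (the defining equations leave several
choices open):

* **Dimensionality.** ED is the Euclidean distance generalized to all
  $N_w$ feature dimensions (the printed 2-D form is read as the
  two-coordinate special case).
* **Standardization.** Each feature column is z-scored on the pooled
  two-class sample (mean 0, unit variance, $n-1$ convention) *before*
  centroids are taken. Without this, large-magnitude features (e.g.
  SSC counts vs AR coefficients) dominate ED and "normalized" would be
  vacuous; with it, J is invariant to per-feature rescaling.
* **σ.** The σ of the index is the per-feature standard deviation over
  the pooled sample, and $\sigma_m$ is the mean of those over features.
  After pooled z-scoring $\sigma_m = 1$ up to floating point, so J
  reduces to the standardized centroid distance; the full formula chain
  is kept so the convention is explicit and testable (a 1-D hand case
  — class A = {0, 0}, class B = {2, 2}, pooled sd 1.1547, J = 1.7321 —
  is frozen in the tests, alongside a 100-matrix brute-force oracle at
  1e-10).
* **Degeneracy.** A constant feature column (sd = 0) or a non-finite
  feature value makes the candidate "n/a" rather than erroring the
  search.

### The search schedule

No candidate-level schedule is canonical, so the package uses a
deterministic coarse-to-fine grid: iteration 1 scans 16 equally spaced
levels across the pooled amplitude range per direction; each later
iteration re-scans 16 levels on an interval of half the previous width
centered on the direction's incumbent best level (4 iterations by
default). Candidates leaving any training signal with fewer than
`min_samples` retained points are recorded "n/a" with a reason —
`min_samples = 8` is the smallest count at which the AR(4) and
SampEn(m = 2) members of the battery are computable. Ties in J break
toward the lower iteration, then toward the upper direction. The
result keeps the full candidate table plus the two-row Upper/Lower ×
iteration summary table with `n/a` literals.

Concatenated datasets are never given their own search: each origin
subset is decomposed with its own learned parameters.

## The feature battery

Twelve features per signal: MAV, WL, SSC, ZC, 4thAR, SampEN, Ceps,
MFL, HFD, DFA, MF, SP. Conventions that needed fixing:

* **Amplitude gate.** The battery's electromyography heritage states a
  "1 µv" threshold; absorbance is unitless, so the gate is 1e-6 in
  native a.u., applied to SSC and ZC only. It is configurable.
* **Peak rule.** The local-maximum rule for SP is
  $x_i \ge x_{i-1}$ and $x_i > x_{i+1}$ (the final sample of a plateau
  counts once) — the minimal completion of a typographically corrupted
  printed definition.
* **AR convention.** The order-4 fit is Burg's lattice (implemented
  directly; verified coefficient-for-coefficient against
  `stats::ar.burg`), stored in the polynomial convention
  $A(z) = 1 + a_1 z^{-1} + \dots + a_4 z^{-4}$ (so $a_i = -\phi_i$ for
  a forecast model $x_t = \sum_i \phi_i x_{t-i} + e_t$). "4thAR" is
  $a_4$; "Ceps" is the first AR-cepstrum coefficient $c_1 = -a_1$
  (index configurable).
* **SampEn.** Richman–Moorman counting: pairs $i < j \le n - m$,
  Chebyshev distance ≤ r, self-matches excluded, $r = 0.2\,\mathrm{sd}$
  of the *analyzed* (sub-)signal — sub-signals have their own scale.
  The O(n²) count is C code (it sits in the search hot loop); it is
  checked exactly against an R brute-force oracle. A/B = 0 yields an
  Inf/NA sentinel, not an error.
* **HFD.** Higuchi's construction with kmax = 8, capped adaptively at
  ⌊n/2⌋ so the reduced battery stays computable on `min_samples`-length
  sub-signals; the standalone function keeps the strict
  n ≥ 2·kmax precondition.
* **Degenerate inputs** (constant series, zero power) become NA
  sentinels carried in the feature vector's `missing` attribute;
  too-short inputs raise an error naming the failing feature.

After decomposition, ZC, DFA and MF are dropped (9 features): an upper
sub-signal is strictly positive (ZC ≡ 0) and too short for stable
DFA/MF scaling estimates — they are redundant post-LSDL. ZC is kept in
the raw-side battery so the drop rule is meaningful.

## Balancing and evaluation

SMOTE interpolates synthetic minority rows between a real row and one
of its k = 5 nearest same-class neighbours in *feature* space (the
interpolation is defined there, and classifiers consume features).
Targets are explicit: majority-size for the cancer/no-cancer exercise
(31/22 → 62), 20 per class for the grade exercise (9/13 → 40 — the
printed totals imply both classes were raised past the majority size).

Two placements are supported and logged loudly:

* **Protocol-faithful (default):** SMOTE on the whole table before
  cross-validation. This matches the emulated workflow but leaks —
  a synthetic row's parents usually sit in the training folds. A
  dedicated test measures the effect: at a *null* class effect the
  leaky placement inflates, e.g., 1-NN accuracy well above chance,
  while the fold-internal placement stays at chance.
* **`leakage_safe`:** SMOTE re-run inside each training fold; test
  folds contain only real rows. The null-calibration acceptance
  criterion runs in this mode, because a calibration check needs the
  unbiased instrument; the directional raw-vs-decomposed comparison
  keeps the protocol-faithful placement. In this mode the fold count
  is capped at the smallest real class (the grade cohort has only 9
  real low-grade subjects).

The nine models use fixed, documented hyperparameters instead of
interactive tuning: CART decision tree (Gini, depth ≤ 8), LDA, QDA,
1-NN (Euclidean; its AUC score is the nearest-negative minus
nearest-positive distance margin), four SVMs (C = 1, kernels linear /
(1 + x·z)² / (1 + x·z)³ / RBF with scale √P/4 — the conventional
"fine" setting; dual solved with `quadprog` plus a 1e-8 ridge), and
binomial-GLM logistic regression. Features are z-scored with
training-fold statistics. Metrics come from the pooled out-of-fold
confusion matrix (single-matrix style, not fold averages); AUC is the
rank/trapezoidal area on pooled scores; table cells are percent,
rounded half-away-from-zero, with unrounded values retained in the
machine output. A model that fails on any fold (e.g. QDA on a singular
class covariance) contributes an `n/a` row with the failure reason.
Fold assignment is stratified and depends only on (seed, labels, n).

## What the synthetic generator emulates — and what it does not

The cohort structure is the emulated study's: 31 noncancer + 22 cancer
subjects, Gleason split 4 (GS < 7, realized as GS 6) / 5 (GS = 7) /
13 (GS > 7, cycled over 8–10); per subject, three acquisitions whose
pointwise mean forms dataset 1 and whose first forms dataset 2;
acquisition noise sd 0.05 a.u.; class effect size 0.5 a.u. The
spectral range and resolution were never stated, so the grid is
configurable with a 4000–650 cm⁻¹ / 2 cm⁻¹ default.

A spectrum is a sum of Gaussian bands at canonical biofluid positions
(amide A ~3300, CH stretch ~2925, amide I ~1650, amide II ~1540,
~1400, carbohydrate ~1080 cm⁻¹ — scaffolding, not biology), a linear
per-subject baseline, and white acquisition noise. The positive class
gains an elevation-plus-narrow-sub-bands distortion (period 20 cm⁻¹,
subject-random phase) applied only where the curve exceeds the
affected band's floor (2.0 a.u.; onset ramp of 0.04 a.u. centered on
the floor), so the class difference is confined to the amplitude band
by construction and the band floor is the recoverable planted
threshold.

Three nuisance components were each added because, measured during
development, threshold recovery fails for a specific reason without
them; their parameters were then frozen:

* **Between-subject band-amplitude variability** (log-normal CV 0.1,
  typical of biofluid cohorts) and **broad tall bands** (200+ grid
  points above the floor): without enough above-floor support, feature
  estimates on boundary sub-signals are noisy and the J optimum drifts
  below the floor, where extra points stabilize estimates.
* **Fingerprint texture** — 30 narrow (σ = 8 cm⁻¹) bands over
  1800–950 cm⁻¹, each present in a random ~60 % of subjects with
  random amplitude and ±8 cm⁻¹ position jitter, capped 0.1 a.u. below
  the floor: compositional subject variability that makes sweeping
  sub-floor points into the sub-signal costly for J. Real fingerprint
  regions are exactly this kind of dense, subject-variable band forest.
* **A broad shoulder band** (2250 cm⁻¹, σ = 180 cm⁻¹) whose
  subject-variable top spans 1.4–1.95 a.u.: it populates the
  amplitudes immediately below the floor, so lowering the threshold
  below the band instantly admits a large subject-specific point mass
  — the dilution penalty that pins the optimum *at* the boundary
  rather than slightly under it.

A green recovery test therefore establishes that the search finds a
genuinely planted amplitude boundary under realistic subject
variability — not that real urine spectra behave this way. The
generator does not model Mie scattering, water-vapor lines, atmospheric
or baseline artifacts beyond a linear drift, detector saturation, or
any actual EV biochemistry; effect sizes are free parameters of the
simulation, not claims about urine chemistry. The motivating study's
numeric result tables were computed on patient data that is not
publicly deposited, so those cells are not reproduction targets; the
package reproduces the protocol's *construction counts* exactly and
its central qualitative claim (decomposition improves cross-validated
accuracy) directionally.

## Numerical choices and degenerate inputs

* One master seed derives all stage seeds (cohort, SMOTE, folds,
  permutations) via a fixed affine map kept below 2³¹.
* J ties break toward the lower iteration, then the upper direction.
* The SVM dual adds a 1e-8 diagonal ridge; the bias averages over
  margin support vectors (all support vectors if none are strictly
  inside the box).
* Percent metrics round half-away-from-zero for display; unrounded
  values travel alongside.
* Signals that retain fewer than `min_samples` points under a learned
  scheme are flagged, excluded downstream, and counted in a warning.
* The permutation null for the search re-uses the per-candidate
  feature cache (features do not depend on labels) and judges
  significance on the max-J statistic over the *fixed iteration-1*
  candidate grid, which controls the family-wise error over the
  scanned levels. Later iterations place their levels adaptively
  around the observed optimum, so maxima over them are not
  exchangeable with permuted maxima and are excluded. A single
  α = 0.05 check still rejects 5 % of true nulls by design, so the
  calibration test asserts the rejection *rate* across null seeds, not
  any single p-value.

## Known limitations

* J saturates: once every feature separates the classes by ~2 pooled
  standard deviations, J differences between thresholds become small
  relative to sampling noise. At 53 subjects the recovered level
  localizes to about one fine-grid step; sharper claims need larger
  cohorts or a less saturating index.
* With 10-fold CV at n = 62, accuracy has a granularity of ~1.6
  percentage points and a null sd of several points; single-table
  differences of a few points are not meaningful.
* The protocol-faithful SMOTE placement is optimistically biased by
  construction; absolute accuracies in that mode should be read as
  reproductions of a workflow, not unbiased performance estimates.
* JCAMP-DX support is the AFFN (X++(Y..Y)) / XYPOINTS subset; SQZ/DIF
  compressed files and vendor binaries (SPC/OPUS) are out of scope.
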