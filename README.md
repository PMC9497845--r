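# lsdlspectra

Amplitude-band decomposition and classifier benchmarking for FTIR
biofluid spectra.

## The problem

Urine is an attractive, noninvasive medium for prostate-cancer
screening: extracellular-vesicle cargo shed into urine carries
disease-associated molecular signatures that ATR-FTIR spectroscopy can
fingerprint as an absorbance spectrum A(ν̃) over wavenumbers ν̃
(cm⁻¹). The statistical obstacle is that most of such a spectrum is
dominated by uninformative between-subject variability, while the class
difference of interest concentrates in a particular *absorbance
amplitude* region.

This package implements the analysis stack for that setting:

1. **LSDL — linear series decomposition learner.** For a threshold
   direction d ∈ {upper, lower} and level t, a spectrum is decomposed
   into the sub-signal of samples on one side of t. A coarse-to-fine
   search (default 4 iterations × 16 levels, interval halved per
   iteration, candidates with fewer than `min_samples = 8` retained
   points marked `n/a`) scores every candidate with the normalized
   Euclidean-distance performance index

   J = ED(p, q) / σₘ,

   where p and q are the class centroids of the per-sub-signal feature
   vectors (features pooled-z-scored first), ED is the Euclidean
   distance over all Nw feature dimensions, and σₘ is the mean of the
   per-feature standard deviations. The argmax-J scheme then decomposes
   every signal from the same source.
2. **A 12-feature signal battery** — MAV, WL, SSC, ZC, 4thAR (Burg),
   SampEN, Ceps, MFL, HFD, DFA, MF, SP — with the documented 1e-6
   amplitude gate for SSC/ZC; after decomposition ZC, DFA and MF are
   redundant and the battery reduces to 9.
3. **SMOTE** class balancing to stated per-class counts.
4. **Nine classifiers under stratified 10-fold CV** — DT, LDA, QDA,
   KNN (K = 1), linear/quadratic/cubic/fine-Gaussian SVM, LR — reported
   as Acc/Sens/Spec/AUC percent tables (pooled out-of-fold confusion
   matrix; singular fits reported as literal `n/a` rows), plus a PCA
   separability projection at 98 % explained variance.
5. **A seeded synthetic cohort generator** emulating the motivating
   study design (31 noncancer + 22 cancer subjects; Gleason groups
   4 / 5 / 13; triple-acquisition averaging vs single acquisition),
   with the class effect planted strictly inside a chosen amplitude
   band so the decomposition learner's target is known.

## Worked example

```r
library(lsdlspectra)

pair <- generate_cohort(cohort_spec(seed = 7), effect_spec())
model <- lsdl_threshold_search(pair$dataset1)
print(model)
```

```
<lsdl_model> optimum: upper @ 2.0245 (iteration 4), J = 5.3142
      Iteration 1 Iteration 2 Iteration 3 Iteration 4
Upper "1.9196"    "1.9795"    "2.0095"    "2.0245"
Lower "2.8793"    "2.9513"    "2.9213"    "2.9063"
```

The learner recovers the planted band: the generator's class effect
lives above 2.0 a.u., and the best scheme is the upper threshold at
2.02 (J, the normalized centroid separation of the 9-feature vectors,
peaks there at 5.31). The table mirrors the two-row Upper/Lower ×
iteration layout used for decomposition results in this literature.

```r
subs  <- lsdl_apply(model, pair$dataset1)
feats <- extract_feature_matrix(subs, feature_config(reduced_after_lsdl = TRUE),
                                labels = dataset_labels(pair$dataset1))
bal   <- smote_balance(feats, balance_spec(seed = 7))   # 31/22 -> 62 rows
tab   <- evaluate_models(bal, cv = cv_config(seed = 7))
writeLines(format_metrics_table(tab))
```

```
       Acc (%) Sens (%) Spec (%) AUC (%)
DT         100      100      100     100
LDA        100      100      100     100
QDA        100      100      100     100
KNN        100      100      100     100
LSVM       100      100      100     100
QSVM       100      100      100     100
CSVM       100      100      100     100
FGSVM      100      100      100     100
LR         100      100      100     100
```

On the decomposed features every model is perfect at the default
(strong) planted effect size; on the *raw* spectra the same seed gives
FGSVM `85 71 100 98` with the rest at 100 — the decomposition's benefit
grows as the effect weakens (see the methods vignette). Accuracy here
is the pooled out-of-fold fraction correct, sensitivity treats the
cancer class as positive, and AUC is the rank (trapezoidal) area under
the pooled-score ROC, all in percent.

The full protocol reproduction — simulate, learn one decomposition per
acquisition protocol, benchmark raw and decomposed representations,
grade exercise (GS ≤ 7 vs GS > 7, SMOTE 9/13 → 20/20), search tables,
PCA plots, provenance report — is one call (or
`inst/cli/lsdl-spectra reproduce`):

```r
res <- cmd_reproduce(run_config(seed = 1, output_dir = "lsdl_run"))
# writes 9 metrics tables, 2 search tables, 2 PCA plots, run_report.json
```

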