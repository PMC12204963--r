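# ctphase

Automatic identification of contrast-enhancement phases in multi-phase
abdominal CT.

Contrast-enhanced abdominal CT is acquired in phases after contrast
injection — early/late arterial (EAP/LAP, ~25–40 s), portal venous (PVP,
~60–75 s) and delayed (DP, ~140–155 s) — and the phase of a series often
has to be recognised from image content because DICOM timing metadata is
unreliable. `ctphase` implements a deep 3D convolutional classifier of
these four phases for examinations of 1–3 co-registered volumes, the
diagnostic-accuracy statistics used to evaluate it, and a synthetic
abdominal phantom generator so the whole pipeline is trainable and testable
without patient data.

The core model runs every phase of an examination through one
shared-parameter 3D residual feature extractor and fuses the per-phase
feature maps after an interior stage by **cross-phase attention**,

    F'_p = F_p + Σ_{q≠p} f(F_p, F_q),    f(A, B) = A softmax(−AᵀB),

where the row-softmax of the negated channel affinity down-weights channels
that agree across phases, accentuating inter-phase differences. Fused
features continue through shared stages to softmax heads. Two strategies
are provided: **one-step** (direct 4-class EAP/LAP/PVP/DP) and the
**two-step cascade** (AP/PVP/DP first, then an EAP/LAP sub-classifier that
is activated only when step 1 flags an arterial phase), plus phase-order
calibration that relabels an exam under the prior of at most one
acquisition per step-1 class in canonical temporal order. Training uses
focal loss, Adam, and a step learning-rate schedule (÷10 every 100 epochs);
evaluation reports per-class sensitivity, specificity, accuracy, PPV, NPV
with 95% CIs, balanced-accuracy AUC, and chi-square subgroup comparisons
with Bonferroni adjustment.

## Worked example

Simulate a labelled phantom cohort, train the two cascade models at desk
scale, and classify a held-out examination:

```r
library(ctphase)

spec  <- phantom_spec()                      # 32^3 grid, ellipsoid liver + vessels
train <- simulate_cohort(30, spec, seed = 11,
                         phase_sets = list(c("arterial", "PVP", "DP")))

m3 <- train_model(train, net_config("desk", n_classes = 3),
                  train_config("desk", seed = 1))      # 30 epochs, ~3 min CPU
m2 <- train_model(train, net_config("desk", n_classes = 2),
                  train_config("desk", seed = 2))

exam <- make_phantom_exam(spec, phase_labels = c("LAP", "PVP", "DP"),
                          rng_seed = 99)
predict_two_step(exam, m3, m2)
#> # A tibble: 3 × 12
#>   exam_id    phase_index true_phase acquisition_index p_EAP p_LAP p_PVP  p_DP
#>   <chr>            <int> <chr>                  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 phantom-99           1 LAP                        2 0.178 0.338 0.278 0.206
#> 2 phantom-99           2 PVP                        3 0.144 0     0.561 0.294
#> 3 phantom-99           3 DP                         4 0.126 0     0.369 0.505
#>   label_raw label_calibrated relative_order strategy
#>   <chr>     <chr>                     <int> <chr>
#> 1 LAP       LAP                           1 two_step
#> 2 PVP       PVP                           2 two_step
#> 3 DP        DP                            3 two_step
```

Each row is one phase: the assembled 4-class probability vector (the
cascade's AP mass split by the EAP/LAP sub-classifier, here 0.178/0.338 for
the arterial acquisition), the raw cascade label, the calibrated label
under the phase-order prior, and the phase's relative temporal rank. All
three phases are labelled correctly (`LAP`, `PVP`, `DP`) with
`relative_order` 1, 2, 3.

Evaluating predictions against truth reproduces the standard diagnostic
table:

```r
preds <- bind_predictions(lapply(
  simulate_cohort(12, spec, seed = 21,
                  phase_sets = list(c("arterial", "PVP", "DP"))),
  predict_two_step, model3 = m3, model2 = m2))
counts <- confusion_from_predictions(preds$label_raw, preds$true_phase)
metrics_from_counts(counts, digits = c(1, 3))
#>   class sensitivity specificity accuracy   ppv   npv   auc
#> 1   EAP        60.0       100.0     94.4 100.0  93.9 0.800
#> 2   LAP       100.0        93.1     94.4  77.8 100.0 0.966
#> 3   PVP       100.0        95.8     97.2  92.3 100.0 0.979
#> 4    DP        91.7       100.0     97.2 100.0  96.0 0.958
```

(per-class percents with 95% Wilson CIs in the full tibble, plus the
hard-classifier AUC; `glance()` reports the overall phase-wise accuracy,
91.7% on this 36-phase cohort).

The package also ships `benchmark_counts()`, the per-class confusion counts
of a published multicentre benchmark of this approach (internal test set,
288 phases, both strategies; external test set, 645 phases, two-step);
feeding them to `metrics_from_counts()` reproduces every cell of the
published performance tables, e.g. an overall two-step accuracy of 98.3%
(internal) and 99.1% (external) versus 91.7% for one-step (internal).

A thin command-line front end (`inst/cli/ctphase`) exposes
`simulate`, `train`, `predict`, `evaluate` and `run-all` over
`run_pipeline()`; volumes are NIfTI-1 files with CSV manifests
(`exam_id, phase_file, true_phase, acquisition_index`).

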