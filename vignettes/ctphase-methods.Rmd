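---
title: "Methods: contrast-phase identification with cross-phase attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast-phase identification with cross-phase attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Contrast-enhanced abdominal CT is acquired in several phases after contrast
injection: an arterial phase (AP, ~25-40 s, subdivided into early arterial,
EAP, and late arterial, LAP), a portal venous phase (PVP, ~60-75 s) and a
delayed phase (DP, ~140-155 s). DICOM timing metadata is unreliable, so the
phase of a series must often be recognised from image content. Radiologists
do this from the enhancement state of a few structures:

* **EAP** — only the hepatic artery is strongly enhanced; portal and hepatic
  veins are unenhanced.
* **LAP** — the portal vein and liver parenchyma are moderately enhanced,
  the hepatic vein still unenhanced.
* **PVP** — portal vein, hepatic vein and parenchyma all strongly enhanced.
* **DP** — the same structures enhanced, but less than in the PVP.

`ctphase` implements an automatic classifier of these four phases for
examinations of 1-3 co-registered volumes, together with a synthetic phantom
generator so that every stage is trainable and testable without patient
data.

## The model

Each phase volume is window-normalized (level 50 HU, width 600 HU, mapped
linearly onto [0, 1] with clamping) and trilinearly resampled to a cubic
grid. All phases pass in parallel through one shared-parameter 3D residual
convolutional extractor: an 18-layer-style stack of basic blocks, each
convolution followed by per-channel spatial normalization with learned
scale/shift (the batch-size-1 form of batch normalization) and ReLU. After an
interior stage, the per-phase feature maps are fused by cross-phase
attention: with `F_p` the flattened (positions x channels) feature map of
phase `p`,

    F'_p = F_p + sum over q != p of f(F_p, F_q),
    f(A, B) = A %*% softmax(-t(A) %*% B)

where the softmax runs over the rows of the negated channel affinity
`t(A) %*% B`. Negation means channels that *agree* across phases are
down-weighted, accentuating inter-phase differences. The fused maps continue
through the remaining shared stages to a global average pool and a softmax
head. Because all branches share parameters and the fusion is symmetric, the
exam-level forward pass is permutation-equivariant: input order is
irrelevant. With a single phase present the fusion sum is empty and the
model reduces to a plain forward pass, so 1-3 phase exams are handled
uniformly.

Two classification strategies are provided:

* **one-step** — a single 4-class head over (EAP, LAP, PVP, DP);
* **two-step** — a 3-class step (AP, PVP, DP) followed, *only when step 1
  flags at least one AP phase*, by a 2-class EAP/LAP sub-classifier run on
  those phases. Full 4-class vectors are assembled by the product rule
  `(p_AP p_EAP, p_AP p_LAP, p_PVP, p_DP)`.

The cascade exists because EAP and LAP differ subtly (essentially the
presence of moderate portal-vein enhancement), whereas AP/PVP/DP differ
grossly; splitting the task lowers the difficulty of each decision.

### Attention operand convention

The published fusion formula does not fix matrix shapes. We read it as
channel-Gram attention: `G = t(A) %*% B` over flattened spatial positions
(C x C), row-softmax of `-G`, right-multiplication of `A`. This is the only
shape-consistent reading that keeps `F'` the same shape as `F` under the
additive fusion; an optional `1/sqrt(N)` affinity scaling is available
(`attention_scale`, off by default). The alternative position-affinity
reading (N x N) would square in the number of voxel positions and change
the output shape; it is not implemented.

### Phase-order calibration

One examination contains at most one acquisition per step-1 class, in the
canonical temporal order EAP < LAP < PVP < DP. `calibrate_order()`
brute-forces all assignments of distinct step-1 classes to the exam's
phases (at most 6), maximizing the product of predicted probabilities, and
excludes order-violating assignments when the acquisition order is known.
Calibration defaults to on for examination-level labels and off for
phase-wise metrics; both raw and calibrated labels are always reported.
Ties everywhere break to the first class in canonical order. "Relative
order" is operationalised as the rank of the calibrated labels under the
canonical timing, the natural reading of an order output for 1-3 unordered
inputs.

## Training

Models train with focal loss (`-(1-p_t)^gamma log p_t`, default `gamma = 2`
and no class weighting — the loss reference gives no parameters), the Adam
optimiser, and a step learning-rate schedule dividing the rate by 10 every
100 epochs. The full-scale (`"full"`) preset is 1000 epochs at 1e-5 on
192^3 inputs with stages 64/128/256/512; it exists as configuration but is
not exercised by the tests. The tested (`"desk"`) preset is a miniature of
the same architecture — 32^3 input, stem of 8 channels, stages 8/16/32 with
one basic block each, attention after stage 2 — trained 30 epochs at 1e-3:
at a few dozen exams and tens of epochs the full-scale rate would barely
move the weights, so the desk presets use a conventionally larger rate,
chosen once. One examination (1-3 phases) is one optimiser sample, matching
the parallel multi-phase input; per-exam loss is the mean over its phases.
Weight initialisation is He-style Gaussian; batch size defaults to 1. Both
are unstated in the reference description and recorded in
`train_config()` / `phase_net()`.

Training-time perturbations mirror the intended invariances: random flips
(drawn once per exam and applied to all phases, preserving co-registration,
since the model compares phases voxel-wise), random dropping of phases to
at least one (missing-phase simulation), and random phase order. The
validation split (default 20%) is stratified by phase-set composition; the
best-validation-accuracy epoch's parameters are kept (earliest on ties).
The 2-class model trains on the single arterial volume of each exam, where
fusion degenerates to the identity.

The network engine (im2col 3D convolutions over BLAS, hand-derived reverse
mode, Adam) is implemented in the package and verified against numerical
differentiation; the attention fusion is additionally checked against a
naive loop reference.

## The synthetic phantom

The generator emulates the *decision-relevant* content of an abdominal
exam, not anatomy: an ellipsoidal liver (parenchyma, baseline 55 HU)
containing a portal-vein and a hepatic-vein tube (blood pool 45 HU), an
aorta-like artery crossing the volume, and soft-tissue background (30 HU).
Each phase volume is the shared baseline plus per-structure mean HU deltas
(jittered per exam) plus additive Gaussian voxel noise (default SD 5 HU).
All phases of an exam share one geometry, so they are co-registered by
construction. One integer seed drives geometry jitter, delta jitter and
noise through tagged sub-seeds, making every exam bit-reproducible.

Default deltas encode the annotation criteria (HU over baseline):

| phase | artery | portal vein | hepatic vein | parenchyma |
|-------|-------:|------------:|-------------:|-----------:|
| EAP   | 250    | 5           | 0            | 5          |
| LAP   | 200    | 45          | 5            | 20         |
| PVP   | 80     | 100         | 90           | 50         |
| DP    | 50     | 55          | 50           | 30         |

The criteria are qualitative; the quantitative cut-offs of the rule-based
labelling oracle (`phase_thresholds()`: artery strong >= 150, portal
moderate in [25, 80), portal strong >= 80, hepatic vein unenhanced < 20,
strong >= 60, parenchyma strong >= 40) are implementer-chosen stand-ins,
consistent with the decision ladder and overridable. For DP the ladder can
use the same exam's PVP deltas as the comparison reference ("less enhanced
than in the PVP") instead of the absolute cut-offs.

Edge-case generators reproduce the patterns of known hard cases: an EAP
whose portal vein flashes ~10-15 HU, a LAP whose portal enhancement sits
just above the moderate threshold, and a PVP/DP pair separated by only
~34 HU (portal vein) and ~9 HU (hepatic vein).

What the phantom deliberately does **not** model: real anatomy and texture,
lesions, respiratory motion and inter-phase misregistration, scanner and
reconstruction effects. Passing tests therefore demonstrate that the
architecture, cascade and statistics behave as specified and that the
models can learn the phase-defining enhancement signals — not that
real-data accuracy is reproduced. The published real-data accuracies are
covered as count-based metric reproductions, never as training targets.

## Evaluation statistics

Per class (one-vs-rest): sensitivity, specificity, accuracy, PPV, NPV in
percent, with two-sided 95% binomial CIs; rates with zero denominators are
undefined (`NA`), never zero. For a hard argmax classifier the reported
"AUC" is the balanced accuracy `(sensitivity + specificity)/2` — this
convention reproduces all published AUC point values exactly; a rank-based
score AUC (`score_auc()`) is available when probability outputs exist. The
published brackets match neither Wilson nor Clopper-Pearson exactly, so the
CI method is configurable (Wilson default, recorded in the report) and CI
values are not regression-tested. Report formatting rounds half-up, 1
decimal for percents and 3 for AUC, matching table conventions. Subgroup
comparisons use the Pearson chi-square test with Bonferroni adjustment
(`min(1, p * n_comparisons)`); no AUC-difference test between strategies is
provided (the method behind the published p-values is unstated).

## Numerical and scale choices

* Desk problem sizes, chosen once for CPU-scale runs and used by the test
  suite and the acceptance script: the 3-class learning check trains on 60
  exams (32^3 input) for 30 epochs with a 20-exam held-out cohort; the
  cascade-vs-one-step comparison trains all three models per seed on 20
  EAP/LAP-hard exams (24^3 input, LAP identical to EAP except the portal
  vein) for 20 epochs — enough, by their validation trajectories, for the
  step-1 and 2-class models to converge — aggregated over 5 seeds.
* Out-of-window HU are clamped (the normalization range statement is read
  as a clamp; rescaling would make the window meaningless).
* Resampling is trilinear and cell-centred, so an identity target shape is
  an exact identity; single-slice axes are rejected rather than
  extrapolated.
* Focal-loss `p_t` is clamped at 1e-7; softmax subtracts the row maximum.
* Probability-sum tolerances are 1e-6 at interfaces.
* Whether step 2 reuses step-1 extractor weights is unstated; the two
  models are trained independently here (simpler, and the 2-class task sees
  single volumes only).

## Known limitations

* The full 192^3 / 1000-epoch configuration is provided but untested at
  scale; the engine is pure R + BLAS and is not expected to be competitive
  with GPU frameworks there.
* The phantom's separability makes desk-scale learning checks meaningful
  but easy; conclusions about real scanners, pathology or misregistration
  are out of scope.
* Only 1-3 phase protocols and the four phase classes are supported; there
  is no pre-contrast class.
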