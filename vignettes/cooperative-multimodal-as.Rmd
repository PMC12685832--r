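---
title: "Cooperative multimodal learning for aortic-stenosis screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative multimodal learning for aortic-stenosis screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coopAS)
```

## The problem

Aortic stenosis (AS) is diagnosed by echocardiography, but echo is usually
ordered only once symptoms appear. Electrocardiograms and chest radiographs
are cheap, ubiquitous, and each carries a partial shadow of the disease:
pressure overload shows up electrically (left-ventricular hypertrophy with a
strain-type repolarization pattern, largest in the lateral leads I, aVL, V5,
V6) and morphologically (cardiac silhouette enlargement, valve
calcification). `coopAS` implements a screening model that reads both at
once and is trained so that the two readers teach each other.

The binary AS label is derived from echo measurements by the standard rule:
peak aortic-valve velocity $\ge 2.5$ m/s, or mean pressure gradient
$\ge 20$ mmHg, or aortic valve area $\le 1.5\ \mathrm{cm}^2$ — any single
criterion suffices (`label_as()`). Comparisons are inclusive at the
thresholds; missing measurements are skipped, and a record with all three
missing cannot be labelled.

## The model

Each modality has its own scoring network emitting one scalar pre-sigmoid
score per sample:

* **ECG branch** (`ecg_model_init()`): every one of the 12 leads is passed
  through the *same* 1-D convolutional tower (weight sharing), pooled over
  time (concatenated mean and max — the max carries QRS peak amplitudes,
  the mean baseline morphology) and projected to an `embed_dim`-dimensional
  embedding (256 by default). The 12 lead embeddings receive learned
  lead-identity embeddings (leads form a set, not a sequence, so these
  replace positional encodings), a learned class token is prepended, and a
  Transformer encoder mixes the 13 tokens. The encoder output at the class
  token, through a linear head, is the ECG score $f_{ecg}(X_{ecg})$.
* **Image branch** (`image_model_init()`): a 2-D CNN over the prepared
  radiograph. The input is z-scored per sample inside the branch — after
  per-image windowing, global brightness and contrast are artefacts of the
  window rather than signal, so standardization forces the network onto
  morphology. Stride-2 convolutions then halve the grid to $\le 8$ pixels,
  a final stride-1 convolution provides the Grad-CAM target layer, and
  global average pooling plus a linear head give $f_{cxr}(X_{cxr})$. A widened
  `"efficientnet-style"` backbone exists for larger runs; the `"small-cnn"`
  backbone keeps tests CPU-fast. No pretrained weights ship with the
  package; requesting them falls back to random initialization with a
  warning.

### The cooperative objective

Training minimizes, over both parameter sets jointly,

$$
\mathbb{E}\Big[\tfrac12\big(y - (f_{ecg} + f_{cxr})\big)^2
  + \tfrac{\rho}{2}\big(f_{ecg} - f_{cxr}\big)^2\Big],
$$

a squared-error *prediction* term on the summed score plus a
$\rho$-weighted *agreement* penalty on the score difference
(`cooperative_loss()`). The per-score gradients are

$$
g_{ecg} = -\big[y - (f_{ecg}+f_{cxr})\big] + \rho (f_{ecg}-f_{cxr}),
\qquad
g_{cxr} = -\big[y - (f_{ecg}+f_{cxr})\big] + \rho (f_{cxr}-f_{ecg}),
$$

so the first term pulls the sum toward the label while the second pulls the
branch difference toward zero, damping modality-specific noise while
keeping the shared disease signal. At $\rho = 0$ the objective reduces to
early fusion (joint fitting of the sum); as $\rho$ grows the marginal
predictions are forced to align, approaching late fusion in the
additive/linear setting. For linear branches the stationarity conditions
form one linear system solved exactly by `linear_closed_form()`, which
serves as the verification oracle: gradient training
(`train_cooperative_linear()`) must recover concatenated OLS at
$\rho = 0$, and the mean squared disagreement at the solution is
non-increasing in $\rho$.

The agreement penalty acts on **pre-sigmoid scores**, not probabilities:
the objective is squared error on raw scores, and the additive structure
("each branch contributes a score") only exists before the nonlinearity.
The evaluation probability is `sigmoid(f_ecg + f_cxr)`; AUROC uses the raw
sum, which is rank-equivalent.

## Preprocessing

* ECG: recordings arrive as 12 × N matrices in mV at 500 Hz. Training draws
  a random contiguous 2-s window (12 × 1000); evaluation uses the
  deterministic centre window (`extract_segment()`). Each segment is
  baseline-calibrated by per-lead mean subtraction, and training adds
  i.i.d. uniform noise in ±0.1 mV (`augment_ecg()`). The mean was chosen as
  the baseline estimator for noise robustness (a first-sample anchor is
  noisier); the noise is read as uniform over the full ±range — both
  choices are configurable. Baseline zeroing is applied per extracted
  segment.
* Images: min–max windowed to 8 bit per image (a constant image maps to
  zero), bilinearly resized to the branch input size (224 default; smaller
  for desk-scale runs), and rescaled to [0, 1] floats (`prepare_image()`).
  Training augments with centre rotations uniform in ±10° (zero fill) and
  full-range autocontrast with probability 0.25 (`augment_image()`).

## Training protocol

`train_cooperative()` / `train_unimodal()` run Adam (β₁ = 0.9, β₂ = 0.999)
with a cosine-annealed learning rate (half-period 10 epochs; the rate
starts at the configured peak and reaches the floor at the period), up to
100 epochs with early stopping on validation loss (patience 20), returning
the weights from the epoch with the lowest validation loss. Early stopping
monitors the *cooperative* loss itself (the probability-scale alternative
is a flag on the unimodal trainer). Splits are by patient
(`split_by_patient()`): patients are shuffled and assigned greedily to the
most-underfilled split relative to 70/15/15 record-count targets, so no
patient ever contributes records to two splits. When labels are available
the shuffle-and-assign runs separately within the positive-patient and
negative-patient strata. This matters at screening prevalence: with 8%
positive patients and a 200-patient cohort, an unstratified 15% validation
split has a sizeable chance of containing *no* positive patient at all — in
which case a constant-zero predictor minimizes the validation loss, the
best-checkpoint rule silently returns an untrained epoch, and validation
AUROC is undefined. Stratification (the grouped analogue of a stratified
split) removes that failure mode while preserving patient atomicity, the
ratio targets and seeded determinism; `stratify = FALSE` restores the plain
split. `tune_hyperparameters()`
searches ρ ∈ [0, 1], batch size ∈ {64, 128} and a log-uniform learning
rate in [1e-6, 1e-3] against validation AUROC, by seeded random search or
a Parzen-style sequential proposal (the random fallback keeps the package
dependency-free); the trial count is configurable (default 20, unstated in
the protocol this mirrors). Mixed precision is accepted as a flag but R
computes in double precision; runs are bit-stable on CPU as a result.

## Interpretability

Phase 1 (`lead_attention()`): the class-token query row of the Transformer
attention, head-averaged, from the last layer by default (averaging over
layers is an option), renormalized over the 12 lead keys. Phase 2
(`gradcam_1d()`): per lead, 1-D Grad-CAM on the shared tower's final
convolutional activations — channel weights are time-averaged gradients of
the positive-class pre-sigmoid score, relevance is the rectified weighted
channel sum upsampled to the segment length. The final heatmap multiplies
each lead's *raw* trace by its Phase-1 weight (`weighted_ecg_heatmap()`);
display normalization is separate so the faithfulness module always sees
raw maps. The image branch uses standard 2-D Grad-CAM (`gradcam_2d()`).

## Faithfulness

`perturbation_curve()` implements blur-based deletion and insertion over
the coverage grid (18, 30, 40, 50)% of pixels: deletion replaces the
saliency top-p% pixels with a Gaussian-blurred image in the model's
normalized space; insertion starts from the fully blurred image and
restores them. "Heavily blurred" is σ = image size / 8 by default,
configurable. Perturbation is cumulative from one fixed reference — the
masks are nested because one saliency ordering is shared across the grid,
with ties broken deterministically in raster order (which also makes the
uniform-map baseline deterministic). `aopc()` supports two summaries:
**score-drop** (default; mean drop from the unperturbed reference for
deletion, mean rise over the blurred reference for insertion) and
**raw-average** (plain mean of curve scores). Both exist because printed
AOPC values in the clinical literature do not always disambiguate the
reference convention; the standard score-drop form is the default.
Baselines are area-matched random pixel sets and the uniform map
(`baseline_saliency()`); uncertainty comes from a 1000-replicate percentile
bootstrap over images (`bootstrap_aopc()`). Bootstrap resampling is over
images, not patients.

## Evaluation

`roc_auc()` is the Mann–Whitney pair statistic (ties counted ½),
`pr_auc()` the step-curve average-precision convention, and
`threshold_metrics()` the standard confusion-matrix set with explicit
zero-denominator conventions. The operating threshold maximizes Youden's J
on validation (`select_threshold()`) — the thresholding rule behind
published screening metrics is rarely stated, so this standard choice is
made explicit. `bootstrap_metric()` reports the bootstrap median with
2.5/97.5 percentile bounds (resampling records by default; a patient-level
unit respects within-patient clustering). `compare_models()` uses shared
resample indices for a paired difference, a percentile CI, and a two-tailed
p-value `2·min(P(diff≤0), P(diff≥0))` with add-one smoothing, capped at 1.

## The synthetic cohort generator

Hospital ECG/CXR/echo cohorts cannot be redistributed, so every stage is
exercised on `generate_cohort()`. Each patient draws a latent severity
(diseased patients — probability `target_prevalence`, default 8% as in the
clinical population this emulates — from U(0.6, 1), others from
U(0, 0.35)) and one set of echo measurements, affine in severity with
Gaussian noise and clipped to physiologic ranges, calibrated so the
noise-free extremes fall on the correct side of every AS threshold. All
records of a patient share its severity and label. Per record:

* the **ECG** is a quasi-periodic P-QRS-T sum of Gaussian bumps at a heart
  rate near 70 bpm, with per-lead projection multipliers; severity scales
  the QRS amplitude in the lateral leads by (1 + severity) and continuously
  flips the T-wave polarity there — a strain analogue;
* the **image** is a smooth background texture plus a central ellipse whose
  width fraction grows with severity (silhouette enlargement analogue) and
  a bright blob appearing with probability 0.9·severity (calcification
  analogue). The generator also emits the planted-signal mask (ellipse ∪
  blob) solely so the faithfulness module has a localization oracle — real
  data carry none;
* each modality expresses `clamp01(severity + N(0, 0.3))` rather than the
  severity itself. This per-record, per-modality jitter is the
  modality-specific signal component: either modality alone sees the
  disease only through independent noise, which is what caps unimodal
  accuracy and makes fusing the two genuinely informative — mirroring the
  clinical situation where ECG and CXR each miss cases the other catches.
  The jitter SD (0.3) was calibrated once, against the latent severities
  themselves rather than any trained model: it places the
  single-modality *ideal-observer* AUROC (severity read through one
  modality's jitter) in the mid-0.8s and the two-modality ideal observer
  in the low-0.9s, reproducing the qualitative regime of published AS
  screening — each modality informative but imperfect, fusion clearly
  better;
* study days are drawn so echo↔CXR and CXR↔ECG offsets exercise the ±90-day
  and ±7-day linkage windows (`link_records()` selects the closest CXR to
  each echo, then the closest ECG to that CXR, both inclusive; equidistant
  ties resolve to the earlier study — "three months" is implemented as ±90
  days).

One interaction worth knowing about: the preprocessing contract min–max
windows every image individually (as radiograph auto-windowing does), so
the generator's absolute-brightness cue is not usable after preparation —
when the bright calcification blob is present it rescales the rest of the
image downward, and the prepared global mean actually anti-correlates with
disease. The image branch therefore has to read morphology (silhouette
width), which requires a reasonable spatial grid; 64-pixel images are the
practical minimum for the small-cnn backbone.

What the generator does **not** emulate: dipole-model ECG morphology,
arrhythmias, anatomically realistic radiographs, DICOM metadata,
severity-dependent heart rate, or class-imbalance pathologies beyond the
prevalence itself. Tests passing on this generator demonstrate that the
pipeline's machinery is correct and that cooperative fusion recovers a
planted shared-latent structure — not that the architecture reaches any
particular clinical accuracy.

## Numerical and scale choices

The neural layers (1-D/2-D convolution via im2col, multi-head
self-attention with a class token, layer normalization, Adam, cosine
annealing) are implemented in dense base-R matrix algebra with explicit
forward/backward passes; a full finite-difference check of every parameter
group is part of the development workflow, and the cooperative gradient is
verified against central differences in the test suite. Default test and
verification runs use desk-scale configurations — 200-patient cohorts,
64-pixel images with `base_channels` 8, `embed_dim` 32, one Transformer
layer, `cnn_scale` 0.25, batch 16 at peak rate 1e-3 throughout, with
per-arm epoch budgets that reflect convergence speed (image branch 20, ECG
branch 30, joint cooperative model 40, each arm keeping the weights from
its best validation-loss epoch) — chosen so the whole verification suite runs on
one CPU core while leaving the full-scale configuration (256-d embeddings,
4 layers, 8 heads, 224-pixel inputs) available through the same configs.
The heavier numerical primitives (strided 1-D/2-D convolution and the
centre-anchored rotation) are compiled (Rcpp/RcppArmadillo) with the R
implementations' exact layout conventions.
Weight initialization is He-scaled; the class token and lead embeddings
start near zero (SD 0.02). Degenerate inputs are handled explicitly:
constant images map to zero, all-zero Grad-CAM gradients return all-zero
maps with a warning, single-class resamples are dropped from bootstrap
replicates (erroring when more than 20% drop), and rank-deficient designs
raise an explicit error in the closed-form solver.

## Known limitations

* The ρ = 1 "late fusion" correspondence is verified empirically (marginal
  predictions align as ρ grows) rather than asserted as an exact
  equivalence.
* A patient-level split with greedy record balancing reproduces target
  ratios only approximately when single patients hold large record shares;
  the patient-disjointness invariant is always hard.
* The DICOM reader is deliberately minimal (explicit VR, little endian,
  uncompressed grayscale) — enough for device exports of that form;
  anything else should be converted to PNG first.
* Desk-scale training on synthetic cohorts says nothing quantitative about
  clinical AUROC; reproducing published clinical numbers requires private
  patient data and full-scale training.
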