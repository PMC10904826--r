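---
title: "Attention-guided diagnosis with partial location labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided diagnosis with partial location labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Model and objective

attnguide trains a convolutional classifier for three panoramic-radiograph
classes (Normal; cyst-and-tumor; an LMBD-like mimic) while supervising the
model's *attention* on whatever subset of training images carries a
radiologist-style lesion mask.

The network is a feature extractor followed by global average pooling (GAP),
dropout (rate 0.25) and a linear head. For target class $y$, the Grad-CAM
attention map on the last-conv grid is

$$H = \sum_k w_k A_k, \qquad w_k = \operatorname{GAP}\!\left(\frac{\partial f_y}{\partial A_k}\right),$$

optionally ReLU-clipped. Because every head here is GAP + linear,
$\partial f_y / \partial A_k$ is spatially constant, so $w_k$ has a closed
form and $H$ coincides with the classical CAM up to a $1/(mn)$ factor (the
acceptance suite asserts this). That closed form is what lets the package
backpropagate the attention loss *exactly*, in plain R/C++, without an
autodiff engine: the full chain — weighted feature sum, optional ReLU,
bilinear upsampling (a fixed linear operator, applied as two small
interpolation-matrix products), min–max normalization (sub-gradient at the
arg-min/arg-max), steep logistic, product-relaxed IoU — is differentiated
analytically, and the test suite checks it against central finite differences
to relative 1e-4.

The soft mask is
$\tilde H = s(\omega(\bar H - \theta))$ with $\bar H$ the min–max-normalized,
upsampled map, $\theta = 0.5$, $\omega = 100$ by default. The attention loss
is $1 - \mathrm{IoU}(\tilde H, Y)$ when a label $Y$ exists and exactly $0$
otherwise; the objective is
$\mathcal{L} = \alpha_{cls}\mathcal{L}_{cls} + \alpha_{att}\mathcal{L}_{att}$
with $(\alpha_{cls}, \alpha_{att}) = (2, 1)$.

### Numerical choices

* **IoU relaxation.** The set IoU is defined on binary masks; the training
  loss needs a differentiable surrogate. The product relaxation
  ($\sum \tilde H Y / \sum(\tilde H + Y - \tilde H Y)$) is the default
  because it reduces *exactly* to the set IoU on binary inputs (tested on 200
  random grids) and is smooth; $\sum\min/\sum\max$ is available as
  `loss_config(iou_relaxation = "minmax")`.
* **Resolution reconciliation.** $H$ lives on the coarse last-conv grid and
  $Y$ at image resolution. $H$ is upsampled to $Y$'s shape (upsample, then
  normalize); downsampling $Y$ instead would destroy thin lesion borders.
* **$\varepsilon$-guard.** Min–max normalization is undefined on constant
  maps (an all-zero post-ReLU map is common early in training);
  $\varepsilon = 10^{-8}$ in the denominator makes it total. A constant map
  yields $\tilde H \approx s(-\omega\theta)$ everywhere.
* **Sigmoid saturation.** At $\omega = 100$ the soft mask saturates to
  exactly 0/1 in double precision away from the threshold; entries are
  mathematically in $(0,1)$ but tests assert the closed interval.
* **Grad-CAM target class.** Ground-truth class during training (the mask
  annotates that lesion), predicted class at inference/visualization.
* **ReLU after the weighted sum** is on by default and switchable
  (`gradcam_relu`), since CAM-style maps are sometimes used unclipped.

## Training protocol

`train_config()` defaults encode the full-scale protocol: stratified 6:2:2
split, SGD (lr $10^{-3}$, weight decay $10^{-5}$), per-epoch cosine annealing
with $T_{max} = 50$ (two arcs over 100 epochs; epoch-stepping was chosen,
batch-stepping is the documented alternative), batch 8, early stopping with
patience 40 on validation accuracy, 5 repeats with per-repeat seeds
`base + repeat`. The attention term of a batch is averaged **over the
mask-flagged samples only**, so its per-sample scale is independent of the
label budget; a whole-batch mean would shrink the guidance signal at low
budgets.

Split rounding is floor-per-split with the remainder assigned train-first;
the attention budget keeps exactly $\lceil r \cdot n \rceil$ of the
mask-carrying training samples, chosen by a seeded shuffle so budgets nest:
the rate-$r_1$ set is a subset of the rate-$r_2$ set for $r_1 < r_2$.
Model selection uses plain multiclass validation accuracy (macro metrics are
logged alongside); early stopping counts epochs since the best epoch.

### The backbone, offline

The architecture of record for clinical-scale work is a pretrained ResNet50
feature extractor; pretrained torch weights do not exist in a pure-R offline
build, so `build_model(backbone = "resnet50")` raises an informative error
and two from-scratch CNNs are provided: `tiny16` (3 conv blocks, stride 16)
and `tiny32` (stride 32; a 940×520 input yields the expected 30×17 last-conv
grid). Convolutions run as im2col + BLAS gemm in C++; initialization is
Kaiming-uniform.

Training a small CNN from scratch on tiny, homogeneous radiographs is a
different optimization regime from fine-tuning a pretrained ResNet, and three
adaptations were needed to make it converge at all (all configurable, all
frozen before the pilot run below):

1. **Input z-scoring and frozen feature standardization.** Phantom
   radiographs are nearly identical to each other, so GAP features sit on a
   large common-mode offset with tiny between-class variation, which
   ill-conditions the linear head. Each input is z-scored per image, and the
   GAP features are standardized with per-feature mean/sd frozen from the
   training set at initialization (a data-dependent initialization, akin to a
   BatchNorm frozen at init; `recalibrate_every` re-freezes it each epoch).
   Both keep $\partial f_y/\partial A_k$ constant, preserving the closed-form
   attention chain.
2. **Momentum and per-layer gradient clipping.** `momentum = 0.9` (the
   conventional SGD setting in this literature) and a per-parameter-group
   gradient-norm cap (`grad_clip`); a *global* cap would let the large
   backbone gradients squash the head's updates.
3. **Desk-scale sharpness.** With $\omega = 100$ the soft-mask loss is
   near-piecewise-constant and a 20-epoch from-scratch run receives almost no
   usable gradient; the desk-scale configuration uses $\omega = 10$. The
   $\omega \to \infty$ sharpening behaviour is asserted separately at
   $\omega = 10^4$.

`desk_train_config()` freezes the desk-scale bundle (tiny16, lr 0.02,
momentum 0.9, clip 1, recalibration each epoch, $\omega = 10$, ≤ 20 epochs);
`train_config()` keeps the full-scale constants.

## Augmentation

Fixed order: intensity jitter (image only) → joint horizontal flip → joint
trapezoid transform → center crop. Contrast is defined as a stretch about the
post-brightness image mean (identity on constant images); only the ±range is
inherited from the protocol, the anchor is this package's choice. The
trapezoid transform keeps the top edge fixed and scales the bottom ("base")
width by $1+\delta$, $\delta \sim U(-0.05, 0.05)$, moving the bottom corners
by $\pm\delta(W-1)/2$ — realizing a maxilla/mandible ratio change. Which edge
is "base" is not fixed by the protocol; `anchor = "bottom"` flips the
convention, and $\delta$ is interpreted as the *full* bottom-width factor
(the half-displacement reading is the documented alternative, one constant
away). Warping is inverse-mapping resampling — bilinear for images, nearest
for masks so they stay binary — with out-of-canvas fill 0 (black, matching
collimation borders). Crop geometry scales the canonical 1280×720 → 940×520
fractions when no explicit size is given. If a warp/crop empties a sample's
mask, that sample falls back to class-only supervision for that epoch.

## The phantom world

`phantom_config()` defaults *are* the package's stated synthetic world, and
they are not tuned against test outcomes:

* 320×180 canvas (¼ of 1280×720; full scale available), 60 images/class —
  the desk-scale counterpart of a ~700-image clinical cohort across three
  training classes.
* Two plateau-profile horizontal bands stand in for maxilla and mandible;
  background Gaussian noise sd 0.02; a faint non-diagnostic dark "shadow" in
  the upper band of *every* image emulates superimposed anatomy and gives
  unguided attention something irrelevant to lock onto.
* Lesions are unions of 2–5 overlapping ellipses (free-form border-style
  ROIs, not boxes — so the IoU loss is exercised on irregular supports) with
  semi-axes 7–16 px at default scale, placed in the mandibular band.
  Cyst-and-tumor blobs are strongly radiolucent (contrast −0.35) with a sharp,
  faintly corticated rim anywhere along the band; the LMBD mimic is softer
  (−0.25, feathered border) and restricted to the posterior (lateral) third —
  mirroring that LMBD is a mandible-specific mimic whose separation benefits
  from looking at the right place.
* Masks are the exact blob support; Normal images never carry masks. Mean
  intensity inside a mask differs from the surrounding band by at least half
  the configured contrast (asserted per sample), which is what makes the
  classification task learnable by construction.

What the generator does **not** emulate: teeth, sinus and spine structures,
exposure physics, multi-lesion images, patient-level grouping (one image =
one synthetic patient; the splitter stratifies by sample). A green test on
phantoms therefore establishes that the *machinery* — losses, budgeting,
augmentation, optimization, metrics — behaves as specified and that attention
guidance has the claimed directional effect in a controlled world; it does
not certify clinical-scale accuracy.

## The scaled scientific property

The acceptance experiment trains rate 0 vs rate 1 on the default phantom
world, 5 seeds each, ≤ 20 epochs, and compares means:

* localization IoU (thresholded predicted-class attention vs ground-truth
  mask on test lesions): 0.126 (rate 1) vs 0.058 (rate 0) in the frozen
  pilot;
* macro accuracy: 74.8 % vs 72.6 %.

The frozen assertions are the stated inequalities themselves — strict
`>` for localization, `>=` for accuracy — evaluated on a fixed-seed,
single-threaded, therefore deterministic run. No empirical number appears in
this vignette that the tests or `scripts/acceptance.R` do not themselves
compute.

## Evaluation

Metrics follow the one-vs-rest reduction: per class $c$, $TP = cm_{cc}$,
$FN$/$FP$ the off-diagonal row/column sums, $TN$ the rest;
accuracy $= (TP+TN)/N$, sensitivity $= TP/(TP+FN)$, specificity
$= TN/(TN+FP)$, each in percent, macro-averaged as the unweighted class mean.
Classes with a zero denominator are excluded from the macro mean with a
warning rather than scored 0 (small test splits should not zero out a class).
Plain multiclass accuracy (trace / total) is reported alongside, since
"accuracy" in a one-vs-rest table can mean either; the macro value is the
headline. Localization quality binarizes the min–max-normalized,
predicted-class attention map at $\theta$ and reports the exact binary IoU
against the mask, mean ± sd over mask-carrying test samples.

## Known limitations

* No pretrained backbone offline: absolute desk-scale accuracies are far
  below clinical-scale numbers by design; only directions and invariants are
  meaningful at this scale.
* The frozen feature standardization trails the backbone during training
  (like frozen BatchNorm); per-epoch recalibration mitigates this.
* The attention chain treats the min–max extrema as fixed (sub-gradient),
  exact except on measure-zero tie sets.
* CLAHE and rotation augmentation are representable only as absent ops in
  ablation configs — they were comparison baselines elsewhere, deliberately
  out of scope here.
* `omega`, `theta` and the IoU relaxation are exposed but interact: very
  large `omega` with a mid-range `theta` gives near-binary masks and
  near-zero gradients; guidance needs either moderate `omega` or long
  schedules.
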