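---
title: "Methods: semi-supervised tumor segmentation for H&E tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-supervised tumor segmentation for H&E tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pixel-accurate tumor annotation of H&E-stained pathology tiles is expensive:
a pathologist must outline tumor regions on hundreds of 640×640 tiles.
Semi-supervised segmentation trains on a small labeled subset plus a large
unlabeled pool. This package implements a mean-teacher pipeline for binary
tumor/background segmentation: a *student* network is trained by gradient
descent while a *teacher* network — an exponential moving average (EMA) of
the student — produces consistency targets on unlabeled tiles,

$$\theta_T^{(t)} = \alpha\,\theta_T^{(t-1)} + (1-\alpha)\,\theta_s^{(t)},$$

with decay $\alpha$ (default 0.99). Three components are layered on top of
this loop: a boundary-aware enhanced U-Net, transformation-based uncertainty
masking, and multi-scale prototype contrastive learning.

## The segmentation network

The backbone is a standard lightweight 2D U-Net: five resolution levels with
channel widths 16, 32, 64, 128, 256, two 3×3 convolution + normalization +
ReLU blocks per level, 2×2 max-pool downsampling, and a decoder using
1×1-convolution channel reduction, bilinear ×2 upsampling and skip
concatenation. A final 1×1 convolution (the *seg-head*) maps the 16-channel
full-resolution features $F_S$ to 2 class logits; everything before it is the
*seg-net*. This configuration has 1,813,506 trainable parameters (1.81 M),
which `count_parameters(build_backbone(model_config()))` verifies against a
closed-form per-layer enumeration in the test suite.

Because the batch size is one tile, the normalization layers normalize each
channel over the tile's spatial extent (instance normalization); this behaves
identically in training and inference and avoids the degenerate batch
statistics that batch normalization would produce at batch size 1.

The full model (`build_model()`) adds:

* **Boundary-aware module.** The canonical 3×3 Sobel pair is applied per
  color channel with reflective padding; the gradient magnitude is scaled by
  a learnable scalar. The branch reads the raw image, in parallel with the
  seg-net.
* **Boundary enhancement.** Five convolution + normalization + ReLU layers
  with kernel sizes 5, 5, 3, 3, 1 and `same` padding produce boundary
  features $F_{BE}$ with $C_B = C_S = 16$ channels.
* **Boundary–spatial fusion (BSFM).** A channel-attention block: sigmoid on
  each feature map, per-channel average and max pooling, a shared scalar
  convolution on the four pooled vectors, concatenation, and a two-layer MLP
  (hidden width $2 C_S$, ReLU) produce a $2 C_S$ weight vector split into
  $W_S$ and $W_{BE}$; the fused features are
  $F_{BSF} = F_S + \alpha\,(F_S \otimes W_S + F_{BE} \otimes W_{BE})$
  with per-channel scaling $\otimes$ and a second learnable scalar $\alpha$.
  Freezing this $\alpha$ at 0 reduces the model exactly to the plain U-Net,
  which gives a clean ablation axis (tested).

Dropout (default rate 0.5, 0.3 in the test-scale configurations) is placed in
the bottleneck and before the seg-head, and can be switched on at inference
for Monte-Carlo sampling.

## Uncertainty-masked consistency

Teacher pseudo-targets are only trusted where two independent uncertainty
estimates agree that the prediction is stable:

* **Monte-Carlo entropy.** $T$ stochastic teacher passes (dropout active,
  default $T = 8$; the number of passes is not prescribed by the method and
  follows the uncertainty-aware mean-teacher convention) are averaged into
  per-pixel probabilities $u_c$; the entropy
  $Q_e = -\sum_c u_c \log u_c$ is thresholded as $Q_e < \xi_E$ (strict).
  $\xi_E$ ramps from $0.75 \ln 2$ to $\ln 2$ over training along the same
  Gaussian shape as the ramp-up weight, normalized so the endpoints are
  exact.
* **Transformation agreement.** The tile is passed through $M = 7$ invertible
  transformations — rotations by 90°/180°/270° (counter-clockwise), the two
  flips, a recorded random permutation of non-overlapping patch blocks
  (default 4×4 grid), and a recorded random permutation of the three color
  channels. Each transformed tile is predicted by the deterministic teacher,
  the prediction is inverted (the color permutation inverts to the identity
  on class maps), and the per-pixel arg-max votes are counted:
  $Q_T^c = M_c / M$. A pixel passes when its strongest class exceeds
  $\xi_T$ (strict; default 0.5). The "patching" and "color channel"
  transformations are not fully specified in the originating description;
  recorded block and channel permutations were chosen because they are
  label-preserving, exactly invertible, and seedable.

The combined mask is the pixel-wise AND, and the consistency loss is the
masked mean squared distance between student and teacher softmax vectors,
with an all-zero mask contributing zero (early-training masks can be empty).

## Multi-scale prototype contrastive learning

From the last $D = 3$ decoder scales (finest first), a per-scale 1×1
projection maps features to $C_\text{out} = 64$ channels ($C_\text{out}$ and
the temperature are free choices; $\tau = 0.1$ follows InfoNCE convention).
Class prototypes are probability-weighted feature means,
$Q_c = \sum_n F'_n \tilde P_{c,n} / \sum_n \tilde P_{c,n}$.

The per-pixel class probabilities $\tilde P$ are the seg-head softmax
average-pooled down to scale $d$, for teacher and student alike. The
alternative — independent per-scale linear classifier heads — was
implemented first and rejected: such heads receive no segmentation signal,
so their softmax is unrelated to tumor/background and the resulting
prototypes mix classes arbitrarily; a controlled decomposition (consistency
term only versus the full unsupervised loss) showed that this variant
systematically degraded held-out Dice, while the pooled-softmax form is
neutral-to-helpful. Pooling the seg-head softmax keeps the weights
semantically meaningful at every scale and remains differentiable on the
student side.

The per-scale loss is an InfoNCE-style ratio on the four prototypes with
cosine similarity, implemented exactly in its printed five-term form:

$$\mathcal{L}_{CL} = -\log
\frac{e^{s(Q_{bg},V_{bg})/\tau} + e^{s(Q_{ca},V_{ca})/\tau}}
{e^{s(Q_{bg},V_{bg})/\tau} + e^{s(Q_{bg},Q_{ca})/\tau} +
 e^{s(Q_{bg},V_{ca})/\tau} + e^{s(V_{bg},Q_{ca})/\tau} +
 e^{s(V_{bg},V_{ca})/\tau}}.$$

Note the denominator omits the $(Q_{ca}, V_{ca})$ positive term that a
textbook InfoNCE would include; the `symmetric_denominator` flag adds it but
is off by default, preserving the printed form. When all four prototypes
coincide the loss is $-\log(2/5)$, which the tests pin down. Teacher
prototypes are constants; gradients flow only into the student. Scales where
either model assigns zero probability mass to a class are skipped and the
remaining weights $\beta = (0.6, 0.3, 0.1)$ (finest first, summing to 1) are
renormalized for that step.

## Loss assembly and schedule

$$\mathcal{L} = \mathcal{L}_s + \lambda\,\omega(t)\,
  (\mathcal{L}_{csy} + \mathcal{L}_{MS\text{-}CL}), \qquad
  \omega(t) = 0.001\, e^{-5 (1 - t/t_\text{max})^2},$$

where $\mathcal{L}_s$ is the mean of pixel cross-entropy and Dice loss
(smoothing $10^{-5}$) on the labeled tile. $t$ counts iterations and
$t_\text{max}$ is the full planned horizon. $\lambda$ has no prescribed
value; the package default is 1. Optimization is SGD (learning rate 0.01,
momentum 0.9), batch parity one labeled + one unlabeled tile per step, the
teacher updated by EMA after every step, and the checkpoint with the highest
validation Dice retained.

## The synthetic tile generator

`generate_dataset()` emulates the statistical structure of an H&E tile
collection so the whole pipeline runs without any download: pink-ish stroma
background and purple-ish tumor coloration with channel-correlated texture
noise and a slow staining drift; smooth connected tumor blobs; a configurable
fraction of tumor-free tiles (default 569/1020, matching the composition the
exclusion filter is designed around); and full bit-reproducibility from one
seed. Blobs are built from a Gaussian-smoothed random field: the superlevel
component containing the field maximum is selected and its threshold found by
bisection so the blob area hits a target fraction drawn from
`tumor_area_range` (component area is monotone in the threshold because
superlevel sets nest; at component-merge jumps the candidate closest to the
target inside the configured range is kept). Tiles default to 640 px; tests
and examples use 32–64 px tiles, which changes nothing structurally.

What the generator deliberately does **not** emulate: across-tile stain
variability, nuclear morphology, tissue architecture, or the intensity
statistics of any real scanner. One consequence matters for interpreting the
test suite: the synthetic task is nearly pixel-color-separable, so even two
labeled tiles carry essentially complete class-color information. The
direction-of-effect study in the acceptance suite (10% labels, equal
labeled-update and checkpoint-selection budgets in both arms, EMA decay
scaled to the short horizon, $\lambda = 100$ so the ramped unsupervised
weight is non-negligible over 90 steps) therefore measures differences that
sit within seed-to-seed noise on this generator: passing or failing it says
little about real tissue, where labeled scarcity genuinely underdetermines
the stain distribution and the published benefit was observed over ~300×
longer horizons. The study is retained at the stated conditions rather than
redesigned around its outcome.

## Numerical and engineering choices

* **Autodiff core.** No deep-learning framework is used; the package carries
  a small tape-based reverse-mode autodiff engine over dense arrays.
  Convolutions are im2col + BLAS matrix products; bilinear upsampling is a
  separable linear operator whose backward pass is the exact adjoint;
  max-pool ties break to the first block in scan order; arg-max class ties
  break to the first class. All gradients are verified against central
  finite differences in the tests.
* **Strictness and guards.** Both uncertainty thresholds compare strictly;
  empty masks short-circuit the consistency loss to 0; cosine similarity
  raises an error on zero-norm prototypes; metrics on empty masks are
  reported as undefined (`NA`) with a warning and excluded from averages.
* **HD95.** Boundary pixels are extracted by 4-connectivity erosion; the two
  directed nearest-neighbour distance sets are pooled and their 95th
  percentile reported in pixel units (the common surface-distance
  convention). Because Dice is concave in Jaccard, per-image
  $DSC = 2J/(1+J)$ holds exactly while fold-averaged Dice generally differs
  from the identity applied to fold-averaged Jaccard; `aggregate_reports()`
  documents this.
* **Problem sizes.** Unit tests run on 32 px tiles with a 4-channel
  3-level model; the acceptance suite uses 64 px tiles (20 training tiles)
  for the training study and 1,020 × 64 px tiles for the exclusion-filter
  count. These sizes are the package's chosen desk-scale study conditions.

## Limitations

The pure-R training core is practical for tiles up to ~128 px and the small
models used here, not for full-scale 640 px training runs. Whole-slide
pyramids, stain normalization, multi-GPU training and pretrained encoders
are out of scope. The five-fold orchestration is available through
`split_semi()` but benchmark-scale cross-validation on real data is expected
to be run with substantially larger compute than the test suite uses.
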