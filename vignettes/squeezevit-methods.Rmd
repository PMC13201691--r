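---
title: "SqueezeViT: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SqueezeViT: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Multi-label chest-radiograph classification assigns, to one grayscale
radiograph, an independent binary indicator for each of 14 findings
(atelectasis, cardiomegaly, effusion, ...), with a `"No Finding"` sentinel
marking normal studies. Clinically deployable models must run on modest
hardware, which motivates architectures that are aggressively
parameter-efficient while still capturing both local texture and global
anatomical context.

SqueezeViT combines two such mechanisms:

* **Fire modules** (from the SqueezeNet family) learn local representations
  cheaply. A module first *squeezes* its input through a 1×1 convolution to
  `C_s = max(1, floor(C_in/2))` channels,

  \[ X' = \mathrm{ReLU}(W_s * X + b_s), \]

  then *excites* through parallel 1×1 and 3×3 convolutions whose outputs are
  channel-concatenated,

  \[ F_{out} = \mathrm{Concat}(e_{1\times1},\; e_{3\times3}), \]

  with each branch producing half of the target output width. Because the
  3×3 kernels see only `C_s` input channels, a Fire module `C_in -> C_out`
  is strictly cheaper than a plain 3×3 convolution of the same widths for
  every `C_in >= 4` (asserted by closed form in the tests).

* **The Translution Block** supplies global context in the MobileViT style.
  The 28×28×128 Stage-2 map is expanded by a Fire module to 256 channels and
  squeezed by a second Fire module to 64-channel *tokens*; the map is then
  partitioned into 4×4 patches (`P = h·w = 16` pixel offsets,
  `N = HW/(hw) = 49` patches) and rearranged, order-preservingly and without
  positional embeddings, into `P` sequences of `N` tokens. A transformer
  encoder applies scaled dot-product attention

  \[ \mathrm{Attention}(Q, K, V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d_k}}\right) V \]

  across patches at each pixel offset. The encoded tokens are folded back,
  projected by a 1×1 convolution to 128 channels, concatenated with the
  block input (`C_{output} = 2C`), and fused back to `C` by a final Fire
  module. The block is therefore shape-preserving end to end.

The full network is: stem (3×3 conv to 3 channels, stride 2; 3×3 max pool,
stride 2) → Stage 1 (Fire Block, plan 3→32→64→64→128, terminated by a 3×3
max pool) → Stage 2 (Translution Block) → Stage 3 (Fire 128→256, 3×3 max
pool, 1×1 conv 256→256, global average pooling, fully connected head to `L`
logits). The spatial ledger for a 224×224 input is
224 → 112 → 56 → 28 → 28 → 14 → 1, so the 4×4 patch grid divides the
Stage-2 map exactly.

Patch size 4×4 rather than 2×2 is the block's efficiency lever: with
per-offset sequences, total attention-score cost is
`P · N² · d_k ∝ (HW)²·d_k/(hw)`, so quadrupling the patch area cuts both the
token count per sequence and the attention FLOPs by exactly 4× (the
`patch_tradeoff()` calculator reproduces this identity).

## Choices the architecture description leaves open

Several details are not fixed by the architecture's published description;
this package resolves them as follows and treats them as its own design.

* **Attention scaling.** The score normaliser is `1/sqrt(d_k)` — the form
  standard practice and the gradient-saturation argument both support —
  rather than `1/d_k`.
* **Encoder geometry and the parameter budget.** The encoder's depth, head
  count and widths are free parameters; the binding constraint adopted here
  is the architecture's printed budget of 0.54 × 10⁶ trainable parameters.
  With depth `L = 2`, 4 heads of `d_k = d_v = 16` on 64-dimensional tokens,
  feed-forward hidden width 64 (ratio 1), pre-norm residual sublayers and
  LayerNorms on encoder entry and exit (MobileViT likewise closes its
  transformer stack with a LayerNorm), the default model has exactly
  539,136 parameters = 0.54 × 10⁶ at two decimals. A 2·d feed-forward width
  would overshoot the budget (0.56 × 10⁶); ratio-1 feed-forwards are common
  in the smallest mobile transformer variants.
* **Projection-then-concatenation.** "Merged back ... through a 1×1
  convolution, followed by channel-wise concatenation" is read as
  project-then-concatenate; it is the only order that yields
  `C_output = 2C`.
* **3×3 excitation padding.** The excitation branches must agree spatially
  for the concatenation, so the 3×3 branch uses stride 1, padding 1.
* **Squeeze width for odd inputs.** `C_s = floor(C_in/2)` clamped to ≥ 1
  (the stem emits 3 channels, so Stage 1's first squeeze width is 1).
* **Stem and pool strides.** The stem convolution and all 3×3 max pools use
  stride 2, padding 1, floor mode — the only combination that produces the
  ledger above and an exact patch grid.
* **Initialisation.** Kaiming fan-in normal weights for ReLU layers,
  Xavier-style `1/fan_in` for linear projections, zero biases — with two
  exceptions around the squeeze bottleneck. Squeeze biases start at 0.1, and
  a width-1 squeeze initialises with half-normal (positive) weights, i.e. as
  a weighted channel average. The squeeze input is non-negative (it follows
  a ReLU), so a one-channel squeeze whose random weights all land negative
  is silenced by its own ReLU for *every* input and no gradient can revive
  it — the whole network is then constant at initialisation. Positive
  initial weights make the bottleneck live for every seed; training is free
  to change their signs afterwards.
* **Ablation plans.** The Stage-1 module-count variants (N = 1, 8, 16) have
  no published channel plans; the package interpolates geometrically from 3
  to 128 and rounds interior widths to even numbers so every excitation
  splits cleanly. `no_translution` removes Stage 2 entirely (identity
  pass-through at 128 channels).
* **Dropout** defaults to 0 (never mentioned in the protocol) and is exposed
  in `attention_spec()`.

## Training and evaluation protocol

`train_spec()` defaults encode the reference recipe: sigmoid binary
cross-entropy on logits (evaluated in the stable `max(z,0) − zy +
log(1+e^{−|z|})` form), Adam with learning rate 1e-4 and default moments,
batch size 64, up to 100 epochs, training from scratch, no schedule, no
weight decay, no early stopping. The `micro_batch` option slices each batch
for memory; gradients are accumulated so the update is mathematically the
full-batch step (asserted in the tests).

Evaluation reports class-wise AUROC (Mann–Whitney midrank form: the
probability a random positive outranks a random negative, ties counted
half), the arithmetic mean over classes with both labels present, and macro
F1 at threshold 0.5 (a class with no true and no predicted positives
contributes 0). Binary normal/abnormal mode relabels a record abnormal
unless it is exactly `"No Finding"` and retrains with a single-logit head;
the max-over-classes score of a multi-label model is available as an
explicitly non-protocol utility. Confidence intervals use a nonparametric
case-resampling percentile bootstrap (B = 2000 by default) — no CI method is
published for the reference results, and the bootstrap is assumption-light
and testable: a Monte-Carlo experiment in the test suite checks ≥ 90%
empirical coverage at nominal 95% on a known-AUROC binormal model.
Undefined-AUROC resamples are redrawn up to 10 times, then skipped with a
reported count.

Splits are uniform random 80/20 at image level (`split_dataset()`), the
reading closest to "split randomly"; a patient-level option exists because
public CXR collections share patients across images, but it is not the
default and requires an explicit `patient_id`.

## The synthetic data generator

Real CXR collections cannot be bundled, so `generate_synthetic()` fabricates
datasets with the structural features the pipeline must handle: 224×224
single-channel images in `[0,1]`, 14 binary labels with class imbalance and
positive co-occurrence, and a deterministic pixel-level link between labels
and image content. Each class owns one fixed geometric template (Gaussian
blobs, rings, bars, a cross — all at distinct locations); an image is
background 0.25 plus amplitude 0.5 times each positive class's template plus
`N(0, sigma²)` pixel noise (sigma 0.1 by default), clipped to `[0,1]` and
quantised to 8 bits so written PNGs round-trip exactly. Labels follow a
latent-severity model: class `k` of image `i` is Bernoulli with probability
`plogis(qlogis(prev_k) + c·u_i)`, `u_i ~ N(0,1)`, so `c = 0` gives
independent labels and the default `c = 0.75` gives the positive
co-morbidity correlation real finding labels show. Default prevalences fall
from 0.30 to 0.08 across classes, mimicking the long-tailed frequency
profile of public CXR label distributions at a desk-runnable scale.

Fixture validity is established independently of any trained model by a
matched-filter oracle: correlating each template against each image must
separate each class nearly perfectly (mean AUROC > 0.95 at sigma 0.1), and
oracle separability must fall monotonically as sigma grows. Amplitude,
background and noise defaults were fixed once, when the generator was
designed, to make the planted patterns about as conspicuous as an obvious
finding on a radiograph; they are study conditions, not tuning knobs.

What passing on this generator shows — and does not show: it demonstrates
that the architecture, gradients, optimiser and metrics are correctly wired
and can learn localized, class-specific structure from pixels; it says
nothing about performance on real radiographs, where findings vary in
position, scale and texture, labels are noisy, and domain shift dominates.

## Numerical choices

Convolutions run as float32 im2col + BLAS sgemm (channels-last layout) with
gradients accumulated back into float32 products; everything else — layer
norms, attention softmax (computed with the max-subtraction trick),
losses, Adam state — is double precision. Single precision roughly doubles
single-core gemm throughput and is far below the noise floor of SGD
training; the test suite's convolution oracle bounds the forward error at
1e-5 absolute on unit-scale inputs, and all determinism contracts
(bit-identical reruns under a fixed seed and thread count) hold because
every kernel is sequential. Max pooling records argmax indices for exact
backprop; ties break toward the first element in column-major window order.
LayerNorm uses eps 1e-5. If a feature map is not divisible by the patch
side, unfolding zero-pads on the bottom/right and folding crops back — the
default pipeline never triggers this path.

## Problem sizes used in the checks

The complexity claims are exact integer arithmetic and run in seconds. The
learning smoke experiment uses 200 synthetic images at the generator
defaults, 15 epochs of the standard recipe, micro-batch 25 — a scale chosen
so the full suite remains desk-runnable on one CPU core. Note what this
scale implies: at batch size 64, fifteen epochs are only 60 Adam updates,
and at learning rate 1e-4 each update moves a parameter by at most about
the learning rate, so a from-scratch network can demonstrate clear descent
and well-above-chance ranking within the smoke budget but not convergence.
Continuing the same run to the recipe's full 100 epochs (400 updates)
raises mean training AUROC to 0.80, still improving when the schedule ends.
The network itself can fit these data essentially perfectly — a
memorisation probe with a freer optimiser budget (20 images, 300 full-batch
updates at ten times the learning rate) drives training AUROC above 0.999 —
so the plateau is a property of the protocol at fixture scale, not of the
architecture or its gradients. The recipe's values are part of the protocol
and are not altered; at reference scale the same schedule delivers three
orders of magnitude more updates per epoch. The bootstrap
coverage experiment uses n = 500, 200 Monte-Carlo repetitions at B = 600
replicates. Reported AUROC values on synthetic data are training-set values
by design: the smoke test asks whether the optimiser can fit planted
structure, not whether it generalises.

## Known limitations

* No GPU path and no parallelism; wall-clock scale is hundreds of images,
  not the 10⁵-image public collections.
* No data augmentation, learning-rate schedules or early stopping — the
  reference protocol specifies none, and none are needed at fixture scale.
* The MAC accounting reports the raw multiply-accumulate count and its
  ×10⁹ form; published MAC figures for this architecture are internally
  inconsistent between sources of the same document, so no acceptance
  quantity is pinned to them.
* Attention maps are computed but no interpretability/visualisation surface
  is provided.
* Pretrained weights and detection/localization heads are out of scope.
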