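---
title: "Adversarial dense-block segmentation: model, phantoms, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial dense-block segmentation: model, phantoms, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ganseg trains and evaluates an adversarial segmentation model for 2D CT
slices. This vignette is the package's account of the science: the model and
its objective, the synthetic phantoms that make the pipeline self-contained,
the evaluation metrics, the numerical conventions, and the design choices
made where the design was genuinely open.

## The segmentation problem

Kidney delineation on abdominal CT is a binary, per-pixel labelling task.
Two features make it harder than generic blob segmentation: slices may show
one kidney, both, or none, and the renal collecting system — a hollow
structure in the middle of the organ — does not belong to the kidney label,
so a good model must carve an interior boundary with little edge contrast.
Plain per-pixel losses are often blind to such structural mistakes; an
adversarial critic that sees whole (image, mask) pairs is one way to supply
that structural signal.

## Model

Two networks are trained against each other.

**Generator** `G`: a fully convolutional encoder–decoder with a U-Net-like
topology. A 3×3 stem convolution is followed by three encoder stages of
*dense block → 1×1 transition → 2×2 max pool*, and three decoder stages of
*2×2 transposed convolution → skip concatenation → dense block → 1×1
transition*, closed by a 1×1 convolution and a sigmoid. Each dense block
applies four units of *batch-norm → ReLU → 3×3 convolution* and concatenates
every unit's output onto its input, so a block maps `c` channels to
`c + 4·growth`. The sigmoid makes the output a per-pixel foreground
probability, which the soft-Dice term requires. One built network accepts
any input whose sides are divisible by 8 (three pooling stages) and
preserves the spatial size.

**Discriminator** `D`: a six-layer multi-scale feature extractor. Every
layer is *convolution → batch-norm → leaky ReLU (slope 0.2)*; the kernel
schedule is `7, 5, 4, 4, 3, 3` with stride 2 on the first four layers. Its
input is the channel-concatenation of the image and a mask, so it judges a
mask *in the context of its slice*. It returns the ordered list of all six
feature maps (the feature pyramid `f_D`) plus a scalar real/fake score from
a global-average-pool head.

## Objective

For a batch of images `x_i` with ground-truth masks `y_i`, the generator
minimises

    L_G = (λ/N) Σ_i E_dice(G(x_i), y_i)  +  (δ/N) Σ_i E_mae(f_D(x_i, y_i), f_D(x_i, G(x_i)))

with the smoothed negative soft-Dice term

    E_dice(p, y) = −(2 Σ p·y + ε) / (Σ p + Σ y + ε)

and the multi-scale mean-absolute-error term `E_mae`, the mean absolute
difference between the two feature pyramids. The discriminator maximises the
MAE component, so its minimised loss is the exact negation of the δ-weighted
MAE — the two players are zero-sum on the shared component, which the test
suite asserts literally on logged training histories.

Conventions where the formulation leaves room:

* `E_dice`'s inner sum is read as a per-pair pixel sum (the per-item value
  lies in `[−1, 0]`, `−1` at a perfect match, including the all-empty case
  forced by ε).
* `E_mae` averages within each pyramid level and then across levels, so deep
  small maps and shallow large maps contribute equally. Pooling all elements
  into one mean would overweight the large shallow maps.
* The discriminator trains on the feature-MAE term only. Its scalar head is
  built, exposed and differentiable, but no binary cross-entropy signal is
  attached by default: the composite objective above is the whole game. The
  classical GAN value function is provided as `gan_value()` for reference
  and testing only.
* λ = δ = 1 and ε = 1 are the defaults; all three are configurable through
  `loss_weights()`.

## Training procedure

Per batch: the discriminator takes one SGD step minimising its (negated MAE)
loss on `(x, y)` versus `(x, G(x))` with the generator output held fixed;
then the generator takes one step against the *updated* discriminator,
receiving both the Dice gradient and the adversarial gradient that flows
back through `D`'s features into the mask channel of its input. The
optimiser is stochastic gradient descent with momentum — learning rate
`1e-4`, weight decay `1e-4`, momentum `0.9`. That triplet of reference
settings is the only reading consistent with a named learning rate, weight
decay *and* momentum, and it is kept verbatim as the default; adaptive
optimisers are deliberately not implemented. Weight decay applies to
convolution weights only (not biases or batch-norm parameters), the usual
convention.

Every random draw — phantom geometry, weight initialisation, shuffling —
goes through R's RNG, so a fixed seed reproduces a run bit-exactly on a
single CPU thread. Non-finite losses abort with the offending term and
epoch rather than being clipped: at desk scale, failures should be loud.
Validation curves track the soft Dice (the negated `E_dice`), while hard,
thresholded DSC is reserved for evaluation — mirroring the usual split
between a training signal and a reported metric.

## The phantom generator

`phantom_config()` / `generate_dataset()` produce seeded, kidney-like
slice/mask pairs so the whole pipeline runs without any external data:

* one or two rotated ellipses per slice (a configurable subset of 0–2), with
  two-region slices placing one ellipse in each image half like the two
  kidneys on an axial slice;
* semi-axes drawn from 8–16 px on a 64×64 canvas, uniformly random rotation;
* with probability 0.5, a concentric interior ellipse at 0.4 of the region's
  semi-axes is carved out of the mask *and* painted at background intensity —
  the collecting-system analogue and the hard case the adversarial term is
  meant to help with;
* foreground mean 0.65, background 0.25, additive Gaussian noise with sd
  0.08 (a contrast-to-noise ratio around 5, a realistic soft-tissue regime),
  clipped to [0, 1].

Each pair is generated from an RNG stream derived from `(seed, index)`, so
datasets are order-independent and any pair can be regenerated alone.

What the phantoms deliberately do **not** emulate: anatomical shape detail,
partial-volume edges, streak or ring artefacts, intensity inhomogeneity, 3D
continuity across slices, and tumour sub-labels. Passing the desk-scale
tests therefore demonstrates that the architecture, losses, training loop
and metrics interact correctly — not that the model generalises to clinical
CT. The NIfTI path in `load_volume()`/`slice_dataset()` exists for real
volumes; its preprocessing is plain 2D axial slicing with Hounsfield-unit
windowing (default window [−200, 300] HU mapped affinely to [0, 1]) and an
optional resize — bilinear for images, nearest-neighbour for masks. The
overlapping-patch scheme sketched in the original description of the
challenge data is ambiguous for a 2D model and was consciously replaced by
this simpler scheme.

## Evaluation metrics

Six per-slice metrics, aggregated as mean, sample sd, max and min:

* **DSC** `2TP / (2TP + FP + FN)`;
* **VOE** `(1 − |A∩B| / |A∪B|) · 100%` (one minus Jaccard, in percent);
* **ASD**: surfaces are foreground pixels with a background 4-neighbour
  (border counts as background; 8-connectivity by flag), distances are
  pixel-centre Euclidean distances in physical mm (anisotropic spacing
  supported), and the symmetric mean over both surfaces is returned. The
  implementation uses an exact Euclidean distance transform; the test suite
  keeps an all-pairs brute-force oracle as ground truth.
* **ACC, SEN, SPE** from the confusion counts.

Degenerate cases are declared, flagged, and never silently imputed: both
masks empty gives DSC 1 / VOE 0 (with a `both_empty` flag in the per-slice
table); ASD with an empty surface is `NA`, excluded from aggregation with a
warning; a zero-denominator SEN/SPE is `NA`. Predictions are binarised at
0.5 by default (configurable). Paired per-slice comparisons between two
models use the two-sided Wilcoxon signed-rank test with zero differences
dropped; an all-zero difference vector returns p = 1 with a warning rather
than an error.

## Numerical choices

* ε = 1 in the Dice term: the conventional smoothing constant; any ε > 0
  yields the same −1 limits asserted in the tests.
* Max-pool ties resolve to the first maximum in column-major order — fixed,
  so backward passes are deterministic.
* He-normal weight initialisation (fan-in), zero biases; batch-norm starts
  at identity (γ = 1, β = 0) with running statistics updated at momentum
  0.1 and used in evaluation mode.
* Inputs not divisible by 8 are rejected in the low-level pass and
  symmetrically zero-padded (then cropped) in `predict_slices()`.
* The convolution, transposed-convolution, pooling, batch-norm and fused
  dense-block kernels are C++ (RcppArmadillo) and are verified in the test
  suite against naive R implementations and central-difference gradients.

## Design choices on open points

* **Final activation**: sigmoid — never named in the original formulation,
  but a probability map is required by the soft-Dice term.
* **Skip connections**: concatenation (the U-Net convention) rather than
  addition.
* **Encoder transitions**: 1×1 convolutions halving channels before each
  pool, DenseNet-style compression that keeps channel growth bounded.
* **Discriminator schedule**: the four listed kernel sizes are assigned to
  six layers as `[7,5,4,4,3,3]` with strides `[2,2,2,2,1,1]` — a declared,
  configurable default.
* **Update order**: D then G, 1:1; no schedule is stated in the source
  formulation.
* **Network widths**: base 6 channels, growth 3, decoder width 12 by
  default. Widths are free parameters of the architecture; these defaults
  are sized so the full desk-scale experiment (200 phantoms at 64×64, 12
  epochs, 70/15/15 split) trains in about three minutes on one CPU while
  converging comfortably on the phantom task. All widths scale up through
  `generator_config()` / `discriminator_config()`.
* **Validation loss**: the full composite objective in evaluation mode;
  validation Dice is soft Dice, so the curves match the training signal.

## Problem sizes used by the checks

The test suite exercises metrics on 100 random 32×32 mask pairs against
brute-force oracles, gradient-checks every layer and both assembled networks
on tiny tensors, and runs the desk-scale experiment (200 phantoms, 64×64,
≤ 30 epochs) with a held-out mean DSC ≥ 0.85 bar plus a Dice-only ablation
(δ = 0) required to land within 0.05 — evidence that the adversarial term
does not destroy convergence at this scale. `scripts/acceptance.R` re-runs
the same experiment from scratch at a caller-supplied seed and writes the
held-out metrics as JSON.

## Known limitations

* Desk-scale widths and phantom simplicity mean results here say nothing
  quantitative about clinical CT benchmarks; the real-data path is provided
  but untuned.
* The discriminator's scalar head is unused by the default objective; no
  cross-entropy variant is implemented.
* 2D only: no 3D convolutions, no volumetric ASD; per-slice metrics are
  averaged, the 2D reading of slice-wise evaluation.
* Single-threaded CPU training only; no GPU, mixed precision, or
  distributed support.
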