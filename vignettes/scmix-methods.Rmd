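---
title: "The hybrid multipath ConvMixer–Swin classifier: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid multipath ConvMixer-Swin classifier: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmix)
```

## The problem and the model

White blood cells (leukocytes) are classified into subtypes — neutrophils,
eosinophils, basophils, lymphocytes, monocytes, and in some datasets immature
granulocytes, platelets and erythroblasts — by morphology: the number of
nuclear lobes, the nucleus-to-cytoplasm area ratio, and staining color.
Automating this from single-cell microscopy images is a standard
image-classification task with one twist: the discriminating features mix
fine local texture (stain granularity, membrane detail) with longer-range
spatial relations (where the nucleus sits relative to the cytoplasm, how
lobes are arranged).

`scmix` implements a hybrid architecture that addresses both scales
explicitly, in three stages:

**Stage 1 — multipath ConvMixer (MPCM).** Three ConvMixer branches run in
parallel at patch sizes $p = 2, 4, 8$. Each branch embeds the image with a
convolution whose kernel and stride both equal $p$ ($h$ filters, GELU, batch
normalization),

$$z_0 = \mathrm{BN}(\sigma(\mathrm{Conv}_{\text{kernel}=p}^{\text{stride}=p}(\text{image}))),$$

then applies `depth` depthwise-separable mixer blocks

$$z' = \mathrm{BN}(\sigma(\mathrm{DepthwiseConv}(z))) + z,\qquad
z^{+} = \mathrm{BN}(\sigma(\mathrm{PointwiseConv}(z'))),$$

with the residual connection around the depthwise stage only. Branch outputs
at $1/2$, $1/4$ and $1/8$ resolution are brought to the common $1/2$ grid by
parameter-free nearest-neighbor upsampling (strides 2 and 4) and fused by
element-wise addition. At the full-scale defaults (224×224×3 input, $h=128$,
depth 4) the fused map is $112\times112\times128$.

**Stage 2 — multipath Swin (MPST).** Two windowed-attention branches
tokenize the fused map at different granularities. Patch extraction is a
$1\times1$ convolution to $k = D/p_e^2$ channels followed by non-overlapping
$p_e \times p_e$ patching, so every token has width $D = 256$ regardless of
the branch. Each branch then runs full Swin cycles

$$\hat z = \mathrm{WMSA}(\mathrm{LN}(z)) + z,\quad
z' = \mathrm{MLP}(\mathrm{LN}(\hat z)) + \hat z,\quad
\hat z' = \mathrm{SWMSA}(\mathrm{LN}(z')) + z',\quad
z'' = \mathrm{MLP}(\mathrm{LN}(\hat z')) + \hat z',$$

where W-MSA restricts self-attention to non-overlapping windows and SW-MSA
repeats it after a cyclic roll of the token grid, with an additive mask that
forbids attention between tokens that were not spatially contiguous before
the roll. The two branch token matrices are concatenated along the token
axis; at the defaults the $28\times28$ and $14\times14$ grids give
$784 + 196 = 980$ tokens of width 256.

**Stage 3 — head.** Global average pooling over the token axis, a fully
connected layer with one output per class, and a softmax. Training minimizes
the categorical cross-entropy $L = -\sum_k Y_k \log P_k$ (batch mean) with
Adam.

The implementation is self-contained vectorized R with the hot inner loops
(depthwise taps, GELU, batch-normalization statistics) in compiled C++;
forward *and* backward passes are hand-derived and validated against central
finite differences in the test suite for all seven architecture variants.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `input_size` | 224 px | input side; forced by the 112×112 fused-map geometry together with the $p=2$ branch |
| `mpcm_patches` | 2, 4, 8 | ConvMixer branch patch sizes (px) |
| `filters` | 128 | ConvMixer width $h$ |
| `depth` | 4 | mixer blocks per branch |
| `dw_kernel` | 3 | depthwise kernel side |
| `mpst_grids` | 28, 14 | token-grid sides of the Swin branches |
| `token_dim` | 256 | token width $D$; sets $k = D/p_e^2$ |
| `window` | 7 | attention window side (divides both default grids) |
| `shift` | 3 | cyclic shift, $\lfloor 7/2 \rfloor$ |
| `heads` | 4 | attention heads (head width 64 at $D=256$) |
| `mlp_dim` | 256 | transformer MLP hidden width |
| `dropout_rate` | 0.1 | MLP dropout |
| `learning_rate` | 1e-4 | Adam step size (full scale) |
| `batch_size` | 16 | minibatch size |
| `epochs` | 100 | full-scale budget |

Where the architecture's published description leaves a value open, the
package fixes it once and documents it here:

* **Window 7, shift 3, 4 heads, relative position bias on.** 7 divides both
  default grids (28, 14); 4 heads divide $D=256$ evenly; the learned relative
  position bias per head is standard in windowed attention and can be
  disabled (`use_relative_bias = FALSE`).
* **Stated patch sizes vs. printed token shapes.** The prose configuration
  gives Stage-2 patch sizes 2 and 4, which on a 112-wide map would produce
  3136 and 784 tokens of widths 1024 and 4096 — inconsistent with the printed
  token matrices ($784\times256$, $196\times256$) and their 980-row
  concatenation. The printed shapes win: the defaults use effective patch
  sizes 4 and 8 (grids 28 and 14). `mpst_grids` is exposed so the other
  reading remains runnable.
* **"Applied twice."** The Stage-2 description applies the Swin operation to
  each branch twice; one cycle already contains both W-MSA and SW-MSA, so
  "twice" could mean one or two full cycles. The default is two full cycles
  per branch (`cycles_per_branch = 2`).
* **Aggregation is addition.** Branch fusion is element-wise addition (not
  concatenation), matching the element-based aggregation wording and keeping
  the channel count at $h$.
* **Upsampling is nearest-neighbor** — parameter-free, so fusion adds no
  learned weights.
* **Residual placement.** The mixer block places the residual around the
  depthwise stage only, following the block equations literally; depthwise
  convolutions use "same" zero padding so the addition is shape-consistent.
* **Model 2 / Model 5 tokenization.** The Swin-only ablation variant
  tokenizes the raw image with a single branch on the first configured grid;
  the MPST-only variant first lifts the image to `filters` channels with a
  $1\times1$ convolution. Effective patch sizes double on the full-resolution
  input, and the $k = D/p_e^2$ integrality constraint is validated per
  variant at build time.

## Numerical choices

* GELU is the exact erf-based form $x\Phi(x)$.
* Softmax subtracts the row maximum; cross-entropy clamps probabilities to
  $[10^{-7}, 1]$, so the loss is always finite.
* Layer normalization acts over the embedding axis with $\varepsilon=10^{-5}$.
* Batch normalization is per-channel with momentum 0.9 and
  $\varepsilon=10^{-5}$; inference uses running moments. Running moments are
  seeded from the first training batch rather than from (0, 1): activations
  after truncated-normal initialization (sd 0.02) have variances orders of
  magnitude below 1, and a unit-variance prior would otherwise dominate the
  running estimate for hundreds of steps, making early-epoch validation
  meaningless and best-checkpoint selection unstable.
* The shifted-window mask value is $-10^9$, which zeroes masked weights to
  double precision.
* Weights are truncated-normal (sd 0.02, resampled beyond $\pm 2$ sd), biases
  zero; initialization is seedable and every stochastic step (shuffling,
  dropout) derives from the single training seed, so runs are bit-for-bit
  reproducible on one machine.
* Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-7}$.
* Argmax prediction breaks ties toward the lowest class index.
* Checkpoint selection keeps the epoch with the highest validation accuracy
  (including its batch-normalization running moments).

## The synthetic data generator

Real single-cell datasets are large external downloads; the package instead
ships a deterministic generator (`synthetic_spec()`, `make_dataset()`,
`write_dataset()`) whose images emulate the morphology axes that define the
real classes: an elliptical cytoplasm, 1–3 overlapping nucleus lobes whose
union area is driven to a class-specific nucleus/cell ratio by bisection on
the rendered mask, class-specific stain hues, and additive Gaussian pixel
noise. Presets `wbc4`, `wbc5`, `wbc8` mirror the class counts of the three
public benchmark datasets; `easy3` is a deliberately well-separated 3-class
set for capability checks.

What the generator does *not* emulate: stain variability and illumination
gradients, touching or occluded cells, red-cell backgrounds, focus blur, and
class imbalance beyond a `class_weights` multiplier. Passing tests therefore
demonstrate that the architecture, optimization, and evaluation machinery are
correct and that the model can learn color/shape-separable classes — they say
nothing about accuracy on real blood smears, which requires the external
datasets and full-scale training.

## Problem sizes used by the test suite

The package's own checks run at a reduced "desk" scale chosen to exercise
every component on a CPU: `desk_preset()` uses 112-pixel inputs, 32 filters,
depth 2, token grids 14/7 with 64-wide tokens (so $k$ stays integral), window
7, and 30 epochs at learning rate $10^{-3}$ — the conventional Adam step size
for training a small model from scratch; the full-scale $10^{-4}$ belongs to
the 100-epoch regime. The learning-capability check trains the full variant
on 40 `easy3` images per class (70/15/15 split) and requires at least 90%
validation accuracy within 30 epochs; training stops early once the target is
reached. The ablation check runs all seven variants at 56-pixel inputs for
two epochs each — enough to produce the comparison table; relative orderings
between variants are not asserted at this scale. The structural check builds
the full-scale default model and verifies the 980×256 concatenated token
matrix on a real forward pass.

## Known limitations

* Pure-R + small-C++ execution is orders of magnitude slower than a GPU
  framework; full-scale 100-epoch training on the real datasets is out of
  reach here by design. The package's claims are correctness claims.
* No data augmentation, learning-rate scheduling, or early stopping are
  applied by default (an optional validation-accuracy target can stop
  capability runs early).
* Hierarchical patch merging of the original Swin design is out of scope; the
  token grids are fixed per branch.
* The per-class "accuracy" in reports is one-vs-rest accuracy
  $(TP+TN)/\text{total}$, which exceeds pooled multi-class accuracy whenever
  any off-diagonal confusion exists and there are more than two classes —
  macro summaries aggregate it unrounded and round only for display
  (half-up, two decimals).
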