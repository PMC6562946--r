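---
title: "Dense nuclei instance segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense nuclei instance segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucseg)
```

## The problem

Nuclei in histopathology and fluorescence microscopy are small (areas of a
few tens to roughly a thousand pixels), dense (often more than 25 and on
average more than 40 per image, up to several hundred), and frequently
adhering or overlapping. Two-stage detect-then-segment models handle the
instance separation well, but their classification-style backbones
downsample aggressively: by the deepest stage a 10-pixel nucleus has been
reduced below one feature cell and is effectively invisible to the proposal
and mask heads. `nucseg` implements an instance segmentation pipeline built
around a backbone that trades late-stage downsampling for dilation, so that
deep, semantically strong features keep a fine spatial grid.

## Multi-path dilated residual blocks

The unit of the backbone (`multipath_block_spec()`, `build_block()`) is a
bottleneck residual block whose middle 3×3 stage is replaced by parallel
dilated 3×3 convolutions. A dilated convolution with expansion rate $r$
spaces its kernel taps $r$ pixels apart, multiplying the receptive field
without touching the resolution; rate 1 is exactly a standard convolution.
The default rate set is $(1, 2, 5)$:

* the rate-1 path plus the shortcut is weight-for-weight an ordinary
  bottleneck residual block (tested to `1e-5`);
* rates 2 and 5 widen the receptive field for larger context;
* mixing odd and even rates removes the *gridding artifact*: stacking
  convolutions that share an even rate leaves input positions that never
  contribute to any output. `coverage_map()` demonstrates this by exhaustive
  tap-chain enumeration — three stacked rate-2 convolutions leave 71% of
  their receptive field with zero contribution, while a (1, 2, 5) stack
  covers every position.

Paths are merged by channel concatenation before the restoring 1×1
convolution (a summation merge is available); "same" padding of
$r(k-1)/2$ keeps stride-1 layers size-preserving, which every shape claim
of the design relies on.

**Depth counting.** Depth names (16, 64) count weight layers the way
residual networks are conventionally named: the stem convolution, plus per
block the reducing 1×1, one layer for the (parallel) dilated stage — paths
add width, not depth — and the restoring 1×1. Pooling and projection
shortcuts are not counted. Under this convention the classical 50-layer
bottleneck shape counts 49 convolutions (`resnet50_shaped_config()`), the
deep preset (3/4/6/8 blocks) counts 64, and the small preset (1/1/1/2
blocks) counts 16.

**Stride plan.** The deep preset (`d_resnet64_config()`) uses a stem of one
stride-2 max pooling ("down sampling layer") plus a 3×3 stride-2
convolution, then a single further ×2 downsample at stage 2: total output
stride 8. Stages 4 and 5 widen their receptive fields with stage-level
dilation 2 and 4 instead of striding, so stages 3–5 share one spatial size.
Output channels stop growing at 256 (the channel cap), bounding model size
as depth grows. The stem operator is realized as max pooling; the design
only fixes that it downsamples.

## Feature pyramid with the no-upsample rule

`build_fpn()`/`fuse()` project each stage to a common width with lateral
1×1 convolutions, accumulate a top-down path, and smooth each fused level
with a 3×3 convolution. Because the dilated backbone's deepest stages share
one resolution, the top-down step between them is a plain addition with *no
upsampling*; a 2:1 size ratio is bridged by nearest-neighbour 2×
upsampling (the standard pyramid choice; the design is silent on the
interpolant). Anything else is a shape error.

Since every pyramid level of this backbone has the same stride, spreading
anchor areas across levels — the usual pyramid convention — degenerates
here; the pipeline therefore attaches the proposal head to the finest fused
level with the full 3-scale × 3-ratio anchor set at each location.

## Region proposals

Anchors (`generate_anchors()`) fix area by scale regardless of aspect
ratio: width $s/\sqrt{\rho}$, height $s\sqrt{\rho}$ for ratio
$\rho \in \{0.5, 1, 2\}$. Default base sizes 8/16/32 px span the observed
nucleus areas (21–1037 px). Boxes are parameterized against anchors as

$$t_x = (x - x_a)/w_a,\quad t_y = (y - y_a)/h_a,\quad
  t_w = \log(w/w_a),\quad t_h = \log(h/h_a),$$

with the exact algebraic inverse in `decode_boxes()`; log-size deltas are
clamped at $\log(1000/16)$ before exponentiation so wild predictions cannot
overflow (with a warning). The proposal objective is

$$L = \frac{1}{N_{cls}}\sum_i L_{cls}(p_i, p_i^*) +
      \lambda \frac{1}{N_{reg}}\sum_i p_i^* L_{reg}(t_i, t_i^*),$$

binary log loss plus smooth-L1 gated to positive anchors. The design names
the symbols but not the values, so the defaults follow the two-stage
detector convention: IoU thresholds 0.7/0.3 with an argmax rescue per
ground truth, $\lambda = 1$, $N_{cls}$ = sampled anchor count (up to 256 at
1:1 positive:negative), $N_{reg}$ = positive count floored at 1 — all
configurable. Non-maximum suppression breaks score ties by lower box index,
making proposal selection fully deterministic.

## Detection heads

ROI features are pooled by ROI-align (`roi_align()`): bilinear sampling at
four regularly spaced sub-bin points per output cell, averaged, with no
coordinate rounding; the operation is linear in the feature map and its
output size is independent of the box. Head sizes are the standard ones the
design leaves open: 7×7 pooling for the classification/box branch, 14×14
for the mask branch with 28×28 logits, class count $k=2$ (nucleus vs
background).

The classification branch is a softmax regression: probabilities
$p_i = \exp(\theta_i^\top x)/\sum_k \exp(\theta_k^\top x)$ (computed with
max-subtraction), cost
$J(\theta) = -\frac1m \sum_i \sum_j 1\{y_i = j\}\,(\theta_j^\top x_i -
\log\sum_l e^{\theta_l^\top x_i})$, gradient
$\nabla_{\theta_j} J = -\frac1m\sum_i (1\{y_i=j\} - p_j(x_i))\,x_i$, and
update $\theta_j \leftarrow \theta_j - \alpha\,\nabla_{\theta_j}J$. These
are exposed directly (`softmax_probs()`, `softmax_loss()`,
`softmax_gradient()`, `sgd_step()`) and the gradient is verified against
central finite differences to `1e-4`.

The mask branch is a small FCN over the pooled feature: two 3×3
convolutions, a 2× upsampling step (nearest-neighbour expansion followed by
a 3×3 convolution — the transposed-convolution family realized without a
dedicated operator), and a 1×1 projection to per-class logits. Its loss is
average binary cross-entropy on the matched class's mask (the standard
choice; the design describes the branch but not its loss). Probabilities
are clamped to $[10^{-7}, 1-10^{-7}]$ inside logs throughout.

## Normalization

`normalize()` implements both kinds behind one switch. Group normalization
standardizes channel groups (default 32, reduced to the channel count)
within each sample, so a sample's output is identical whether processed
alone or in a batch — the property that keeps training stable when dense
scenes force batch size 1. Batch normalization pools statistics across the
batch in training mode and is therefore batch-dependent; running averages
serve evaluation mode, and a frozen mode reproduces
pretrained-statistics behaviour. $\varepsilon = 10^{-5}$.

## Augmentation with replayable records

Training draws 1–3 of eight transform families (sharpening, Gaussian
noise, grayscale conversion, contrast/brightness, random scaling, rotation,
flip, channel rearrangement) and composes them in the drawn order — "a few,
superimposed" is the protocol; the count is a package choice since no
number is fixed. Geometric transforms are applied identically to the label
map with nearest-neighbour interpolation; photometric transforms never
touch it. Every call emits a record (transform names, parameters, noise
sub-seeds) whose replay is bitwise identical, so augmented images and
annotations can always be regenerated consistently. Rotation defaults to
exact quarter-turns (index operations); a small-angle mode uses an
inverse-mapped bilinear/nearest warp. Parameter ranges (sharpening amount
0.5–1.5, noise sd 0.01–0.05, contrast 0.7–1.3, brightness ±0.15, scale
0.75–1.3) are configurable defaults; instances scaled out of existence are
dropped with a warning.

## Evaluation metrics

Object level: greedy one-to-one matching in descending IoU at threshold 0.5
(the conventional value; the definition leaves it open), then
$F1 = 2TP/(2TP+FP+FN)$. Pixel level: the aggregated Jaccard index — for
each ground-truth instance the best-Jaccard prediction is accumulated into
intersection and union counters and marked used; unused predictions add
their full pixel count to the union, penalizing spurious instances;
argmax ties break to the lowest prediction id, and a ground truth with no
overlapping prediction adds its own pixels to the union. Predictions are
kept partition-valued (overlaps resolved by score order) because the metric
assumes disjoint regions. `aji()` is verified *exactly* against
`aji_bruteforce_oracle()`, an independent naive pixel-set implementation,
on 100 random maps plus hand-computed examples.

## Synthetic scenes

`generate_scene()` emulates the statistics the real benchmarks report:
dense fields (a "dense" preset of ≥26 nuclei on 256×256 always exceeds 25),
instance areas from the ~21 px minimum upward, adhering/overlapping
instances, and two imaging modes — brightfield H&E-like rendering (dark
blue-purple nuclei on pink cytoplasm with grey-blue matrix patches) and
fluorescence (bright blobs with radial falloff on a dark noisy background).
Nuclei are ellipses with low-frequency radial boundary jitter; overlap is
resolved by placement order (later instances occlude earlier ones), keeping
the label map a partition, with candidates rejected when they would push
any instance below the minimum area or exceed the allowed overlap fraction.
Instance ids are canonicalized in reading order, and identical specs
(including seed) are bitwise reproducible.

What the generator does *not* emulate: real stain variation and texture,
out-of-focus blur, imaging artifacts, irregular (non-ellipsoidal) nucleus
morphology, and annotation noise. Passing the desk-scale tests therefore
demonstrates that the machinery — architecture, losses, optimization,
metrics — is correct and trainable, not that the model reaches
benchmark-level accuracy on real tissue; that requires the real datasets
and GPU-scale training, which are out of scope here.

## Training regime

The reference regime is the default `train_config()`: staged learning rates
$10^{-4} \to 10^{-5} \to 10^{-6}$ with boundaries at 20/40/75 epochs (read
as a decay schedule; the alternative reading — three separate settings — is
configurable), the amsgrad optimizer, gradient clipping at global norm 5.0,
and batch size 1 with group normalization. Ground-truth boxes are always
derived from instance masks via `mask_to_bbox()`. During training,
ground-truth boxes are appended to the proposal pool so the heads see
positive ROIs from the first iterations. Training is single-threaded and
fully deterministic given the config seed: two runs produce identical loss
traces.

**Desk-scale benchmark.** The tiny preset (`tiny_backbone_config()`: one
block per stage, 32 base channels, total stride 4 so that 64×64 scenes
keep a 16×16 feature grid) is trained for 200 iterations on 32 easy
fluorescence scenes (5–10 well-separated nuclei, radius 4–7 px) and scored
by mean AJI on 20 held-out scenes. `tiny_train_config()` starts at learning
rate $10^{-3}$ — the standard adaptive-moment rate for small networks
trained from random initialization, where the reference $10^{-4}$ (chosen
for fine-tuning-scale budgets) would not converge within 200 steps. These
problem sizes keep the whole benchmark in the minutes range on one CPU
core.

## Numerical and degenerate-input choices

* Anchor/NMS/argmax ties always break to the lowest index, for
  reproducibility across platforms.
* `decode_boxes()` clamps log-size deltas at $\log(1000/16)$; degenerate
  (zero-extent) boxes are configuration errors in `roi_align()` and
  `encode_boxes()`.
* Empty cases are defined, not accidental: zero-nuclei scenes render pure
  background; AJI with no predictions is 0 (and errors with no ground
  truth); an RPN batch with no positives has a zero regression term with
  $N_{reg}$ floored at 1.
* Checkpoints store all weights, the training configuration and the
  iteration counter; reloading reproduces predictions bitwise. Optimizer
  moment estimates are not persisted; resuming restarts them.
* The overlap tie-break on reading instance layouts (first-listed mask
  wins, with a warning) mirrors the writer's id order, making
  write-then-read an identity up to id permutation.

## Known limitations

The network engine is a compact reverse-mode implementation in base R,
sized for desk-scale experiments and CI — not for GPU-scale training runs.
Batch normalization inside the network operates per image (exactly what
batch size 1 induces, and the regime the group-normalization comparison
targets); cross-image batch statistics inside the training loop would need
batched forward passes. Rotation by arbitrary angles uses
nearest-neighbour labels, which can nibble single-pixel instance borders.
The synthetic generator's realism limits are listed above.
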