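---
title: "Methods: IOU-constrained volumetric segmentation with auto-context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IOU-constrained volumetric segmentation with auto-context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gliomas occupy a vanishing fraction of a multimodal MR volume — on the
order of one voxel per thousand — yet their delineation into nested
subregions (whole tumor, tumor core, enhancing tumor) is what downstream
clinical decisions consume. `ioucseg` implements a complete desk-scale
pipeline for this task: a symmetric 3D encoder–decoder convolutional
network trained under a class-weighted soft-Jaccard ("IOU-constraint")
loss, a two-stage multimodal auto-context cascade with integral-volume 3D
Haar-like features, adaptive connected-component post-processing, and a
region-wise evaluation suite. Every numerical primitive — convolution,
pooling, trilinear upsampling, their gradients, integral volumes,
Hausdorff distances — is implemented natively and validated against
brute-force oracles in the test suite.

## The network

The architecture is a five-level symmetric fully convolutional network.
The coarse block layer extracts features with two same-padded 3×3×3
convolutions; five 2×2×2 max-pooling stages halve resolution while channel
widths double from `base_filters` (4 at desk scale, 32 at paper scale).
Between pooling stages sit four 3D residual groups of three bottlenecked
blocks each (1³ → 3³ → 1³ convolutions reducing m channels to m/2 and
back, ReLU activations, additive skip). The decoder (refinement block
layer) restores resolution by separable trilinear interpolation; at each
level an adapter block (1³ convolution on the encoder skip, then
pixel-wise addition) fuses encoder detail into the upsampled decoder
stream. A 1³ head maps the full-resolution features to per-class scores,
and a normalized exponential over the class axis yields per-voxel
probabilities. Spatial dimensions must be divisible by 2⁵ = 32; larger
volumes are processed as overlapping sub-volumes whose probability crops
are mean-fused (`plan_crops()`, `stitch_probability()`).

Dropout (rate 0.5) is applied after the two deepest encoder convolution
stacks during training. Weights use variance-scaling (He) initialization
with two deliberate exceptions: the last 1³ convolution of every residual
block starts at zero, so each block begins as the identity and effective
depth grows with training (the standard fixup-style control of activation
growth in networks without normalization layers), and the head starts at a
small scale (sd 0.01) so training begins near the uniform prediction
rather than at saturated class scores.

Per-channel instance normalization between each hidden convolution and its
activation is available (`normalization = "instance"`) but off by default:
the architecture as published carries no normalization layers, and in our
experiments normalized features — while placid — need far more optimizer
steps at the fixed initial learning rate than desk-scale budgets allow,
because class-score gaps must then be assembled from unit-scale features.

## The loss

With predicted probabilities $X_{cv}$ and one-hot ground truth $Y_{cv}$
over $C$ classes and $V$ voxels, class weights
$w_c = 1/(\gamma_c^2 + \varepsilon)$, $\gamma_c = \sum_v Y_{cv}$, the
loss is

$$L = 1 - s\,\frac{\sum_c w_c \sum_v X_{cv} Y_{cv}}
                 {\sum_c w_c \sum_v (X_{cv} + Y_{cv} - X_{cv} Y_{cv})}$$

The `literal` variant uses $s = 1/C$ — exactly the printed form, whose
value at a perfect prediction is $1 - 1/C$ because the ratio of sums is 1
— and the `normalized` variant uses $s = 1$ so that a perfect prediction
scores 0; the normalized form is the training default, the literal form is
kept for fidelity and both are tested. At zero overlap both variants equal
exactly 1. The $1/\gamma_c^2$ weighting is what counteracts extreme
imbalance: a 30-voxel tumor class and a 32 000-voxel background class
contribute comparably to the ratio.

Two numerical decisions around this formula deserve record:

* **Absent classes.** When a class has no voxels in the evaluated region,
  $1/\gamma_c^2$ is singular. The exported loss stabilizes it as
  $1/(\gamma_c^2+\varepsilon)$ with $\varepsilon = 10^{-6}$. During
  *training*, however, that convention gives an absent class a weight of
  $10^6$ — one tumor-free sub-volume then dominates every gradient step
  with "suppress this class everywhere" pressure, which we observed to
  collapse the model into an all-background prediction. The training path
  therefore drops absent classes from both sums (weight 0,
  `absent = "drop"`), leaving softmax competition to regulate them.
* **Saturation.** Ratio losses have bounded gradients in $X$: once the
  softmax saturates (any class at probability ≈ 0 or 1), the chain rule
  through the softmax kills the gradient and the state is absorbing —
  observed in practice as a frozen all-background model. A small
  logit-norm regularizer (gradient $\lambda z / |z|$ with
  $\lambda = 10^{-3}$, `logit_decay`) keeps class scores bounded and every
  class recoverable. It is an optimizer-side stabilizer, not part of the
  reported loss value.

## Optimization schedule

Adaptive-moment gradient descent (Adam, $\beta_1 = 0.9$,
$\beta_2 = 0.999$) starts at the learning rate $10^{-4}$; when the epoch
loss fails to reach a new best for `lr_patience = 3` consecutive epochs
the rate is halved (a plateau window rather than a literal
halve-on-any-uptick, which we found drives the rate to $10^{-10}$ on the
noisy epoch losses of batch-size-1 training), with a floor of $10^{-6}$.
The epoch budget is initialized at 100. When a held-out set is supplied,
the *error rate* — one minus mean held-out whole-tumor Dice — is monitored
every epoch: training stops once it reaches `error_rate_stop` (default
0.05), and the weights returned are those of the best monitored epoch.
Best-iterate selection matters here: at desk scale the loss trajectory
oscillates (the $1/\gamma^2$ weights make each sub-volume's objective
depend strongly on its rarest class), and the monitored optimum is
substantially better than the last iterate. Batches are single sub-volumes
by default; larger batches pool $\gamma$ over the batch but cost
optimizer steps, which at a fixed wall-clock budget trained worse.

## The auto-context cascade

Stage 1 is trained on the raw modality stacks. Its per-class probability
maps become the context channels of stage 2, concatenated after the raw
modalities and before eight dense 3D Haar-like feature channels
(4 + 5 + 8 = 17 input channels by default). The cascade is exactly two
stages; the second classifier's prediction is the final segmentation.
Stage-2 training uses stage-1 predictions on the same training subjects.
Haar features are computed from the raw flair channel by default — flair
carries the strongest whole-tumor contrast, and the templates are meant to
summarize local context of the raw images — with the template catalogue
(three edges, three lines, center-surround, eight-octant checkerboard, 8³
window) serialized in the checkpoint sidecar. Ablation switches
(`haar_modality = NULL`, `use_probability = FALSE`) reduce stage 2 to an
independently trained stage-1-equivalent.

Channel scaling in the stage-2 input matters: raw modalities and Haar
channels are z-scored, but the probability channels are passed through on
their native [0, 1] scale. Z-scoring a probability channel — whose
variance under extreme imbalance is minuscule — would turn it into a grid
of extreme outliers; in our experiments that single mistake made stage 2
train *worse* than stage 1.

Stage 2 also warm-starts from stage 1: every layer is copied, and the
widened first convolution reads the modality channels with the stage-1
kernels while the added context channels start at zero. Refinement
therefore begins exactly at stage-1 performance and learns to exploit the
probability and Haar context from there. Trained from scratch, stage 2 was
bimodal across seeds at desk scale — sometimes clearly better than stage
1, sometimes collapsed — which is the known instability of this loss on a
fresh network, not a property of the auto-context idea.

## Synthetic phantoms

Real benchmark volumes cannot ship with a package, so the generator
produces multimodal phantoms with the statistical structure the method
assumes: a nested-ellipsoid tumor (edema shell ⊃ non-enhancing ⊃
enhancing rim ⊃ necrotic center, boundary radii at 1 / 0.80 / 0.62 / 0.40
of the outer radius) placed uniformly at random, rendered into four
modality channels by a label-contrast lookup chosen to mimic the
qualitative appearance of real contrasts (edema bright on flair/t2,
enhancing tumor bright on t1Gd, t1 deliberately least informative), plus
additive Gaussian noise (sd 0.05, roughly the noise level of normalized
MR) and an optional multiplicative low-order-polynomial bias field
(default off, emulating upstream inhomogeneity correction; switch it on to
exercise the external bias-correction hook). The default foreground
fraction of $10^{-3}$ reproduces the extreme imbalance of real volumes —
about 33 tumor voxels in a 32³ grid.

What the phantoms do *not* model: irregular tumor topology, partial-volume
mixing at boundaries, anatomical background texture, scanner-dependent
intensity distributions. Passing the phantom-based tests demonstrates that
the pipeline's machinery — loss, gradients, cascade, post-processing,
metrics — behaves as specified under controlled conditions; it does not
certify benchmark-level accuracy on clinical data, which requires the
external benchmark and paper-scale training.

## Problem sizes used by the tests and acceptance script

Desk-scale runs use 32³ volumes, `base_filters = 4` (≈1.6 M parameters),
cohorts of 12–50 phantoms and epoch budgets of 8–20; these sizes were
chosen so a full train–predict–evaluate cycle completes on a single CPU in
minutes while still exercising five pooling levels, all four residual
groups and the full cascade. Oracle-equivalence tests (convolution,
pooling, interpolation, Haar, Hausdorff, loss) run on grids of 3–16 voxels
per side where brute force is exact and fast.

## Evaluation conventions

Dice is $2|T\cap P| / (|T| + |P|)$ (two empty masks score 1); recall and
precision return 1 only when both masks are empty, else 0, with a
degeneracy flag. The Hausdorff distance is the symmetric max-min Euclidean
distance over all foreground voxels (a surface-only option exists),
scaled by voxel spacing so results are in millimetres; it is *undefined*
— reported as missing, never 0 — when either mask is empty. Evaluation
regions follow the standard nesting: whole = labels {1,2,3,4}, core =
{1,3,4}, enhancing = {4}. The adaptive post-filter merges labels 1–4 into
one foreground, labels connected components (26-neighborhood by default)
and deletes those smaller than one tenth of the largest; it only deletes,
is idempotent, and never removes the largest component.

## Known limitations

Training at desk scale is deliberately small and remains sensitive to
seed; the best-iterate mechanism absorbs most of that variance but
held-out Dice on 33-voxel tumors is inherently coarse (each boundary voxel
is ≈3 Dice points). Noise-free phantoms are, counter-intuitively, *harder*
to train on than noisy ones: with an exactly constant background the
volume standard deviation collapses and z-scored tumor voxels become
30–70σ outliers, which destabilizes optimization; held-out Dice on
noise-free phantoms plateaus well below the noisy-phantom result within
desk-scale step budgets, even though a per-voxel linear classifier (which
the network can represent) separates the classes perfectly. The literal loss variant is non-zero at a perfect
prediction by construction. The channel schedule treats the published
filter table as indicative, deriving widths by doubling from
`base_filters`, because the printed input/output filter counts are not
mutually consistent. Orientation metadata beyond voxel spacing is carried
opaquely and never resampled.
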