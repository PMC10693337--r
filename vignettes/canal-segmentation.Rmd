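---
title: "Topology-aware segmentation of the mandibular canal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware segmentation of the mandibular canal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The mandibular canal (MC) is the thin, curved channel in the lower jaw that
carries the inferior alveolar nerve. Segmenting it from cone-beam CT (CBCT)
is hard for two structural reasons: the canal occupies well under 2% of the
volume, so a segmentation loss dominated by background learns to predict
nothing; and its walls have nearly the same gray values as the surrounding
trabecular bone, so boundaries are faint. On top of that, the canal is a
*tube*: a segmentation that is 95% correct voxel-wise but broken into three
fragments is clinically much worse than one with slightly rougher walls but
intact connectivity. `canalseg` packages an approach built around these
three facts: aggressive foreground-focusing preprocessing, a transformer
encoder with pixel-level feature fusion for fine detail, and a
centerline-Dice (clDice) loss that directly scores tube connectivity.

Everything is exercisable without clinical data through a synthetic canal
phantom generator, and the whole pipeline — preprocessing, training,
sliding-window inference, evaluation — runs on one CPU at a reduced
("tiny") scale.

# Preprocessing

**Cropping.** Training labels pin down where the canal is, so volumes are
cropped to the axis-aligned bounding box of the label's largest
26-connected component, expanded by a margin (default 3 mm = 10 voxels at
0.3 mm) and clipped to the grid. The two canal openings (the mandibular and
mental foramina) are located as the extreme points of that component along
its long axis — centroid, farthest voxel, farthest voxel from that — and
reported for diagnostics; the crop itself is the component box, which is
what "largest connected domain" means operationally. `restore_to_original()`
inverts the crop so metrics always run at original geometry.

At inference time no label exists. The crop operation therefore accepts any
mask or box: a user-supplied bounding box, or a coarse mask from a cheap
first-pass inference. The phantom pipeline mirrors that setting and
crops with the label at training time only.

**CLAHE.** Contrast-limited adaptive histogram equalization is applied
independently to each axial slice (clip limit 2.0, 8x8 tiles, 256 bins —
the reference protocol pins no parameter values; these are the
standard defaults of every mainstream implementation). Slice-wise 2D CLAHE
rather than 3D block equalization is the established dental-CBCT practice
and has deterministic, well-tested implementations (EBImage). Flat slices
are passed through unchanged, and tile grids larger than the slice are
clamped with a logged warning.

**Intensity normalization.** Raw intensities are min-max rescaled to
[0, 1] at load — the simplest deterministic choice, with CLAHE running
after it. Data already
inside [0, 1] is read back unchanged so write/read round trips are
lossless.

# The network

A 4-stage shifted-window transformer encoder over 3D patches feeds a
U-shaped convolutional decoder:

- **Stem**: a stride-2, kernel-2 convolution (patch size 2) embeds the
  single-channel patch at half resolution with `base_embed_dim` channels
  (48 by default, 8 in the tiny preset).
- **Stages**: each of the 4 stages applies two transformer blocks —
  windowed multi-head self-attention, then the same with the window grid
  cyclically shifted by half a window — followed by 2x2x2 patch merging
  that halves the grid and doubles the channels. Head count is
  `channels / 32` (minimum 1). The window edge defaults to 6, which tiles
  every stage grid of the 96^3 protocol (48, 24, 12, 6) exactly, so no
  attention masking is needed; per stage the window is clamped to the
  largest value that tiles the grid. A patch edge must be divisible by
  2^5 = 32: one stem halving plus four merges.
- **Decoder**: five x2 upsamplings mirror the encoder. Each level
  trilinearly upsamples the coarser state, projects channels with a 3^3
  convolution, concatenates the skip connection, and applies a residual
  module of two 3x3x3 convolutions (bottlenecked to half the output
  channels internally) with a 1x1x1 projection shortcut. The final
  full-resolution level uses a pointwise projection after upsampling — the
  detail at that scale comes from the fusion path and the head. The head is
  a 1x1x1 convolution with a sigmoid.
- **Pixel-level fusion (DRC)**: after each decoder level, the coarser
  decoder output is upsampled x2 and passed through a deep residual
  convolution block — a 1x1x1 branch plus a 1x1x1 / 3x3x3 / 1x1x1
  bottleneck branch, each convolution followed by instance normalization
  and ReLU — whose output is added voxel-wise to the level's features. The
  1x1x1 convolutions perform the channel projection. A config flag swaps
  the DRC for a plain convolution block (`plain_conv`) or disables the
  addition (`none`), reproducing the ablation axis baseline / traditional
  convolution / DRC.

Normalization is *instance* norm everywhere in the convolutional path
(batch size is 1, making batch statistics degenerate) and layer norm in the
transformer blocks. With a single spatial voxel (the bottleneck of a 32^3
patch) instance statistics would zero the signal, so the op reduces to its
learnable affine map there.

The network and its reverse-mode differentiation are implemented natively:
an R tape-based autograd over compiled kernels (im2col convolution,
separable min/max pooling, trilinear upsampling, batched scaled-dot-product
attention). Every kernel's gradient is tested against central finite
differences, both per-op and through the assembled network.

# Losses

The soft Dice loss is `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)`.

The clDice loss compares *skeletons* with *volumes*: with `S_P` and `S_L`
the soft skeletons of prediction and reference, topology precision
`Tprec = |S_P ∩ V_L| / |S_P|` asks whether the predicted centerline lies
inside the true canal, and topology sensitivity
`Tsens = |S_L ∩ V_P| / |S_L|` asks whether the true centerline is covered
by the prediction. The loss is one minus their harmonic mean. Soft
skeletons come from iterated soft morphology: min-pool (3^3) erosion,
max-pool dilation, opening as their composition, accumulating the opening
residues of successively eroded masks over `k` iterations. `k` defaults to
5 — enough to reduce tubes up to roughly 5 voxels in radius, covering both
the phantom radii (2–4 voxels) and the MC's ~1–1.5 mm radius at 0.3 mm
spacing; it is exposed in `loss_config()`. Every ratio carries a smoothing
`eps = 1e-6` so empty masks are well-defined.

The total loss is the convex combination
`(1 - lambda) * L_Dice + lambda * L_clDice`, exactly the Dice loss at
`lambda = 0` and exactly the clDice loss at `lambda = 1`. The default
`lambda = 0.1` weights connectivity lightly against voxel overlap; it is
the topology arm in the package's own held-out comparisons. Two
conventions are fixed deliberately: the clDice denominator is the *sum* of
the two topology terms (harmonic mean), and `V_L` is the reference while
`V_P` is the prediction, following the convention of the work that
introduced the score.

# Training and inference

Training follows the reference protocol: Adam with beta1 = 0.99 (the
protocol's "momentum"), beta2 = 0.999, initial learning rate 1e-4, cosine annealing to
zero, batch size 1, 500 epochs, 96^3 patches. Patch sampling is
foreground-biased — by default half the patches are centred on a random
foreground voxel — because at <2% prevalence uniform patches rarely contain
canal; the bias is configurable down to 0. Runs are fully seeded and
reproduce bit-for-bit.

The **tiny preset** is the same architecture and protocol scaled to one
CPU: embedding width 8, window 2, 32^3 patches, 30 epochs, and a learning
rate of 1e-3 — the full-protocol 1e-4 is calibrated for a schedule roughly
sixty times longer, and transfers poorly to 600-step runs. This preset is
what the test suite trains.

Inference tiles the volume with a 96^3 sliding window at stride 48 (50%
overlap; 32/16 in the tiny preset) and blends overlapping predictions by
unweighted mean — the protocol says only "stitching", and the mean makes
stitching of any consistent patch operator exact, a property the tests
exploit with an identity operator. Gaussian-weighted blending is available
behind a flag. Volumes smaller than a window are edge-padded and cropped
back. Final-epoch weights are used; best-on-validation selection is not
implied by the protocol and is left to the caller.

# Deep label fusion

Sparse datasets annotate only some 2D slices. Circular-expansion labels
interpolate centroid and equivalent radius between annotated slices and
rasterize a disk per slice — clean boundaries, but a cylinder-segment
geometry that cannot follow the canal between slices. Model pseudo-labels
are geometrically faithful but can be noisy or disconnected. Deep label
fusion combines them as `alpha * pseudo + (1 - alpha) * circ`, thresholds,
and keeps the largest 26-connected component.

The threshold matters more than it looks: at `alpha = 0.5` with threshold
0.5 the fused mask is provably `circ ∪ {pseudo = 1}` — fusion could never
*remove* an expansion voxel, and no improvement over the expansion labels
is possible. The default is therefore `threshold = 0.6`: an expansion voxel
survives only if the pseudo-label grants it probability at least 0.2 (a
weak veto), and voxels outside the expansion are never added. On phantoms
with known truth this fusion improves Dice over the expansion labels on
every test case.

The two-stage pipeline (`pretrain_then_finetune()`) trains on dense labels,
pseudo-labels the sparse volumes, fuses, pre-trains a *fresh* model on the
fused set, and fine-tunes on the dense set. Fine-tuning a fresh model
rather than the stage-1 model was chosen so the pre-training set cannot
leak optimizer state.

# Evaluation

Hard metrics per (prediction, reference) pair: Dice `2TP/(FP+2TP+FN)`, IoU
`TP/(TP+FP+FN)` (with `dice = 2*iou/(1+iou)` exactly), clDice on binary
skeletons, and surface Hausdorff distances in mm. Surfaces are foreground
voxels with a 6-neighbour background (grid edges count as background);
HD95 takes the 95th percentile of each directed surface-distance set and
returns the maximum of the two directions — the dominant convention in
segmentation benchmarking, declared here explicitly because surface and
full-voxel-set variants of HD95 coexist in the literature. The hard
skeleton is a binary morphological skeleton (iterated erosion-opening
residues, the binary limit of the soft-skeleton scheme) rather than a
parallel-thinning skeleton; the connectivity standard the score derives
from does not pin an algorithm, and the choice is recorded in each report's
metadata. Conventions for degenerate cases are explicit: two empty masks
score Dice = IoU = 1 with a logged note; one empty mask scores 0 with
distances flagged undefined rather than silently 0.

# The phantom generator

`generate_phantom()` emulates the *statistical* challenges of canal CBCT,
not its anatomy: a smooth curved centerline (interpolating spline through
seeded control points) swept with a varying radius (2–4 voxels) into a
single 26-connected tube; a bone-like background of band-limited noise
around intensity 0.6; canal intensity `contrast_gap` below the background
(default 0.3, i.e. low contrast); additive Gaussian noise; all clipped to
[0, 1]. Under the default 128^3 spec the foreground fraction stays below
2%, reproducing the class-imbalance regime. Three annotation styles mirror
the dataset structure: dense 3D masks, sparse per-slice annotations (exact
2D restrictions of the dense mask on seeded axial slices), and
circular-expansion masks derived from the sparse ones. The sparse-slice
axis is axial by declaration; no claim is made about how any particular
clinical dataset orients its sparse annotations.

What the phantoms do *not* model: beam hardening, scatter, teeth and
cortical bone, bilateral canals, branching. Passing tests on phantoms
demonstrate that the machinery — losses, topology sensitivity, fusion,
recovery — behaves as designed under canal-like statistics; they say
nothing about clinical accuracy on real CBCT.

# Problem sizes used by the tests

The test suite trains the tiny preset on 20 easy phantoms (32^3 crops,
contrast gap 0.4, noise sd 0.05) for 30 epochs, three seeds per loss arm,
evaluating 5 held-out phantoms per run — sizes chosen so the full suite
runs on a single CPU in well under half an hour while the recovery question
(median held-out Dice >= 0.6) remains meaningfully hard. The label-fusion
pre-training comparison runs three seeds at 6 dense + 4 sparse phantoms and
8 epochs per stage. All runs are seeded; reported comparisons are
reproducible exactly.

# Known limitations

- The full 96^3 protocol builds and runs but is not trainable in reasonable
  time on one CPU; the tiny preset is the supported desk-scale
  configuration.
- Single-class segmentation only; no DICOM ingestion; no resampling
  between voxel spacings.
- The autograd engine implements exactly the operator set this network
  needs; it is not a general-purpose framework.
- Automatic foramen detection from raw intensities (without any label or
  box) is out of scope; inference-time cropping expects a box or coarse
  mask.
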