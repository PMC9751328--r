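---
title: "Low-annotation classification of SEM biofilm constituents"
author: "SEMBiofilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-annotation classification of SEM biofilm constituents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microbially induced corrosion (MIC) is driven by biofilms — here, sulfate-
reducing bacteria such as *Desulfovibrio* — growing on metal surfaces.
Scanning electron microscopy (SEM) of such biofilms shows three morphological
constituents whose spatial distribution matters for assessing coatings and
corrosion: microbial **cells** (singly and in clusters), **byproducts**
(corrosion products and biofilm microstructure without canonical shape), and
the **non-occluded surface**. Expert pixel-level annotation of these crowded,
low-contrast images is the bottleneck: frames are slow to produce (weeks of
biofilm growth per batch) and hard to label.

SEMBiofilm implements a patch-level pipeline that needs image-level labels
for only ~10% of the data. Images are cut into overlapping `m x m` patches;
representations are learned from *all* patches without labels by
self-supervised learning (SSL); three binary classifiers — one per class,
the binary-relevance scheme — are then fine-tuned on the small labeled
subset, and their merged outputs give a multi-label decision per patch, from
which per-image class-distribution heatmaps are assembled.

## Pipeline stages and their parameters

### Preprocessing

1. **Metadata-strip crop.** SEM frames carry a black strip with instrument
   text at the bottom. Its height is a per-dataset metadata field
   (`metaStripHeight`), not a constant — frame conventions differ — and the
   crop removes exactly those rows from image and annotation.
2. **CLAHE** (via EBImage), clip limit 2 on an 8x8 tile grid — conventional
   defaults; the goal is sharper object boundaries, and the annotation is
   untouched.
3. **Conditional super-resolution.** Frames at coarse scale
   (`scaleUm >= 10`) *and* low magnification (`< 1000X`) are upscaled by
   `srFactor = 4` so object sizes are comparable across magnifications;
   close-ups are left alone. The default backend is classical
   cubic-convolution (Catmull–Rom) interpolation for pixels with
   nearest-neighbour for the label map, so pixel-level labels stay aligned.
   A learned super-resolution model can be plugged in as a function
   `(pixels, factor) -> pixels`; no pretrained weights ship with the
   package.

### Patches, masks, labels, splits

- **Patch geometry.** Kernel 64 px with stride = kernel/2 by default.
  Overlapping windows reduce boundary feature loss; a stride given in
  pixels keeps the patch count explicit
  (`(floor((H-k)/s)+1) * (floor((W-k)/s)+1)` per image).
- **Object masks** render one class per copy of the patch (other pixels
  black). They are audit artifacts and the source of ground truth; the
  classifiers consume the *original* patch.
- **Presence threshold.** A class is "present" when it covers at least
  `minFraction = 1%` of the patch. Zero means "any pixel"; 1% suppresses
  single-pixel annotation specks while keeping genuinely mixed patches
  multi-labeled. Raising the threshold can only switch labels off
  (monotonicity is tested).
- **Split.** 80% of patches for representation learning, 10% for
  fine-tuning, 10% for testing. The default `random_patch` strategy
  mirrors patch-wise sampling; because overlapping patches shared between
  fine-tune and test leak pixels, a `spatial_block` strategy is also
  provided that assigns whole overlap-connected groups of windows to one
  subset (with stride < kernel these groups grow to whole images, so
  fractions are met only approximately — the price of a leak-free split).

### Self-supervised objectives

Both variants share a small convolutional encoder (3x3 convolutions with
channel batch normalization, ReLU and 2x2 max pooling; 8/16/32 channels)
over 32 px views, followed by global average pooling and a linear projector
(output dimension D = 64). Two stochastic views of each patch are formed by
random area crops (60–100% of the patch, rescaled to 32 px) and horizontal
flips.

**Contrastive (momentum queue).** A query encoder embeds one view (`q`), an
exponential-moving-average (EMA) "momentum" copy embeds the other (`k+`);
embeddings are L2-normalized. With a FIFO queue of previous keys as
negatives, the loss per query is

    -log[ exp(q.k+ / tau) / (exp(q.k+ / tau) + sum_k- exp(q.k- / tau)) ]

i.e. softmax cross-entropy with the positive as the true class. The queue is
filled with momentum-encoder keys *before* the first update so every step
faces the same number of negatives and per-epoch losses are comparable.

**Non-contrastive (redundancy reduction).** The twin branches share weights;
their batch-normalized projector outputs `zA`, `zB` give the
cross-correlation matrix `C[i,j] = <zA_i, zB_j> / (||zA_i|| ||zB_j||)` over
the batch, and the loss

    sum_i (1 - C[i,i])^2 + lambda * sum_{i != j} C[i,j]^2

drives the diagonal to 1 (view-invariant dimensions) and the off-diagonal to
0 (decorrelated dimensions).

**Constants.** `tau = 0.2` and `lambda = 5e-3` are the values published with
these objectives. The EMA coefficient and queue capacity scale with the
training horizon: the published `m = 0.999` and queue 65k assume schedules
of ~10^5 steps, while a desk-scale run here takes a few hundred steps, so
the defaults are `m = 0.9` (EMA horizon ~10 steps << schedule length) and a
queue of 512 keys (8 batches). Optimizer: plain SGD, momentum 0.9, constant
learning rate 0.1; all of this is exposed in `pretrainConfig()`.

### Downstream protocols

- **Linear probe** (`linear_frozen`): encoder frozen (bit-identical before
  and after, tested); a logistic head is trained on standardized frozen
  features. Feature standardization makes the probe a well-conditioned
  logistic problem whatever the activation scales.
- **Fine-tuning** (`finetune`): encoder and head are updated jointly for
  exactly 20 epochs; the encoder learning rate is one tenth of the head's
  so the pretrained representation is adapted, not destroyed. GAP features
  are batch-normalized in front of the head (running statistics are kept
  for inference).
- **Supervised baseline:** the same architecture under the *identical*
  downstream protocol (same epochs, learning rates, augmentations and
  weighted cross-entropy), but starting from a fresh He initialization
  instead of pretrained representations. Protocol parity makes the
  representation the only difference between baseline and SSL pipeline —
  the reference comparison fine-tunes a supervised-pretrained backbone the
  same way; no externally pretrained backbone is shipped or assumed here,
  so a fresh initialization stands in.
- **Class imbalance.** Surface positives vastly outnumber Byproduct
  positives; inverse-frequency loss weighting is on by default.
- **Decisions.** Each head outputs a sigmoid score; `score >= 0.5` gives
  the per-class flag. No mutual exclusion: zero to three labels per patch.

### Evaluation and visualization

Accuracy is correct/total; for multi-label reports every (patch, class)
decision counts once. `crossValidate()` repeats training/evaluation 10
times (repeated random splits by default, classic k-fold selectable) and
reports per-class and overall mean ± sample standard deviation (n-1) in
percent. "Overall" is the arithmetic mean of the three per-class means —
the construction consistent with the reference accuracy tables.

Class activation maps are the GAP construction: the class head's weights
(rescaled by the feature standardization) weight the final convolutional
feature maps, upsampled bilinearly to the patch and min–max normalized;
a constant map is reported as 0.5 everywhere. Class-distribution heatmaps
run the classifiers over the sliding-window grid of a whole image.

## The synthetic scene generator

Real SEM biofilm data is access-restricted, so the package ships a
generator whose scenes carry exact tri-color ground truth (blue = Cell,
pink = Byproduct, green = Surface on disk):

- textured dark metal background (smooth random fields at two scales);
- byproduct blobs: thresholded smoothed noise with a solid core and a
  granular rim — no canonical shape, and large "mats" (radius up to ~75 px)
  that can fully occlude the surface locally, reflecting heavy crowding;
- cells: shaded ellipses at toy scale (major axis 10–28 px), singly and in
  Gaussian-scattered clusters, drawn on top of byproducts (the annotation
  keeps the topmost class);
- cell and byproduct grey levels deliberately *overlap* (cells ~168–200,
  byproduct ~130–170): the classes are separated by shape and texture more
  than by brightness, mirroring the low inter-class variance between cells
  and byproducts in real frames;
- a per-image smooth illumination/gain field (±12%) and additive Gaussian
  noise (sd 10 grey levels), because acquisitions differ in brightness;
- optionally a black metadata strip with bright synthetic text marks.

Byproduct sizes have no published calibration; the ranges are free
parameters chosen so that all three labels are two-sided at the default
patch size (every class has positives *and* negatives — otherwise the
binary-relevance scheme is degenerate).

Every scene element draws from its own derived RNG substream, so raising
one object count leaves all other elements bit-identical — class pixel
counts respond monotonically to their parameters (tested).

**What passing tests on these scenes does and does not show.** The
synthetic scenes exercise every contract of the pipeline (geometry, label
bookkeeping, losses, protocols) and give a realistic *difficulty ordering*
(surface easiest, cell/byproduct confusable). They do not emulate electron
optics, charging artifacts, depth effects or real byproduct chemistry, so
absolute accuracies obtained here say nothing quantitative about real SEM
data — only the directional comparisons (e.g. SSL + 10% labels vs
supervised on the same 10%) are meaningful, and those only at the scales
tested.

## Numerical choices

- Batch normalization uses population statistics of the current batch in
  every pass (spatial positions count toward channel statistics, so
  single-patch passes — e.g. CAMs — are well-defined). Feature
  encoding for prediction always batches patches in a fixed order, keeping
  results deterministic.
- Evaluation views are center crops at 90% of the patch side rescaled to
  the network input, matching the scale distribution of the training crops
  (random 60–100% area crops rescaled); a full-resolution center crop at
  the network input size would cover only a quarter of the patch area and
  systematically miss off-center objects.
- The seed of every stochastic stage is derived from the global run seed
  and the stage name, so stages are reproducible in isolation; scenes
  derive one seed per object.
- Degenerate inputs: an empty negative queue and non-positive temperature
  are validation errors; zero-variance embedding dimensions make the
  cross-correlation undefined and are flagged rather than silently
  regularized; constant activation maps normalize to 0.5.
- Gradients of the two objectives, the conv/pool kernels and the batch-norm
  backward pass are verified against finite differences and brute-force
  reimplementations in the test suite.

## Desk-scale study conditions

The default end-to-end run (`defaultRunConfig()`, also what
`scripts/acceptance.R` executes) uses 12 synthetic scenes of 512 x 512
(472 content rows + 40 strip rows), 64 px patches at stride 32 (2340
patches), the 80/10/10 split, both SSL variants pretrained 20 epochs at
batch 64, heads fine-tuned 20 epochs on the 10% labeled split, and accuracy
scored on the held-out 10%. On one CPU core this takes on the order of ten
minutes. These sizes are the package's chosen desk-scale study; the
configuration accepts the larger patch (128 px), batch (128/256) and epoch
(200–400) settings of GPU-scale studies unchanged.

## Known limitations

- The encoder is a small CNN, not a ResNet-50; the package's claims are
  about the losses and protocols, not about backbone capacity.
- Binary relevance ignores label correlations by construction; the
  representation stage is the only place correlations can be captured.
- The contrastive variant is sensitive to its EMA horizon at short
  schedules; the desk default `m = 0.9` is not appropriate for 10^5-step
  runs (use 0.999 there).
- `random_patch` splitting shares source pixels between subsets through
  window overlap; use `spatial_block` when leakage matters more than exact
  fractions.
- At desk scale the held-out 10% test split is only ~700 binary decisions,
  so directional comparisons between methods whose true margin is a point
  or two (as linear probes suggest for SSL vs a fresh initialization here)
  sit inside the evaluation noise; the end-to-end accuracy comparison in
  the test suite is exactly such a check and can land on either side of
  the baseline from seed to seed. Batch-normalized random convolutional
  features are themselves a strong representation at this network size,
  which compresses margins that are large for deep backbones on big patch
  corpora.
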