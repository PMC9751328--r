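# SEMBiofilm

Low-annotation, patch-level analysis of scanning electron microscope (SEM)
images of bacterial biofilms on corroding metal surfaces. The package
detects the three morphological constituents that matter for microbially
induced corrosion (MIC) studies — microbial **cells** (and cell clusters),
MIC **byproducts**, and the **non-occluded surface** — and maps their
spatial distribution across each image, while requiring image-level labels
for only ~10% of the data.

It is aimed at microscopy and biofilm groups who have few annotated frames:
representation learning runs on *unlabeled* patches, annotation effort goes
into a small fine-tuning subset, and everything (including a synthetic
SEM-like scene generator with exact pixel-level ground truth) runs on a
single CPU.

## The method

Images are preprocessed (metadata-strip crop, CLAHE contrast enhancement,
and conditional 4x super-resolution for coarse-scale, low-magnification
frames), then cut into overlapping `m x m` patches by sliding window.
Per-class object masks derived from pixel-level annotations yield an
image-level multi-label per patch (`minFraction` presence threshold).

Representations are learned from unlabeled patches with either of two
self-supervised objectives over twin augmented views (random crop +
horizontal flip):

* **Contrastive (momentum queue).** With L2-normalized query `q`, positive
  key `k+` from an EMA momentum encoder, a FIFO queue of negative keys
  `k-`, and temperature `tau`:

      L(q) = -log[ exp(q.k+/tau) / ( exp(q.k+/tau) + sum_{k-} exp(q.k-/tau) ) ]

* **Non-contrastive (redundancy reduction).** With batch-normalized twin
  embeddings `z^A`, `z^B` and their cross-correlation matrix
  `C_ij = sum_b z^A_bi z^B_bj / (||z^A_i|| ||z^B_j||)`:

      L = sum_i (1 - C_ii)^2 + lambda * sum_i sum_{j != i} C_ij^2

The downstream task is **binary relevance**: `K = 3` independent binary
classifiers (linear probe on the frozen encoder, or joint fine-tuning for
20 epochs with the encoder at a tenth of the head learning rate), whose
merged sigmoid decisions give 0-3 labels per patch. Accuracy
(correct/total, per class and overall = mean of the per-class accuracies)
is reported as mean +/- sd over 10 cross-validation repeats, and class
activation maps plus per-image class-distribution heatmaps visualize what
the models found where.

## Worked example

```r
library(SEMBiofilm)

# a synthetic annotated SEM-like scene (436X, 10 um scale bar, 40 px strip)
spec <- SceneSpec(width = 512L, height = 472L, nCells = 40L, nClusters = 8L,
                  nByproductBlobs = 22L, byproductRadiusRange = c(15, 75),
                  metaStripHeight = 40L)
img <- generateScene(spec, seed = 7)
img
#> AnnotatedImage 512 x 512 (rows x cols), 436X, 10 um scale, strip 40 px
#>   class cover: Byproduct 39.2%, Cell 5.6%, Surface 55.3%

# preprocess (crop strip, CLAHE; the 436X / 10 um rule would trigger
# super-resolution, disabled here with srFactor = 1)
pp <- preprocessImage(img, PreprocessConfig(srFactor = 1L))

# 64 px patches at half-kernel stride, with multi-label ground truth
ps <- deriveLabels(extractPatches(pp, kernel = 64, stride = 32), 0.01)
ps
#> PatchSet: 195 patches of 64 x 64 (stride 32) from 1 image(s)
#>   label prevalence: Byproduct 80.0%, Cell 63.1%, Surface 94.4%
```

`Byproduct 80.0%` means 80% of the 195 patches contain at least 1%
byproduct pixels — crowded scenes give heavily multi-label patches, and
5.6% of patches are fully occluded (no Surface left in the window). The full study —
pretraining both SSL variants on 12 such scenes, fine-tuning the three
binary heads on 10% of the labels and scoring the held-out 10% — is one
call:

```r
state <- runPipeline(defaultRunConfig(seed = 1))
state$evaluation
```

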