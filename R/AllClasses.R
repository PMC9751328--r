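#' SceneSpec: parameters of a synthetic SEM biofilm scene
#'
#' Describes a synthetic scanning-electron-microscope scene: a textured metal
#' background (the non-occluded surface), rod/ellipse shaped bacterial cells
#' drawn singly and in clusters, irregular granular corrosion-byproduct blobs,
#' optional instrument metadata strip, and acquisition metadata. Defaults
#' emulate a 1024-wide SEM frame with a 76-px metadata strip (so the stored
#' frame is 1024 x 758) at 436X magnification and a 10 micrometer scale bar.
#'
#' @slot width,height integer, scene content size in pixels (the metadata
#'   strip, if any, is appended below the content rows).
#' @slot nCells integer, number of isolated cells.
#' @slot nClusters integer, number of cell clusters.
#' @slot clusterSizeRange integer length-2, cells per cluster (low, high).
#' @slot nByproductBlobs integer, number of byproduct blobs.
#' @slot cellAxisRange numeric length-2, full major-axis range of cell
#'   ellipses in pixels.
#' @slot byproductRadiusRange numeric length-2, blob radius range in pixels.
#' @slot backgroundTextureScale numeric, amplitude (grey levels) of the
#'   smooth background texture field.
#' @slot noiseSd numeric, additive Gaussian pixel noise, grey levels.
#' @slot overlapAllowed logical, whether objects may overlap.
#' @slot metaStripHeight integer, height in pixels of the black metadata
#'   strip appended at the bottom (0 = none).
#' @slot magnificationLabel numeric, nominal magnification (436 = "436X").
#' @slot scaleUm numeric, scale-bar length in micrometers.
#' @export
setClass("SceneSpec", representation(
  width = "integer", height = "integer",
  nCells = "integer", nClusters = "integer",
  clusterSizeRange = "integer", nByproductBlobs = "integer",
  cellAxisRange = "numeric", byproductRadiusRange = "numeric",
  backgroundTextureScale = "numeric", noiseSd = "numeric",
  overlapAllowed = "logical", metaStripHeight = "integer",
  magnificationLabel = "numeric", scaleUm = "numeric"
))

setValidity("SceneSpec", function(object) {
  chkRange <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r))) return(sprintf("%s: must be a finite length-2 interval", nm))
    if (r[1] > r[2]) return(sprintf("%s: low > high", nm))
    if (any(r < 0)) return(sprintf("%s: negative", nm))
    NULL
  }
  for (nm in c("width", "height")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v <= 0L) return(sprintf("%s: must be a positive integer", nm))
  }
  for (nm in c("nCells", "nClusters", "nByproductBlobs", "metaStripHeight")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0L) return(sprintf("%s: must be a non-negative integer", nm))
  }
  for (nm in c("clusterSizeRange", "cellAxisRange", "byproductRadiusRange")) {
    msg <- chkRange(slot(object, nm), nm)
    if (!is.null(msg)) return(msg)
  }
  if (object@backgroundTextureScale < 0) return("backgroundTextureScale: negative")
  if (object@noiseSd < 0) return("noiseSd: negative")
  if (object@magnificationLabel <= 0) return("magnificationLabel: must be > 0")
  if (object@scaleUm <= 0) return("scaleUm: must be > 0")
  TRUE
})

#' @rdname SceneSpec-class
#' @param width,height,nCells,nClusters,clusterSizeRange,nByproductBlobs
#'   see slots.
#' @param cellAxisRange,byproductRadiusRange,backgroundTextureScale,noiseSd
#'   see slots.
#' @param overlapAllowed,metaStripHeight,magnificationLabel,scaleUm see slots.
#' @return A validated `SceneSpec`.
#' @export
#' @examples SceneSpec(width = 256L, height = 256L, nCells = 10L)
SceneSpec <- function(width = 1024L, height = 682L, nCells = 120L,
                      nClusters = 20L, clusterSizeRange = c(8L, 18L),
                      nByproductBlobs = 60L, cellAxisRange = c(10, 28),
                      byproductRadiusRange = c(15, 75),
                      backgroundTextureScale = 8, noiseSd = 10,
                      overlapAllowed = TRUE, metaStripHeight = 76L,
                      magnificationLabel = 436, scaleUm = 10) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      nCells = as.integer(nCells), nClusters = as.integer(nClusters),
      clusterSizeRange = as.integer(clusterSizeRange),
      nByproductBlobs = as.integer(nByproductBlobs),
      cellAxisRange = as.numeric(cellAxisRange),
      byproductRadiusRange = as.numeric(byproductRadiusRange),
      backgroundTextureScale = as.numeric(backgroundTextureScale),
      noiseSd = as.numeric(noiseSd), overlapAllowed = isTRUE(overlapAllowed),
      metaStripHeight = as.integer(metaStripHeight),
      magnificationLabel = as.numeric(magnificationLabel),
      scaleUm = as.numeric(scaleUm))
}

#' AnnotatedImage: grayscale SEM frame plus pixel-level class annotation
#'
#' Couples an 8-bit grayscale image with a same-size class map in which every
#' pixel carries exactly one of the three constituent classes (Byproduct = 1,
#' Cell = 2, Surface = 3; rendered on disk as pink/blue/green), plus
#' acquisition metadata (magnification, scale bar, metadata-strip height).
#'
#' @slot pixels numeric matrix (rows = image rows), grey levels in `[0, 255]`.
#' @slot annotation integer matrix of class codes 1:3, same size as `pixels`.
#' @slot meta list with `magnificationLabel`, `scaleUm`, `metaStripHeight`.
#' @export
setClass("AnnotatedImage", representation(
  pixels = "matrix", annotation = "matrix", meta = "list"
))

setValidity("AnnotatedImage", function(object) {
  if (!all(dim(object@pixels) == dim(object@annotation)))
    return("pixels and annotation must have identical dimensions")
  if (min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixels must lie in [0, 255]")
  a <- object@annotation
  if (!all(a %in% 1:3))
    return("annotation must be a full partition into class codes 1:3")
  need <- c("magnificationLabel", "scaleUm", "metaStripHeight")
  if (!all(need %in% names(object@meta)))
    return(paste("meta must contain:", paste(need, collapse = ", ")))
  if (object@meta$metaStripHeight >= nrow(object@pixels))
    return("metaStripHeight must be smaller than the image height")
  TRUE
})

#' @rdname AnnotatedImage-class
#' @param pixels,annotation see slots.
#' @param magnificationLabel,scaleUm,metaStripHeight metadata fields.
#' @return A validated `AnnotatedImage`.
#' @export
AnnotatedImage <- function(pixels, annotation,
                           magnificationLabel = 436, scaleUm = 10,
                           metaStripHeight = 0L) {
  storage.mode(annotation) <- "integer"
  new("AnnotatedImage", pixels = pixels, annotation = annotation,
      meta = list(magnificationLabel = magnificationLabel, scaleUm = scaleUm,
                  metaStripHeight = as.integer(metaStripHeight)))
}

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@pixels)
  fr <- round(100 * tabulate(object@annotation, 3L) / length(object@annotation), 1)
  cat(sprintf("AnnotatedImage %d x %d (rows x cols), %sX, %g um scale, strip %d px\n",
              d[1], d[2], format(object@meta$magnificationLabel),
              object@meta$scaleUm, object@meta$metaStripHeight))
  cat(sprintf("  class cover: Byproduct %.1f%%, Cell %.1f%%, Surface %.1f%%\n",
              fr[1], fr[2], fr[3]))
})

#' PatchSet: sliding-window patches with aligned annotations and labels
#'
#' A stack of m x m grayscale patches cut from one or more source images,
#' with the matching annotation patches, window origins, multi-label ground
#' truth (once derived) and split/fold assignment (once planned).
#'
#' @slot pixels numeric array `[m, m, n]` of patch grey levels.
#' @slot annotations integer array `[m, m, n]` of class codes.
#' @slot origins integer matrix `n x 2`, 0-based (row, col) window origins.
#' @slot sourceId character length-n source image identifiers.
#' @slot kernel,stride integer, window size and stride in pixels.
#' @slot labels logical matrix `n x 3` (Byproduct, Cell, Surface) or 0-row
#'   before [deriveLabels()].
#' @slot split character length-n in {"", "repr", "finetune", "test"}.
#' @slot fold integer length-n (0 where unassigned).
#' @export
setClass("PatchSet", representation(
  pixels = "array", annotations = "array", origins = "matrix",
  sourceId = "character", kernel = "integer", stride = "integer",
  labels = "matrix", split = "character", fold = "integer"
))

setValidity("PatchSet", function(object) {
  n <- dim(object@pixels)[3]
  if (!all(dim(object@pixels) == dim(object@annotations)))
    return("pixels and annotations arrays must match in shape")
  if (dim(object@pixels)[1] != object@kernel || dim(object@pixels)[2] != object@kernel)
    return("patch arrays must be kernel x kernel")
  if (nrow(object@origins) != n || length(object@sourceId) != n)
    return("origins/sourceId length must equal patch count")
  if (nrow(object@labels) > 0 && (nrow(object@labels) != n || ncol(object@labels) != 3))
    return("labels must be an n x 3 logical matrix")
  if (length(object@split) != n || length(object@fold) != n)
    return("split/fold must have one entry per patch")
  TRUE
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %d x %d (stride %d) from %d image(s)\n",
              nPatches(object), object@kernel, object@kernel, object@stride,
              length(unique(object@sourceId))))
  if (nrow(object@labels) > 0) {
    pos <- colMeans(object@labels) * 100
    cat(sprintf("  label prevalence: Byproduct %.1f%%, Cell %.1f%%, Surface %.1f%%\n",
                pos[1], pos[2], pos[3]))
  }
  if (any(nzchar(object@split)))
    cat("  split:", paste(sprintf("%s=%d", names(table(object@split)),
                                  table(object@split)), collapse = ", "), "\n")
})

#' SplitPlan: representation-learning / fine-tune / test partition plan
#'
#' @slot reprFraction,finetuneFraction,testFraction numeric fractions summing
#'   to 1 (defaults 0.8 / 0.1 / 0.1).
#' @slot strategy "random_patch" (patch-wise shuffling) or "spatial_block"
#'   (overlap-connected groups of windows are kept together so held-out
#'   patches never share source pixels with other subsets).
#' @slot seed integer, shuffling seed.
#' @slot folds integer, number of cross-validation repeats/folds.
#' @export
setClass("SplitPlan", representation(
  reprFraction = "numeric", finetuneFraction = "numeric",
  testFraction = "numeric", strategy = "character", seed = "integer",
  folds = "integer"
))

setValidity("SplitPlan", function(object) {
  s <- object@reprFraction + object@finetuneFraction + object@testFraction
  if (abs(s - 1) > 1e-9) return("fractions must sum to 1")
  if (any(c(object@reprFraction, object@finetuneFraction, object@testFraction) < 0))
    return("fractions must be non-negative")
  if (!object@strategy %in% c("random_patch", "spatial_block"))
    return("strategy must be 'random_patch' or 'spatial_block'")
  if (object@folds < 2L) return("folds must be >= 2")
  TRUE
})

#' @rdname SplitPlan-class
#' @param reprFraction,finetuneFraction,testFraction,strategy,seed,folds see
#'   slots.
#' @return A validated `SplitPlan`.
#' @export
SplitPlan <- function(reprFraction = 0.8, finetuneFraction = 0.1,
                      testFraction = 0.1, strategy = "random_patch",
                      seed = 1L, folds = 10L) {
  new("SplitPlan", reprFraction = reprFraction,
      finetuneFraction = finetuneFraction, testFraction = testFraction,
      strategy = strategy, seed = as.integer(seed), folds = as.integer(folds))
}

#' EncoderState: encoder/projector parameters for self-supervised training
#'
#' Holds the query branch (convolutional encoder plus projector), and for the
#' contrastive variant the momentum branch of identical shape together with
#' the FIFO queue of negative keys. Hyperparameters: temperature `tau`
#' (InfoNCE similarity scaling), EMA coefficient `m` of the momentum encoder,
#' off-diagonal weight `lambda` of the redundancy-reduction objective.
#'
#' @slot variant "contrastive" or "noncontrastive".
#' @slot params list with `conv` (conv layer weights) and `proj` (linear
#'   projector weights) for the query/twin branch.
#' @slot momentumParams same shape as `params` (contrastive) or empty list.
#' @slot queue numeric matrix D x q of L2-normalized negative keys.
#' @slot queueCapacity integer FIFO capacity.
#' @slot hyper list: `tau`, `m`, `lambda`, optimizer settings.
#' @slot arch list: channels, projector widths, view size.
#' @slot lossTrace numeric, per-epoch mean training loss.
#' @slot config list, echo of the training configuration and seed.
#' @export
setClass("EncoderState", representation(
  variant = "character", params = "list", momentumParams = "list",
  queue = "matrix", queueCapacity = "integer", hyper = "list",
  arch = "list", lossTrace = "numeric", config = "list"
))

.congruent <- function(a, b) {
  if (is.list(a))
    return(is.list(b) && length(a) == length(b) &&
             all(vapply(seq_along(a), function(i) .congruent(a[[i]], b[[i]]), TRUE)))
  identical(dim(a), dim(b)) && length(a) == length(b)
}

setValidity("EncoderState", function(object) {
  if (!object@variant %in% c("contrastive", "noncontrastive"))
    return("variant must be 'contrastive' or 'noncontrastive'")
  h <- object@hyper
  if (!is.null(h$tau) && h$tau <= 0) return("temperature tau must be > 0")
  if (!is.null(h$m) && (h$m < 0 || h$m > 1)) return("momentum coefficient m must lie in [0, 1]")
  if (!is.null(h$lambda) && h$lambda < 0) return("lambda must be >= 0")
  if (object@variant == "contrastive") {
    if (!.congruent(object@params, object@momentumParams))
      return("query and momentum parameters must be shape-congruent")
    if (ncol(object@queue) > object@queueCapacity)
      return("queue exceeds capacity")
  }
  TRUE
})

setMethod("show", "EncoderState", function(object) {
  cat(sprintf("EncoderState (%s): conv channels [%s], projector dim %d\n",
              object@variant, paste(object@arch$channels, collapse = ", "),
              object@arch$projDim))
  if (object@variant == "contrastive")
    cat(sprintf("  negative queue: %d / %d keys\n", ncol(object@queue),
                object@queueCapacity))
  if (length(object@lossTrace))
    cat(sprintf("  trained %d epochs, loss %.4f -> %.4f\n",
                length(object@lossTrace), object@lossTrace[1],
                object@lossTrace[length(object@lossTrace)]))
})

#' EvalReport: cross-validated accuracy report
#'
#' Per-class and overall classification accuracy, each as mean and sample
#' standard deviation (percent) over cross-validation repeats. The overall
#' mean is by construction the arithmetic mean of the three per-class means.
#'
#' @slot perClassMean,perClassSd named numeric length-3, percent.
#' @slot overallMean,overallSd numeric, percent.
#' @slot nRepeats integer.
#' @slot protocol "linear" or "finetune" (or a free-form label).
#' @slot configEcho list of the hyperparameters used.
#' @export
setClass("EvalReport", representation(
  perClassMean = "numeric", perClassSd = "numeric",
  overallMean = "numeric", overallSd = "numeric", nRepeats = "integer",
  protocol = "character", configEcho = "list"
))

setValidity("EvalReport", function(object) {
  if (abs(object@overallMean - mean(object@perClassMean)) > 1e-9)
    return("overall mean must equal the mean of the per-class means")
  acc <- c(object@perClassMean, object@overallMean)
  if (any(acc < 0 - 1e-12) || any(acc > 100 + 1e-12))
    return("accuracies must lie in [0, 100] percent")
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s protocol, %d repeats)\n", object@protocol,
              object@nRepeats))
  nm <- c(.semClasses, "Overall")
  mu <- c(object@perClassMean, object@overallMean)
  sdv <- c(object@perClassSd, object@overallSd)
  for (i in seq_along(nm))
    cat(sprintf("  %-9s %6.2f +/- %.2f %%\n", nm[i], mu[i], sdv[i]))
})

#' ClassHeatmap: spatial distribution of one class over an image
#'
#' Grid over sliding-window patch origins; each cell holds the per-class
#' decision and score for the patch anchored there.
#'
#' @slot decisions logical matrix over the patch-origin grid.
#' @slot scores numeric matrix, same shape, per-class probability scores.
#' @slot kernel,stride integer pixels.
#' @slot targetClass character, one of [semClasses()].
#' @export
setClass("ClassHeatmap", representation(
  decisions = "matrix", scores = "matrix", kernel = "integer",
  stride = "integer", targetClass = "character"
))

setMethod("show", "ClassHeatmap", function(object) {
  cat(sprintf("ClassHeatmap '%s': %d x %d patch grid (kernel %d, stride %d), %.1f%% positive\n",
              object@targetClass, nrow(object@decisions), ncol(object@decisions),
              object@kernel, object@stride, 100 * mean(object@decisions)))
})
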