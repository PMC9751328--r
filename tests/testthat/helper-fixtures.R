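# shared fixtures: everything is generated in code at test time

tinySpec <- function(...) {
  args <- list(width = 160L, height = 160L, nCells = 8L, nClusters = 1L,
               clusterSizeRange = c(3L, 5L), nByproductBlobs = 4L,
               byproductRadiusRange = c(6, 18), cellAxisRange = c(8, 20),
               metaStripHeight = 0L)
  override <- list(...)
  args[names(override)] <- override
  do.call(SceneSpec, args)
}

tinyImage <- function(seed = 1, ...) generateScene(tinySpec(...), seed)

# labeled patch set from a couple of small scenes
tinyPatchSet <- function(kernel = 32L, stride = 16L, nImages = 2,
                         seed = 1, minFraction = 0.01) {
  imgs <- generateDataset(nImages, tinySpec(), seed)
  deriveLabels(extractPatches(imgs, kernel, stride), minFraction)
}

# handmade AnnotatedImage with a deterministic annotation layout
flatImage <- function(H = 64, W = 64, value = 128, class = 3L, strip = 0L) {
  AnnotatedImage(matrix(value, H, W), matrix(class, H, W),
                 metaStripHeight = strip)
}

ns <- asNamespace("SEMBiofilm")

smallEncoder <- function(seed = 5)
  ns$initEncoderState("noncontrastive",
                      pretrainConfig(channels = c(6L, 12L), projDim = 16L,
                                     projHidden = 16L, seed = seed))

# patch set whose mean brightness separates the Cell label perfectly:
# positives are bright blocks, negatives dark ones
separablePatchSet <- function(n = 40, k = 32L, seed = 1,
                              surfaceTwoSided = FALSE) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  surf <- if (surfaceTwoSided) rep(c(TRUE, TRUE, TRUE, FALSE), length.out = n)
          else rep(TRUE, n)
  px <- array(0, c(k, k, n)); an <- array(3L, c(k, k, n))
  for (i in seq_len(n)) {
    px[, , i] <- matrix(runif(k * k, 0, 30) + if (y[i]) 180 else 40, k, k)
    if (y[i]) an[1:8, 1:8, i] <- 2L
    if (!surf[i]) an[, , i] <- 1L
  }
  new("PatchSet", pixels = px, annotations = an,
      origins = matrix(0L, n, 2), sourceId = rep("s", n), kernel = k,
      stride = k, labels = cbind(Byproduct = rep(c(TRUE, FALSE), length.out = n),
                                 Cell = y, Surface = surf),
      split = rep("finetune", n), fold = rep(1L, n))
}

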