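# Synthetic SEM-like biofilm scenes with pixel-level tri-class ground truth.
# These stand-ins emulate the gross appearance statistics of SEM biofilm
# frames -- bright rod/ellipse cells (singly and clustered), mid-grey granular
# corrosion-byproduct blobs, dark textured metal surface, additive noise and a
# black instrument metadata strip -- so the whole pipeline is exercisable
# without access-restricted microscope data.

# unit-variance smooth random field, correlation length ~ gridStep pixels
.smoothField <- function(H, W, gridStep = 16) {
  ch <- max(2L, ceiling(H / gridStep) + 1L)
  cw <- max(2L, ceiling(W / gridStep) + 1L)
  f <- resizeBilinear(matrix(rnorm(ch * cw), ch, cw), H, W)
  f / max(sd(f), 1e-8)
}

# paint one granular byproduct blob; returns updated (px, ann, occ)
.paintBlob <- function(px, ann, occ, spec) {
  H <- nrow(px); W <- ncol(px)
  rr <- spec@byproductRadiusRange
  for (try in 1:100) {
    r <- runif(1, rr[1], rr[2])
    r0 <- sample.int(H, 1); c0 <- sample.int(W, 1)
    rows <- max(1, floor(r0 - r)):min(H, ceiling(r0 + r))
    cols <- max(1, floor(c0 - r)):min(W, ceiling(c0 + r))
    d2 <- outer((rows - r0)^2, (cols - c0)^2, "+") / max(r^2, 1)
    gran <- .smoothField(length(rows), length(cols), gridStep = max(2, r / 2))
    # solid core with an irregular granular rim: large blobs form byproduct
    # mats that can fully occlude the surface locally
    mask <- d2 <= 0.5 | (d2 <= 1 & gran > -0.4)
    if (!any(mask)) next
    if (!spec@overlapAllowed && any(occ[rows, cols][mask])) next
    sub <- px[rows, cols]
    sub[mask] <- 150 + 22 * gran[mask]
    px[rows, cols] <- sub
    asub <- ann[rows, cols]; asub[mask] <- 1L; ann[rows, cols] <- asub
    occ[rows, cols] <- occ[rows, cols] | mask
    break
  }
  list(px = px, ann = ann, occ = occ)
}

# paint one elliptical cell (rod-like morphology at toy scale)
.paintCell <- function(px, ann, occ, spec, center = NULL, spread = 0) {
  H <- nrow(px); W <- ncol(px)
  ar <- spec@cellAxisRange
  for (try in 1:100) {
    a <- runif(1, ar[1], ar[2]) / 2                 # semi-major
    b <- a * runif(1, 0.35, 0.65)                   # semi-minor
    th <- runif(1, 0, pi)
    if (is.null(center)) {
      r0 <- sample.int(H, 1); c0 <- sample.int(W, 1)
    } else {
      r0 <- round(center[1] + rnorm(1, 0, spread))
      c0 <- round(center[2] + rnorm(1, 0, spread))
      if (r0 < 1 || r0 > H || c0 < 1 || c0 > W) next
    }
    ext <- ceiling(a)
    rows <- max(1, r0 - ext):min(H, r0 + ext)
    cols <- max(1, c0 - ext):min(W, c0 + ext)
    dr <- matrix(rows - r0, length(rows), length(cols))
    dc <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    q <- (u / a)^2 + (v / b)^2
    mask <- q <= 1
    if (!any(mask)) next
    if (!spec@overlapAllowed && any(occ[rows, cols][mask])) next
    sub <- px[rows, cols]
    sub[mask] <- 168 + 34 * (1 - sqrt(pmax(q[mask], 0)))  # shaded rod profile
    px[rows, cols] <- sub
    asub <- ann[rows, cols]; asub[mask] <- 2L; ann[rows, cols] <- asub
    occ[rows, cols] <- occ[rows, cols] | mask
    break
  }
  list(px = px, ann = ann, occ = occ)
}

# Each scene element draws from its own RNG substream (derived from the
# scene seed and the element index), so enlarging one object count leaves
# every other element bit-identical: class pixel fractions respond
# monotonically to their count parameters.
.renderScene <- function(spec, seed) {
  H <- spec@height; W <- spec@width
  px <- withSeed(deriveSeed(seed, "background"),
                 75 + spec@backgroundTextureScale * .smoothField(H, W) +
                   3 * .smoothField(H, W, gridStep = 4))
  ann <- matrix(3L, H, W)
  occ <- matrix(FALSE, H, W)
  # byproducts below cells: annotation keeps the topmost object class
  for (i in seq_len(spec@nByproductBlobs)) {
    s <- withSeed(deriveSeed(seed, paste0("blob-", i)),
                  .paintBlob(px, ann, occ, spec))
    px <- s$px; ann <- s$ann; occ <- s$occ
  }
  for (i in seq_len(spec@nCells)) {
    s <- withSeed(deriveSeed(seed, paste0("cell-", i)),
                  .paintCell(px, ann, occ, spec))
    px <- s$px; ann <- s$ann; occ <- s$occ
  }
  for (i in seq_len(spec@nClusters)) {
    s <- withSeed(deriveSeed(seed, paste0("cluster-", i)), {
      ctr <- c(sample.int(H, 1), sample.int(W, 1))
      k <- sample(seq(spec@clusterSizeRange[1], spec@clusterSizeRange[2]), 1)
      spread <- 0.6 * mean(spec@cellAxisRange)
      st <- list(px = px, ann = ann, occ = occ)
      for (j in seq_len(k))
        st <- .paintCell(st$px, st$ann, st$occ, spec, center = ctr,
                         spread = spread)
      st
    })
    px <- s$px; ann <- s$ann; occ <- s$occ
  }
  # slowly varying illumination/charging field, distinct per image: SEM
  # frames differ in brightness and gain across acquisitions
  illum <- withSeed(deriveSeed(seed, "illumination"),
                    1 + 0.12 * .smoothField(H, W, gridStep = max(H, W) / 3))
  px <- px * illum +
    withSeed(deriveSeed(seed, "noise"), rnorm(H * W, 0, spec@noiseSd))
  px <- round(pmin(pmax(px, 0), 255))
  if (spec@metaStripHeight > 0) {
    strip <- withSeed(deriveSeed(seed, "strip"), {
      s <- matrix(0, spec@metaStripHeight, W)
      # synthetic "text" marks: a few bright rectangles along the strip
      mh <- max(1L, floor(spec@metaStripHeight / 3))
      top <- max(1L, floor(spec@metaStripHeight / 3))
      for (i in 1:6) {
        mw <- sample(10:30, 1)
        c0 <- sample.int(max(1L, W - mw), 1)
        s[top:(top + mh - 1), c0:(c0 + mw - 1)] <- 220
      }
      s
    })
    px <- rbind(px, strip)
    ann <- rbind(ann, matrix(3L, spec@metaStripHeight, W))
  }
  AnnotatedImage(px, ann, magnificationLabel = spec@magnificationLabel,
                 scaleUm = spec@scaleUm,
                 metaStripHeight = spec@metaStripHeight)
}

#' Generate one synthetic annotated SEM-like scene
#'
#' Renders a textured-metal background, granular byproduct blobs and bright
#' elliptical cells (singly and in Gaussian-scattered clusters), assigns every
#' pixel the topmost object class (Surface where nothing was painted), adds
#' Gaussian pixel noise, and, if `metaStripHeight > 0`, appends a black
#' metadata strip with synthetic text marks at the bottom (annotated as
#' Surface). Bit-identical output for identical `(spec, seed)`.
#'
#' @param spec a [SceneSpec()].
#' @param seed integer seed.
#' @return An [AnnotatedImage-class].
#' @export
#' @examples
#' img <- generateScene(SceneSpec(width = 128L, height = 128L, nCells = 6L,
#'                                nClusters = 1L, nByproductBlobs = 3L,
#'                                metaStripHeight = 0L), seed = 1)
generateScene <- function(spec, seed) {
  validObject(spec)
  .renderScene(spec, as.integer(seed))
}

#' Generate a dataset of synthetic annotated scenes
#'
#' Draws `nImages` scenes from the same [SceneSpec()] under per-image seeds
#' derived from `seed`. Optionally writes grayscale PNGs, tri-color
#' annotation PNGs and a tab-delimited metadata table to `dir`.
#'
#' @param nImages number of images (>= 1).
#' @param spec a [SceneSpec()].
#' @param seed integer global seed.
#' @param dir optional output directory.
#' @return Named list of [AnnotatedImage-class] objects.
#' @export
generateDataset <- function(nImages, spec, seed, dir = NULL) {
  if (length(nImages) != 1L || is.na(nImages) || nImages < 1)
    .stopf("nImages must be >= 1 (got %s)", format(nImages))
  nImages <- as.integer(nImages)
  imgs <- lapply(seq_len(nImages), function(i)
    generateScene(spec, deriveSeed(seed, paste0("image-", i))))
  names(imgs) <- sprintf("img-%02d", seq_len(nImages))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(imgs)) writeAnnotatedImage(imgs[[nm]], dir, nm)
    meta <- data.frame(
      filename = paste0(names(imgs), ".png"),
      magnification_label = vapply(imgs, function(x) x@meta$magnificationLabel, 0),
      scale_um = vapply(imgs, function(x) x@meta$scaleUm, 0),
      meta_strip_height = vapply(imgs, function(x) x@meta$metaStripHeight, 0L)
    )
    write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  imgs
}

#' Convert between class-coded annotations and their RGB rendering
#'
#' The on-disk convention renders Cell in blue (0,0,255), Byproduct in pink
#' (255,105,180) and Surface in green (0,255,0). The mapping is lossless in
#' both directions; unknown colors are rejected.
#'
#' @param annotation integer matrix of class codes 1:3.
#' @return `annotationToRGB`: integer array `[H, W, 3]` in 0-255.
#' @export
annotationToRGB <- function(annotation) {
  arr <- array(0L, c(dim(annotation), 3L))
  for (ch in 1:3) {
    m <- matrix(.semColors[annotation, ch], nrow(annotation), ncol(annotation))
    arr[, , ch] <- m
  }
  arr
}

#' @rdname annotationToRGB
#' @param rgb integer array `[H, W, 3]` with the exact class colors.
#' @return `rgbToAnnotation`: integer matrix of class codes.
#' @export
rgbToAnnotation <- function(rgb) {
  key <- rgb[, , 1] * 65536L + rgb[, , 2] * 256L + rgb[, , 3]
  colKey <- .semColors[, 1] * 65536L + .semColors[, 2] * 256L + .semColors[, 3]
  ann <- matrix(match(key, colKey), nrow(key), ncol(key))
  if (anyNA(ann))
    .stopf("annotation contains %d pixel(s) with colors outside the blue/pink/green coding",
           sum(is.na(ann)))
  storage.mode(ann) <- "integer"
  ann
}
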