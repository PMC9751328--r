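# Preprocessing: metadata-strip removal, CLAHE contrast enhancement, and
# conditional super-resolution to normalize object sizes across magnification
# scales. Pipeline order is crop -> contrast -> (conditional) super-resolve.

#' PreprocessConfig: preprocessing parameters
#'
#' @slot claheClipLimit numeric, CLAHE clip limit (> 0).
#' @slot claheTileGrid integer length-2, contextual tile grid (nx, ny).
#' @slot srFactor integer, super-resolution scale factor (>= 1).
#' @slot srBackend "classical_bicubic" (built-in cubic-convolution upscale) or
#'   "pluggable_learned" (caller supplies a function via `srBackendFn`).
#' @slot srScaleThresholdUm numeric, apply super-resolution only when the
#'   scale bar is at least this many micrometers.
#' @slot srMagnificationThreshold numeric, and the magnification is strictly
#'   below this value.
#' @slot srBackendFn list holding an optional `fn(pixels, factor)` for the
#'   learned backend.
#' @export
setClass("PreprocessConfig", representation(
  claheClipLimit = "numeric", claheTileGrid = "integer", srFactor = "integer",
  srBackend = "character", srScaleThresholdUm = "numeric",
  srMagnificationThreshold = "numeric", srBackendFn = "list"
))

setValidity("PreprocessConfig", function(object) {
  if (object@claheClipLimit <= 0) return("claheClipLimit must be > 0")
  if (length(object@claheTileGrid) != 2L || any(object@claheTileGrid < 1L))
    return("claheTileGrid must be two positive counts")
  if (object@srFactor < 1L) return("srFactor must be >= 1")
  if (!object@srBackend %in% c("classical_bicubic", "pluggable_learned"))
    return(sprintf("unknown srBackend '%s'", object@srBackend))
  if (object@srScaleThresholdUm <= 0 || object@srMagnificationThreshold <= 0)
    return("super-resolution thresholds must be > 0")
  TRUE
})

#' @rdname PreprocessConfig-class
#' @param claheClipLimit,claheTileGrid,srFactor,srBackend see slots.
#' @param srScaleThresholdUm,srMagnificationThreshold,srBackendFn see slots.
#' @return A validated `PreprocessConfig`.
#' @export
#' @examples PreprocessConfig()
PreprocessConfig <- function(claheClipLimit = 2, claheTileGrid = c(8L, 8L),
                             srFactor = 4L, srBackend = "classical_bicubic",
                             srScaleThresholdUm = 10,
                             srMagnificationThreshold = 1000,
                             srBackendFn = NULL) {
  new("PreprocessConfig", claheClipLimit = claheClipLimit,
      claheTileGrid = as.integer(claheTileGrid), srFactor = as.integer(srFactor),
      srBackend = srBackend, srScaleThresholdUm = srScaleThresholdUm,
      srMagnificationThreshold = srMagnificationThreshold,
      srBackendFn = if (is.null(srBackendFn)) list() else list(fn = srBackendFn))
}

#' Remove the instrument metadata strip
#'
#' Drops the bottom `metaStripHeight` rows from both the pixels and the
#' annotation (the strip carries magnification/scale text, not sample
#' content) and resets the recorded strip height to 0.
#'
#' @param img an [AnnotatedImage-class].
#' @return The cropped [AnnotatedImage-class].
#' @export
cropMetaStrip <- function(img) {
  h <- img@meta$metaStripHeight
  H <- nrow(img@pixels)
  if (h >= H) .stopf("metaStripHeight (%d) must be smaller than the image height (%d)", h, H)
  if (h == 0L) return(img)
  keep <- seq_len(H - h)
  AnnotatedImage(img@pixels[keep, , drop = FALSE],
                 img@annotation[keep, , drop = FALSE],
                 magnificationLabel = img@meta$magnificationLabel,
                 scaleUm = img@meta$scaleUm, metaStripHeight = 0L)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Sharpens the class objects with CLAHE (via EBImage). The annotation is
#' untouched and dimensions are preserved.
#'
#' @param img an [AnnotatedImage-class].
#' @param cfg a [PreprocessConfig()].
#' @return The contrast-enhanced [AnnotatedImage-class].
#' @export
enhanceContrast <- function(img, cfg = PreprocessConfig()) {
  validObject(cfg)
  x <- EBImage::Image(t(img@pixels) / 255)
  y <- EBImage::clahe(x, nx = cfg@claheTileGrid[1], ny = cfg@claheTileGrid[2],
                      limit = cfg@claheClipLimit)
  px <- pmin(pmax(t(EBImage::imageData(y)) * 255, 0), 255)
  AnnotatedImage(px, img@annotation,
                 magnificationLabel = img@meta$magnificationLabel,
                 scaleUm = img@meta$scaleUm,
                 metaStripHeight = img@meta$metaStripHeight)
}

#' Decide whether an image should be super-resolved
#'
#' Frames captured at coarse scale and low magnification carry small objects
#' and get upscaled; high-magnification close-ups do not. True iff
#' `scaleUm >= srScaleThresholdUm` and
#' `magnificationLabel < srMagnificationThreshold` (strict).
#'
#' @param meta metadata list with `scaleUm` and `magnificationLabel` (an
#'   [AnnotatedImage-class] is also accepted).
#' @param cfg a [PreprocessConfig()].
#' @return Logical flag.
#' @export
#' @examples
#' shouldSuperResolve(list(scaleUm = 10, magnificationLabel = 436))
shouldSuperResolve <- function(meta, cfg = PreprocessConfig()) {
  if (is(meta, "AnnotatedImage")) meta <- meta@meta
  if (is.null(meta$scaleUm) || is.null(meta$magnificationLabel) ||
      is.na(meta$scaleUm) || is.na(meta$magnificationLabel))
    .stopf("metadata must provide scaleUm and magnificationLabel")
  meta$scaleUm >= cfg@srScaleThresholdUm &&
    meta$magnificationLabel < cfg@srMagnificationThreshold
}

#' Super-resolve an annotated image
#'
#' Upscales the pixels by `srFactor` with the configured backend (built-in
#' cubic-convolution interpolation, or a supplied learned model) and the
#' annotation by nearest neighbour with the same factor, so pixel-level
#' labels stay aligned after enhancement.
#'
#' @param img an [AnnotatedImage-class].
#' @param cfg a [PreprocessConfig()].
#' @return The upscaled [AnnotatedImage-class].
#' @export
superResolve <- function(img, cfg = PreprocessConfig()) {
  validObject(cfg)
  f <- cfg@srFactor
  if (f == 1L) return(img)
  px <- switch(cfg@srBackend,
    classical_bicubic = bicubicUpscale(img@pixels, f),
    pluggable_learned = {
      if (is.null(cfg@srBackendFn$fn))
        .stopf("srBackend 'pluggable_learned' requires srBackendFn")
      cfg@srBackendFn$fn(img@pixels, f)
    },
    .stopf("unknown srBackend '%s'", cfg@srBackend))
  px <- pmin(pmax(px, 0), 255)
  AnnotatedImage(px, nearestUpscale(img@annotation, f),
                 magnificationLabel = img@meta$magnificationLabel,
                 scaleUm = img@meta$scaleUm,
                 metaStripHeight = img@meta$metaStripHeight)
}

#' Full preprocessing pipeline for one image
#'
#' Crop the metadata strip, apply CLAHE, then super-resolve when the
#' scale/magnification rule fires.
#'
#' @param img an [AnnotatedImage-class].
#' @param cfg a [PreprocessConfig()].
#' @return The preprocessed [AnnotatedImage-class].
#' @export
preprocessImage <- function(img, cfg = PreprocessConfig()) {
  out <- enhanceContrast(cropMetaStrip(img), cfg)
  if (shouldSuperResolve(out@meta, cfg)) out <- superResolve(out, cfg)
  out
}
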