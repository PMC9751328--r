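# Reading/writing images through EBImage. Internal matrix convention is
# rows x cols (row = image row); EBImage stores x (width) first, so matrices
# are transposed at the boundary.

#' Write an annotated image pair to disk
#'
#' Writes `<name>.png` (8-bit grayscale) and `<name>_annotation.png` (RGB with
#' the exact blue/pink/green class colors).
#'
#' @param img an [AnnotatedImage-class].
#' @param dir output directory.
#' @param name file basename.
#' @return Invisibly, the two file paths.
#' @export
writeAnnotatedImage <- function(img, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pGray <- file.path(dir, paste0(name, ".png"))
  pAnn <- file.path(dir, paste0(name, "_annotation.png"))
  EBImage::writeImage(EBImage::Image(t(img@pixels) / 255), pGray)
  rgb <- annotationToRGB(img@annotation)
  EBImage::writeImage(EBImage::Image(aperm(rgb, c(2, 1, 3)) / 255,
                                     colormode = "Color"), pAnn)
  invisible(c(pGray, pAnn))
}

#' Read an annotated image pair from disk
#'
#' @param imagePath grayscale PNG/TIFF path.
#' @param annotationPath RGB annotation PNG path.
#' @param magnificationLabel,scaleUm,metaStripHeight acquisition metadata.
#' @return An [AnnotatedImage-class].
#' @export
readAnnotatedImage <- function(imagePath, annotationPath,
                               magnificationLabel = 436, scaleUm = 10,
                               metaStripHeight = 0L) {
  g <- EBImage::readImage(imagePath)
  px <- round(t(EBImage::imageData(g)) * 255)
  a <- EBImage::imageData(EBImage::readImage(annotationPath))
  if (length(dim(a)) != 3L || dim(a)[3] < 3L)
    .stopf("annotation at '%s' is not an RGB image", annotationPath)
  rgb <- aperm(a[, , 1:3], c(2, 1, 3))
  ann <- rgbToAnnotation(array(as.integer(round(rgb * 255)), dim(rgb)))
  AnnotatedImage(px, ann, magnificationLabel = magnificationLabel,
                 scaleUm = scaleUm, metaStripHeight = metaStripHeight)
}
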