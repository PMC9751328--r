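#' @name accessors
#' @title Accessors for package classes
#' @param object a package object.
#' @param value replacement value.
#' @return The slot contents (or the modified object for setters).
NULL

#' @rdname accessors
#' @export
setGeneric("nPatches", function(object) standardGeneric("nPatches"))
#' @rdname accessors
#' @export
setGeneric("patchPixels", function(object) standardGeneric("patchPixels"))
#' @rdname accessors
#' @export
setGeneric("patchAnnotations", function(object) standardGeneric("patchAnnotations"))
#' @rdname accessors
#' @export
setGeneric("patchOrigins", function(object) standardGeneric("patchOrigins"))
#' @rdname accessors
#' @export
setGeneric("patchLabels", function(object) standardGeneric("patchLabels"))
#' @rdname accessors
#' @export
setGeneric("patchLabels<-", function(object, value) standardGeneric("patchLabels<-"))
#' @rdname accessors
#' @export
setGeneric("patchSplit", function(object) standardGeneric("patchSplit"))
#' @rdname accessors
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setGeneric("imageAnnotation", function(object) standardGeneric("imageAnnotation"))
#' @rdname accessors
#' @export
setGeneric("imageMeta", function(object) standardGeneric("imageMeta"))

#' @rdname accessors
#' @export
setMethod("nPatches", "PatchSet", function(object) dim(object@pixels)[3])
#' @rdname accessors
#' @export
setMethod("patchPixels", "PatchSet", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("patchAnnotations", "PatchSet", function(object) object@annotations)
#' @rdname accessors
#' @export
setMethod("patchOrigins", "PatchSet", function(object) object@origins)
#' @rdname accessors
#' @export
setMethod("patchLabels", "PatchSet", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("patchLabels<-", "PatchSet", function(object, value) {
  object@labels <- value
  validObject(object)
  object
})
#' @rdname accessors
#' @export
setMethod("patchSplit", "PatchSet", function(object) object@split)
#' @rdname accessors
#' @export
setMethod("imagePixels", "AnnotatedImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("imageAnnotation", "AnnotatedImage", function(object) object@annotation)
#' @rdname accessors
#' @export
setMethod("imageMeta", "AnnotatedImage", function(object) object@meta)

#' @rdname deriveLabels
#' @export
setGeneric("deriveLabels", function(object, minFraction = 0.01)
  standardGeneric("deriveLabels"))

#' @rdname momentumUpdate
#' @export
setGeneric("momentumUpdate", function(state) standardGeneric("momentumUpdate"))
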