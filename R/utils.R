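#' @import methods
#' @importFrom stats rnorm runif sd quantile
#' @importFrom utils write.table read.table head
#' @useDynLib SEMBiofilm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# class coding shared across all modules: integer codes in annotation maps and
# the exact RGB rendering used on disk
.semClasses <- c("Byproduct", "Cell", "Surface")
.semColors <- rbind(
  Byproduct = c(255L, 105L, 180L),  # pink
  Cell      = c(0L, 0L, 255L),      # blue
  Surface   = c(0L, 255L, 0L)       # green
)

#' Class names used throughout the package
#'
#' The three morphological constituents scored in SEM biofilm images:
#' corrosion/biofilm byproducts, microbial cells (including clusters), and
#' non-occluded metal surface.
#' @return Character vector of the three class names, in coding order.
#' @export
#' @examples semClasses()
semClasses <- function() .semClasses

# evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from the global run seed and the stage name, so stages are reproducible in
#' isolation and independent of each other's random-number consumption.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples deriveSeed(1, "synth")
deriveSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  m <- 2147483629
  h <- as.double(seed %% m)
  for (u in utf8ToInt(stage)) h <- (h * 69069 + u) %% m
  as.integer(h) + 1L
}

# separable bilinear resize of a matrix to (outH, outW); weights are built per
# axis so the hot training loop avoids per-pixel interpolation in R
.axisWeights <- function(nIn, nOut) {
  if (nIn == nOut) return(diag(nOut))
  # centers aligned: output pixel center maps to input coordinate space
  pos <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5 - 1  # 0-based input coord
  lo <- floor(pos)
  fr <- pos - lo
  lo <- pmin(pmax(lo, 0), nIn - 1)
  hi <- pmin(lo + 1, nIn - 1)
  A <- matrix(0, nOut, nIn)
  A[cbind(seq_len(nOut), lo + 1)] <- A[cbind(seq_len(nOut), lo + 1)] + (1 - fr)
  A[cbind(seq_len(nOut), hi + 1)] <- A[cbind(seq_len(nOut), hi + 1)] + fr
  A
}

resizeBilinear <- function(x, outH, outW) {
  if (nrow(x) == outH && ncol(x) == outW) return(x)
  .axisWeights(nrow(x), outH) %*% x %*% t(.axisWeights(ncol(x), outW))
}

# Catmull-Rom cubic-convolution upscale by an integer factor (reflected edges)
.cubicKernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

.cubicAxisWeights <- function(nIn, factor) {
  nOut <- nIn * factor
  pos <- (seq_len(nOut) - 0.5) / factor + 0.5 - 1
  base <- floor(pos)
  A <- matrix(0, nOut, nIn)
  for (k in -1:2) {
    j <- base + k
    wt <- .cubicKernel(pos - j)
    j <- pmin(pmax(j, 0), nIn - 1)             # reflect/clamp at borders
    ij <- cbind(seq_len(nOut), j + 1)
    A[ij] <- A[ij] + wt
  }
  A / rowSums(A)
}

bicubicUpscale <- function(x, factor) {
  if (factor == 1) return(x)
  .cubicAxisWeights(nrow(x), factor) %*% x %*% t(.cubicAxisWeights(ncol(x), factor))
}

# nearest-neighbour integer upscale (label maps)
nearestUpscale <- function(x, factor) {
  if (factor == 1) return(x)
  x[rep(seq_len(nrow(x)), each = factor), rep(seq_len(ncol(x)), each = factor),
    drop = FALSE]
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
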