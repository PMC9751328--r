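# Evaluation: prediction accuracy (correct / total), cross-validated
# mean +/- sd reports, class activation maps, and per-image class-distribution
# heatmaps over the patch grid.

#' Classification accuracy
#'
#' Number of correct predictions over total predictions. For multi-label
#' matrices every (patch, class) decision counts as one prediction.
#'
#' @param predictions,truths aligned logical/numeric vectors or matrices.
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples classificationAccuracy(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
classificationAccuracy <- function(predictions, truths) {
  if (length(predictions) == 0) .stopf("empty prediction set")
  if (length(predictions) != length(truths))
    .stopf("predictions and truths differ in length (%d vs %d)",
           length(predictions), length(truths))
  mean(predictions == truths)
}

#' Build an EvalReport from per-repeat, per-class accuracies
#'
#' @param accMatrix numeric matrix (repeats x 3 classes) of accuracies as
#'   proportions in `[0, 1]`.
#' @param protocol report label ("linear", "finetune", ...).
#' @param configEcho list echoed into the report.
#' @return An [EvalReport-class] in percent; the overall mean equals the mean
#'   of the per-class means, and sds are sample standard deviations (n - 1).
#' @export
evalReport <- function(accMatrix, protocol = "finetune", configEcho = list()) {
  accMatrix <- as.matrix(accMatrix) * 100
  colnames(accMatrix) <- .semClasses
  perRepOverall <- rowMeans(accMatrix)
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  new("EvalReport",
      perClassMean = colMeans(accMatrix),
      perClassSd = apply(accMatrix, 2, sd0),
      overallMean = mean(perRepOverall), overallSd = sd0(perRepOverall),
      nRepeats = nrow(accMatrix), protocol = protocol,
      configEcho = configEcho)
}

#' Cross-validated evaluation
#'
#' Runs `pipelineFn` over `folds` repeats and aggregates per-class accuracy
#' into an [EvalReport-class]. With `scheme = "repeated_split"` each repeat
#' draws a fresh random train/test partition of the labeled pool at
#' `1 - testFraction` / `testFraction`; with `scheme = "kfold"` the pool is
#' cut once into `folds` folds and each serves as the test set in turn.
#' Deterministic given `seed`.
#'
#' @param pipelineFn `function(trainIdx, testIdx, seed)` returning a length-3
#'   named vector of per-class accuracies (proportions).
#' @param n size of the labeled pool being resampled.
#' @param folds number of repeats/folds (>= 2).
#' @param seed integer seed.
#' @param scheme "repeated_split" or "kfold".
#' @param testFraction held-out fraction under "repeated_split".
#' @param protocol,configEcho passed to [evalReport()].
#' @return An [EvalReport-class].
#' @export
crossValidate <- function(pipelineFn, n, folds = 10L, seed = 1L,
                          scheme = c("repeated_split", "kfold"),
                          testFraction = 0.5, protocol = "finetune",
                          configEcho = list()) {
  scheme <- match.arg(scheme)
  folds <- as.integer(folds)
  if (folds < 2L) .stopf("folds must be >= 2")
  if (n < folds) .stopf("insufficient data: %d observations for %d folds", n, folds)
  acc <- matrix(NA_real_, folds, 3)
  withSeed(deriveSeed(seed, "cv"), {
    foldId <- if (scheme == "kfold") rep_len(seq_len(folds), n)[sample.int(n)]
    for (r in seq_len(folds)) {
      if (scheme == "repeated_split") {
        test <- sample.int(n, max(1L, round(n * testFraction)))
      } else {
        test <- which(foldId == r)
      }
      train <- setdiff(seq_len(n), test)
      acc[r, ] <- pipelineFn(train, test, deriveSeed(seed, paste0("cv-", r)))
    }
  })
  evalReport(acc, protocol = protocol,
             configEcho = c(configEcho, list(folds = folds, seed = seed,
                                             scheme = scheme)))
}

#' Write an EvalReport as text and key-value tables
#'
#' `<path>.txt` holds the human-readable accuracy table (rows = one method,
#' columns Byproduct/Cell/Surface/Overall as "mean +/- sd"); `<path>.tsv`
#' holds the machine-readable long form.
#'
#' @param report an [EvalReport-class].
#' @param path output path prefix.
#' @param method row label.
#' @return Invisibly, the two file paths.
#' @export
writeEvalReport <- function(report, path, method = report@protocol) {
  nm <- c(.semClasses, "Overall")
  mu <- c(report@perClassMean, report@overallMean)
  sdv <- c(report@perClassSd, report@overallSd)
  txt <- paste0(method, "\t",
                paste(sprintf("%.2f +/- %.2f", mu, sdv), collapse = "\t"))
  writeLines(c(paste(c("Method", nm), collapse = "\t"), txt),
             paste0(path, ".txt"))
  write.table(data.frame(method = method, class = nm, mean_pct = mu,
                         sd_pct = sdv, n_repeats = report@nRepeats),
              paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paste0(path, c(".txt", ".tsv")))
}

#' Class activation map for one patch
#'
#' Weighted sum of the final convolutional feature maps with the class head's
#' weights (the global-average-pooling construction), upsampled bilinearly to
#' the patch size and min-max normalized to `[0, 1]`. A constant map is
#' returned as 0.5 everywhere.
#'
#' @param model a "semBinaryModel" classifier.
#' @param patch numeric matrix; its sides must survive the encoder's
#'   pooling stages (divisible by `2^depth`).
#' @return Numeric matrix of the patch shape with values in `[0, 1]`.
#' @export
generateCAM <- function(model, patch) {
  if (!inherits(model, "semBinaryModel"))
    .stopf("CAM requires a convolutional classifier exposing feature maps")
  depth <- length(model$encoder@params$conv)
  if (any(dim(patch) %% (2^depth) != 0))
    .stopf("patch dims must be divisible by %d for this encoder", 2^depth)
  fwd <- encoderForward(model$encoder@params$conv,
                        array(patch / 255, c(dim(patch), 1L, 1L)),
                        keepCache = FALSE)
  d <- fwd$mapDim
  fm <- fwd$maps; dim(fm) <- c(d[1] * d[2], d[3])
  wEff <- model$head$W[, 1]
  if (!is.null(model$norm)) wEff <- wEff / model$norm$sd  # undo feature scaling
  cam <- matrix(fm %*% wEff, d[1], d[2])
  cam <- resizeBilinear(cam, nrow(patch), ncol(patch))
  rng <- range(cam)
  if (diff(rng) < 1e-12) return(matrix(0.5, nrow(patch), ncol(patch)))
  (cam - rng[1]) / diff(rng)
}

#' Per-image class-distribution heatmaps
#'
#' Slides the patch window over a preprocessed image, predicts the three
#' class presences for every patch, and arranges decisions and scores on the
#' patch-origin grid -- the spatial distribution of cells, byproducts and
#' non-occluded surface across the frame.
#'
#' @param img an [AnnotatedImage-class].
#' @param models output of [trainMultiLabel()] / [trainSupervisedBaseline()]
#'   or an [oracleModel()].
#' @param kernel,stride sliding-window geometry in pixels.
#' @return Named list of three [ClassHeatmap-class] objects.
#' @export
classDistributionHeatmap <- function(img, models, kernel, stride) {
  ps <- extractPatches(img, kernel, stride)
  pred <- predictMultilabel(models, ps)
  nR <- length(unique(ps@origins[, 1]))
  nC <- length(unique(ps@origins[, 2]))
  out <- lapply(.semClasses, function(cl) {
    new("ClassHeatmap",
        decisions = matrix(pred$decisions[, cl], nR, nC),
        scores = matrix(pred$scores[, cl], nR, nC),
        kernel = ps@kernel, stride = ps@stride, targetClass = cl)
  })
  names(out) <- .semClasses
  out
}

#' Write a heatmap as a PNG overlay and a delimited table
#'
#' @param hm a [ClassHeatmap-class].
#' @param path output prefix (writes `<path>.png` and `<path>.tsv`).
#' @return Invisibly, the file paths.
#' @export
writeHeatmap <- function(hm, path) {
  sc <- hm@scores
  EBImage::writeImage(EBImage::Image(t(sc)), paste0(path, ".png"))
  tb <- data.frame(row = rep(seq_len(nrow(sc)) - 1L, ncol(sc)) * hm@stride,
                   col = rep(seq_len(ncol(sc)) - 1L, each = nrow(sc)) * hm@stride,
                   score = as.vector(sc), decision = as.vector(hm@decisions))
  write.table(tb, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paste0(path, c(".png", ".tsv")))
}
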