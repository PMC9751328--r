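# Binary-relevance downstream classification: one binary head per class
# (K = 3), under a linear-probe protocol (frozen encoder) or joint
# fine-tuning, plus a fully supervised from-scratch baseline with the same
# architecture, loss and augmentations.

#' ProbeConfig: downstream training protocol
#'
#' @slot mode "linear_frozen" (train only the head on frozen features) or
#'   "finetune" (update encoder and head jointly; encoder learning rate one
#'   order of magnitude below the head's).
#' @slot labelFraction fraction of the supplied labeled patches actually
#'   used (the low-annotation budget).
#' @slot epochs training epochs (20 for fine-tuning in the reference
#'   protocol).
#' @slot folds cross-validation repeats.
#' @slot seed integer seed.
#' @slot lr head learning rate.
#' @slot batchSize minibatch size.
#' @slot threshold decision threshold on the sigmoid score.
#' @slot classWeighting logical, inverse-frequency loss weighting to counter
#'   the Surface-heavy class imbalance.
#' @export
setClass("ProbeConfig", representation(
  mode = "character", labelFraction = "numeric", epochs = "integer",
  folds = "integer", seed = "integer", lr = "numeric", batchSize = "integer",
  threshold = "numeric", classWeighting = "logical"
))

setValidity("ProbeConfig", function(object) {
  if (!object@mode %in% c("linear_frozen", "finetune"))
    return("mode must be 'linear_frozen' or 'finetune'")
  if (object@labelFraction <= 0 || object@labelFraction > 1)
    return("labelFraction must lie in (0, 1]")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})

#' @rdname ProbeConfig-class
#' @param mode,labelFraction,epochs,folds,seed,lr,batchSize,threshold see
#'   slots.
#' @param classWeighting see slots.
#' @return A validated `ProbeConfig`.
#' @export
#' @examples ProbeConfig(mode = "finetune")
ProbeConfig <- function(mode = "linear_frozen", labelFraction = 1,
                        epochs = 20L, folds = 10L, seed = 1L, lr = 0.1,
                        batchSize = 64L, threshold = 0.5,
                        classWeighting = TRUE) {
  new("ProbeConfig", mode = mode, labelFraction = labelFraction,
      epochs = as.integer(epochs), folds = as.integer(folds),
      seed = as.integer(seed), lr = lr, batchSize = as.integer(batchSize),
      threshold = threshold, classWeighting = isTRUE(classWeighting))
}

# weighted binary cross-entropy on logits; returns loss and dlogits
.bceGrad <- function(logits, y, w) {
  p <- 1 / (1 + exp(-logits))
  loss <- -mean(w * (y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12))))
  list(loss = loss, dlogits = w * (p - y) / length(y))
}

.classWeights <- function(y, on) {
  if (!on) return(rep(1, length(y)))
  npos <- sum(y); nneg <- length(y) - npos
  w <- ifelse(y > 0, length(y) / (2 * npos), length(y) / (2 * nneg))
  w
}

#' Train one binary classification head
#'
#' Binary-relevance component for `targetClass`. Under `linear_frozen` only a
#' logistic head is trained on frozen encoder features (the encoder
#' parameters are bit-identical before and after); under `finetune` the
#' encoder is updated jointly at a tenth of the head learning rate for
#' exactly `cfg@epochs` epochs, with the stochastic training augmentations.
#'
#' @param encoder an [EncoderState-class].
#' @param ps labeled [PatchSet-class] (the annotated pool; `labelFraction`
#'   of it is used).
#' @param targetClass one of [semClasses()].
#' @param cfg a [ProbeConfig()].
#' @return A classifier model list: `head`, `encoder`, `targetClass`,
#'   `threshold`, `outputSize`, class "semBinaryModel".
#' @export
trainBinaryHead <- function(encoder, ps, targetClass, cfg = ProbeConfig()) {
  validObject(cfg)
  stopifnot(targetClass %in% .semClasses)
  if (nrow(ps@labels) != nPatches(ps))
    .stopf("patch set has no derived labels; call deriveLabels() first")
  n <- nPatches(ps)
  nUse <- max(1L, round(n * cfg@labelFraction))
  outputSize <- encoder@arch$outputSize
  withSeed(deriveSeed(cfg@seed, paste0("head-", targetClass)), {
    use <- if (nUse < n) sample.int(n, nUse) else seq_len(n)
    y <- as.numeric(ps@labels[use, targetClass])
    if (length(unique(y)) < 2L)
      .stopf("labeled set contains a single class for '%s'; need positives and negatives",
             targetClass)
    w <- .classWeights(y, cfg@classWeighting)
    C <- encoder@arch$channels[length(encoder@arch$channels)]
    head <- .initLinear(C, 1L)
    params <- encoder@params$conv
    norm <- NULL
    if (cfg@mode == "linear_frozen") {
      feats <- encodeFeatures(params, ps@pixels, use, outputSize)
      # standardize frozen features: the probe solves a well-conditioned
      # logistic problem regardless of the encoder's activation scales
      norm <- list(mu = colMeans(feats),
                   sd = pmax(apply(feats, 2, sd), 1e-6))
      fs <- sweep(sweep(feats, 2, norm$mu), 2, norm$sd, "/")
      velH <- paramZero(head)
      trace <- numeric(cfg@epochs)
      for (ep in seq_len(cfg@epochs)) {
        ord <- sample.int(length(use))
        epLoss <- c()
        for (start in seq(1L, length(ord), by = cfg@batchSize)) {
          sel <- ord[start:min(start + cfg@batchSize - 1L, length(ord))]
          logits <- as.numeric(fs[sel, , drop = FALSE] %*% head$W + head$b)
          g <- .bceGrad(logits, y[sel], w[sel])
          epLoss <- c(epLoss, g$loss)
          gh <- list(W = crossprod(fs[sel, , drop = FALSE],
                                   matrix(g$dlogits)), b = sum(g$dlogits))
          st <- sgdStep(head, gh, velH, cfg@lr, 0.9)
          head <- st$params; velH <- st$vel
        }
        trace[ep] <- mean(epLoss)
      }
      enc <- encoder
    } else {
      policy <- AugmentPolicy(outputSize = outputSize)
      velH <- paramZero(head); velC <- paramZero(params)
      trace <- numeric(cfg@epochs)
      rmu <- NULL; rvar <- NULL   # running feature statistics for inference
      for (ep in seq_len(cfg@epochs)) {
        ord <- sample.int(length(use))
        epLoss <- c()
        for (start in seq(1L, length(ord), by = cfg@batchSize)) {
          sel <- ord[start:min(start + cfg@batchSize - 1L, length(ord))]
          if (length(sel) < 2L) next
          views <- lapply(use[sel], function(i)
            .augmentOne(ps@pixels[, , i], policy) / 255)
          fwd <- encoderForward(params, stackBatch(views))
          bn <- bnForward(fwd$features)
          mu <- colMeans(fwd$features); va <- bn$sd^2
          if (is.null(rmu)) { rmu <- mu; rvar <- va }
          else { rmu <- 0.9 * rmu + 0.1 * mu; rvar <- 0.9 * rvar + 0.1 * va }
          logits <- as.numeric(bn$zn %*% head$W + head$b)
          g <- .bceGrad(logits, y[sel], w[sel])
          epLoss <- c(epLoss, g$loss)
          gh <- list(W = crossprod(bn$zn, matrix(g$dlogits)),
                     b = sum(g$dlogits))
          dzn <- matrix(g$dlogits) %*% t(head$W)
          dfeat <- bnBackward(bn, dzn)
          gc <- encoderBackward(params, fwd, dfeat)
          stH <- sgdStep(head, gh, velH, cfg@lr, 0.9)
          head <- stH$params; velH <- stH$vel
          stC <- sgdStep(params, gc, velC, cfg@lr / 10, 0.9)
          params <- stC$params; velC <- stC$vel
        }
        trace[ep] <- mean(epLoss)
      }
      norm <- list(mu = rmu, sd = sqrt(rvar))
      enc <- encoder
      enc@params$conv <- params
    }
    structure(list(head = head, encoder = enc, targetClass = targetClass,
                   threshold = cfg@threshold, outputSize = outputSize,
                   nUsed = length(use), lossTrace = trace, norm = norm),
              class = "semBinaryModel")
  })
}

#' Train the three binary-relevance heads
#'
#' @param encoder an [EncoderState-class].
#' @param ps labeled [PatchSet-class].
#' @param cfg a [ProbeConfig()].
#' @return Named list of three "semBinaryModel" classifiers.
#' @export
trainMultiLabel <- function(encoder, ps, cfg = ProbeConfig()) {
  models <- lapply(.semClasses, function(cl)
    trainBinaryHead(encoder, ps, cl, cfg))
  names(models) <- .semClasses
  models
}

#' Fully supervised baseline classifiers
#'
#' The comparator for the self-supervised pipelines: the same encoder
#' architecture under the *same* downstream protocol (same augmentations,
#' weighted cross-entropy, same epochs and learning rates), but starting
#' from a fresh supervised-style (He) initialization instead of pretrained
#' representations -- so the only difference between baseline and SSL
#' pipeline is the representation the protocol starts from. No externally
#' pretrained backbone is shipped or assumed. Deterministic given
#' `cfg@seed`.
#'
#' @param ps labeled [PatchSet-class].
#' @param cfg a [ProbeConfig()]; `mode = "finetune"` mirrors the
#'   fine-tuning comparison, `mode = "linear_frozen"` the linear-evaluation
#'   comparison (head on frozen randomly initialized features).
#' @param config a [pretrainConfig()] describing the architecture.
#' @return Named list of three "semBinaryModel" classifiers.
#' @export
trainSupervisedBaseline <- function(ps, cfg = ProbeConfig(mode = "finetune"),
                                    config = pretrainConfig(seed = cfg@seed)) {
  models <- lapply(.semClasses, function(cl) {
    enc <- withSeed(deriveSeed(cfg@seed, paste0("sup-", cl)), {
      conv <- initEncoderParams(config$channels)
      new("EncoderState", variant = "noncontrastive",
          params = list(conv = conv, proj = list()), momentumParams = list(),
          queue = matrix(0, 1, 0), queueCapacity = 0L,
          hyper = list(), arch = list(channels = config$channels,
                                      projDim = config$projDim,
                                      outputSize = config$outputSize),
          lossTrace = numeric(0), config = config)
    })
    trainBinaryHead(enc, ps, cl, cfg)
  })
  names(models) <- .semClasses
  models
}

#' Oracle model backed by ground-truth annotations
#'
#' Predicts labels directly from the pixel-level annotation via
#' [deriveLabels()]; used to audit heatmap and bookkeeping paths
#' independently of any trained network.
#'
#' @param minFraction presence threshold passed to [deriveLabels()].
#' @return An object of class "semOracleModel".
#' @export
oracleModel <- function(minFraction = 0.01) {
  structure(list(minFraction = minFraction), class = "semOracleModel")
}

#' Multi-label prediction by binary relevance
#'
#' Applies the three independent binary classifiers and merges their
#' decisions: no mutual exclusion is imposed, so a patch may receive zero,
#' one, two or all three labels.
#'
#' @param models named list with one "semBinaryModel" per class (or a
#'   "semOracleModel").
#' @param ps a [PatchSet-class].
#' @return List with `scores` (n x 3) and `decisions` (n x 3 logical).
#' @export
predictMultilabel <- function(models, ps) {
  n <- nPatches(ps)
  if (inherits(models, "semOracleModel")) {
    lab <- patchLabels(deriveLabels(ps, models$minFraction))
    return(list(scores = lab * 1, decisions = lab))
  }
  missing <- setdiff(.semClasses, names(models))
  if (length(missing))
    .stopf("missing classifier head(s): %s", paste(missing, collapse = ", "))
  scores <- matrix(NA_real_, n, 3, dimnames = list(NULL, .semClasses))
  decisions <- matrix(NA, n, 3, dimnames = list(NULL, .semClasses))
  for (cl in .semClasses) {
    m <- models[[cl]]
    feats <- encodeFeatures(m$encoder@params$conv, ps@pixels, seq_len(n),
                            m$outputSize)
    if (!is.null(m$norm))
      feats <- sweep(sweep(feats, 2, m$norm$mu), 2, m$norm$sd, "/")
    s <- 1 / (1 + exp(-(as.numeric(feats %*% m$head$W + m$head$b))))
    scores[, cl] <- s
    decisions[, cl] <- s >= m$threshold
  }
  list(scores = scores, decisions = decisions)
}
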