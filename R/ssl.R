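# Self-supervised objectives over patch views: the contrastive InfoNCE loss
# with a momentum encoder and a FIFO queue of negative keys, and the
# non-contrastive cross-correlation (invariance + redundancy-reduction)
# loss over twin batch-normalized embeddings.

#' AugmentPolicy: stochastic view generation for self-supervised training
#'
#' Training views are random area crops (rescaled to `outputSize`) followed by
#' a horizontal flip with probability `hflipProb`; evaluation views are
#' deterministic center crops.
#'
#' @slot cropScale numeric length-2, crop area as a fraction of the patch
#'   area (low, high).
#' @slot hflipProb numeric in `[0, 1]`.
#' @slot outputSize integer, side of the emitted views (must not exceed the
#'   patch kernel).
#' @export
setClass("AugmentPolicy", representation(
  cropScale = "numeric", hflipProb = "numeric", outputSize = "integer"
))

setValidity("AugmentPolicy", function(object) {
  if (length(object@cropScale) != 2L || object@cropScale[1] > object@cropScale[2] ||
      object@cropScale[1] <= 0 || object@cropScale[2] > 1)
    return("cropScale must be an interval within (0, 1]")
  if (object@hflipProb < 0 || object@hflipProb > 1)
    return("hflipProb must lie in [0, 1]")
  if (object@outputSize < 4L) return("outputSize too small")
  TRUE
})

#' @rdname AugmentPolicy-class
#' @param cropScale,hflipProb,outputSize see slots.
#' @return A validated `AugmentPolicy`.
#' @export
#' @examples AugmentPolicy(outputSize = 32L)
AugmentPolicy <- function(cropScale = c(0.6, 1.0), hflipProb = 0.5,
                          outputSize = 32L) {
  new("AugmentPolicy", cropScale = as.numeric(cropScale),
      hflipProb = as.numeric(hflipProb), outputSize = as.integer(outputSize))
}

#' Deterministic center crop
#'
#' @param patch numeric matrix.
#' @param size crop side in pixels.
#' @return `size x size` matrix.
#' @export
centerCrop <- function(patch, size) {
  if (size > min(dim(patch))) .stopf("center crop larger than patch")
  r0 <- floor((nrow(patch) - size) / 2)
  c0 <- floor((ncol(patch) - size) / 2)
  patch[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), drop = FALSE]
}

# one stochastic view under the current RNG stream
.augmentOne <- function(patch, policy) {
  k <- nrow(patch)
  s <- runif(1, policy@cropScale[1], policy@cropScale[2])
  side <- max(4L, min(k, round(k * sqrt(s))))
  r0 <- if (side < k) sample.int(k - side + 1L, 1L) - 1L else 0L
  c0 <- if (side < k) sample.int(k - side + 1L, 1L) - 1L else 0L
  v <- patch[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
  v <- resizeBilinear(v, policy@outputSize, policy@outputSize)
  if (runif(1) < policy@hflipProb) v <- v[, rev(seq_len(ncol(v))), drop = FALSE]
  v
}

#' Two independently augmented views of one patch
#'
#' Samples the two stochastic views that form a positive pair for
#' self-supervised training. Deterministic given `seed`.
#'
#' @param patch numeric matrix (side >= `policy@outputSize`).
#' @param policy an [AugmentPolicy()].
#' @param seed integer seed.
#' @return List of two `outputSize x outputSize` matrices.
#' @export
augmentPair <- function(patch, policy = AugmentPolicy(), seed = 1L) {
  validObject(policy)
  if (min(dim(patch)) < policy@outputSize)
    .stopf("patch (%d px) smaller than requested view size (%d px)",
           min(dim(patch)), policy@outputSize)
  withSeed(seed, list(view1 = .augmentOne(patch, policy),
                      view2 = .augmentOne(patch, policy)))
}

# ---- negative-key queue -------------------------------------------------

#' NegativeQueue: FIFO buffer of negative keys
#'
#' Holds up to `capacity` L2-normalized key embeddings (columns), oldest
#' first; enqueueing beyond capacity evicts the oldest keys.
#'
#' @slot keys numeric matrix D x size.
#' @slot capacity integer.
#' @export
setClass("NegativeQueue", representation(keys = "matrix", capacity = "integer"))

setValidity("NegativeQueue", function(object) {
  if (ncol(object@keys) > object@capacity) return("queue size exceeds capacity")
  TRUE
})

#' @rdname NegativeQueue-class
#' @param dim embedding dimension D.
#' @param capacity FIFO capacity.
#' @return An empty `NegativeQueue`.
#' @export
#' @examples NegativeQueue(dim = 8, capacity = 16)
NegativeQueue <- function(dim, capacity) {
  new("NegativeQueue", keys = matrix(0, dim, 0), capacity = as.integer(capacity))
}

#' @rdname NegativeQueue-class
#' @param object a `NegativeQueue`.
#' @export
setGeneric("queueSize", function(object) standardGeneric("queueSize"))

#' @rdname NegativeQueue-class
#' @export
setMethod("queueSize", "NegativeQueue", function(object) ncol(object@keys))

setMethod("show", "NegativeQueue", function(object) {
  cat(sprintf("NegativeQueue: %d / %d keys of dim %d\n", queueSize(object),
              object@capacity, nrow(object@keys)))
})

#' Enqueue keys into a FIFO negative queue
#'
#' Appends key columns in order; if the result exceeds capacity, the oldest
#' keys are evicted.
#'
#' @param queue a [NegativeQueue()].
#' @param keys numeric matrix D x b (a vector is taken as one key).
#' @return The updated [NegativeQueue()].
#' @export
enqueueKeys <- function(queue, keys) {
  if (is.null(dim(keys))) keys <- matrix(keys, ncol = 1)
  if (nrow(keys) != nrow(queue@keys))
    .stopf("key dimension (%d) does not match queue dimension (%d)",
           nrow(keys), nrow(queue@keys))
  all <- cbind(queue@keys, keys)
  if (ncol(all) > queue@capacity)
    all <- all[, (ncol(all) - queue@capacity + 1):ncol(all), drop = FALSE]
  new("NegativeQueue", keys = all, capacity = queue@capacity)
}

# ---- losses -------------------------------------------------------------

#' Contrastive InfoNCE loss with queued negatives
#'
#' For a query `q`, its positive key `k+` and the queued negative keys, the
#' loss is `-log( exp(q.k+ / tau) / (exp(q.k+ / tau) + sum_k- exp(q.k- / tau)) )`,
#' i.e. softmax cross-entropy over similarities with the positive as the true
#' class, scaled by the temperature `tau`. Inputs are expected L2-normalized.
#' For batched inputs the mean over the batch is returned.
#'
#' @param q query embeddings, vector or B x D matrix.
#' @param kPos positive keys, same shape as `q`.
#' @param queue a [NegativeQueue()] (non-empty) or a D x K key matrix.
#' @param tau temperature (> 0).
#' @return Scalar loss (strictly positive).
#' @export
#' @examples
#' q <- l2NormalizeRows(rnorm(8)); k <- l2NormalizeRows(rnorm(8))
#' neg <- l2NormalizeRows(matrix(rnorm(40), 5, 8))
#' infoNCE(q, k, t(neg), tau = 0.2)
infoNCE <- function(q, kPos, queue, tau = 0.2) {
  if (tau <= 0) .stopf("temperature tau must be > 0 (got %g)", tau)
  keys <- if (is(queue, "NegativeQueue")) queue@keys else queue
  if (is.null(dim(keys))) keys <- matrix(keys, ncol = 1)
  if (ncol(keys) == 0) .stopf("negative queue is empty")
  if (is.null(dim(q))) q <- matrix(q, 1)
  if (is.null(dim(kPos))) kPos <- matrix(kPos, 1)
  if (ncol(q) != nrow(keys) || !all(dim(q) == dim(kPos)))
    .stopf("embedding dimensions do not agree")
  logits <- cbind(rowSums(q * kPos), q %*% keys) / tau
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[, 1])
}

# loss + gradient wrt q (keys are constants: momentum branch is not
# backpropagated through)
.infoNCEGrad <- function(q, kPos, keys, tau) {
  B <- nrow(q)
  logits <- cbind(rowSums(q * kPos), q %*% keys) / tau
  mx <- apply(logits, 1, max)
  p <- exp(logits - mx)
  p <- p / rowSums(p)
  loss <- mean(-log(p[, 1]))
  dq <- ((p[, 1] - 1) * kPos + p[, -1, drop = FALSE] %*% t(keys)) / (tau * B)
  list(loss = loss, dq = dq)
}

#' Cross-correlation matrix of twin embedding batches
#'
#' `C[i, j] = sum_b zA[b, i] * zB[b, j] / (||zA[, i]|| * ||zB[, j]||)`: the
#' cosine similarity between embedding dimensions of the two branches over
#' the batch. With batch-normalized inputs all entries lie in `[-1, 1]`.
#'
#' @param zA,zB numeric matrices B x D (batch-normalized).
#' @return D x D matrix.
#' @export
crossCorrelation <- function(zA, zB) {
  if (!all(dim(zA) == dim(zB))) .stopf("zA and zB must have the same shape")
  na <- sqrt(colSums(zA^2)); nb <- sqrt(colSums(zB^2))
  if (any(na < 1e-12) || any(nb < 1e-12))
    .stopf("zero-variance embedding dimension: cross-correlation undefined")
  crossprod(zA, zB) / outer(na, nb)
}

#' Redundancy-reduction (twin) loss on a cross-correlation matrix
#'
#' `sum_i (1 - C[i,i])^2 + lambda * sum_{i != j} C[i,j]^2`: the invariance
#' term drives the diagonal to 1 (robust, aligned embeddings) and the
#' off-diagonal term decorrelates embedding dimensions.
#'
#' @param C square cross-correlation matrix.
#' @param lambda off-diagonal weight (>= 0).
#' @return Scalar loss (>= 0).
#' @export
#' @examples barlowTwinsLoss(diag(4))  # 0
barlowTwinsLoss <- function(C, lambda = 5e-3) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) .stopf("C must be square")
  if (lambda < 0) .stopf("lambda must be >= 0")
  off <- C; diag(off) <- 0
  sum((1 - diag(C))^2) + lambda * sum(off^2)
}

# loss + gradients wrt zA, zB through the column-cosine normalization
.barlowGrad <- function(zA, zB, lambda) {
  na <- pmax(sqrt(colSums(zA^2)), 1e-12)
  nb <- pmax(sqrt(colSums(zB^2)), 1e-12)
  An <- sweep(zA, 2, na, "/")
  Bn <- sweep(zB, 2, nb, "/")
  C <- crossprod(An, Bn)
  off <- C; diag(off) <- 0
  loss <- sum((1 - diag(C))^2) + lambda * sum(off^2)
  G <- 2 * lambda * off
  diag(G) <- -2 * (1 - diag(C))
  dAn <- Bn %*% t(G)                    # dL/dAn[, i] = sum_j G[i, j] Bn[, j]
  dBn <- An %*% G
  dzA <- sweep(dAn - sweep(An, 2, colSums(dAn * An), "*"), 2, na, "/")
  dzB <- sweep(dBn - sweep(Bn, 2, colSums(dBn * Bn), "*"), 2, nb, "/")
  list(loss = loss, dzA = dzA, dzB = dzB, C = C)
}

#' @describeIn momentumUpdate EMA update of the momentum branch:
#'   `momentum <- m * momentum + (1 - m) * query`, elementwise over all
#'   parameters; the query branch is untouched.
#' @export
setMethod("momentumUpdate", "EncoderState", function(state) {
  if (state@variant != "contrastive")
    .stopf("momentumUpdate applies to the contrastive variant")
  state@momentumParams <- emaUpdate(state@momentumParams, state@params,
                                    state@hyper$m)
  state
})

#' Momentum (EMA) update of the key encoder
#'
#' @param state an [EncoderState-class] (contrastive variant).
#' @return The updated state.
#' @name momentumUpdate
NULL

# ---- pretraining --------------------------------------------------------

#' Configuration for self-supervised pretraining
#'
#' Desk-scale defaults: a 3-block convolutional encoder (8/16/32 channels)
#' over 32 px views, projector output D = 64, SGD (momentum 0.9) at a
#' constant learning rate. `tau` and `lambda` follow the values published
#' with the respective objectives; the EMA coefficient and queue capacity are
#' desk-scale choices sized to short schedules (see the vignette).
#'
#' @param outputSize view side in pixels.
#' @param channels conv channels per block.
#' @param projDim projector output dimension D.
#' @param projHidden hidden width of the projector.
#' @param batchSize,epochs training schedule.
#' @param lr,sgdMomentum optimizer settings.
#' @param tau InfoNCE temperature.
#' @param m EMA coefficient of the momentum encoder.
#' @param queueCapacity FIFO capacity of the negative queue.
#' @param lambda off-diagonal weight of the twin loss.
#' @param cropScale,hflipProb augmentation policy.
#' @param seed integer seed.
#' @return Named list of settings.
#' @export
pretrainConfig <- function(outputSize = 32L, channels = c(8L, 16L, 32L),
                           projDim = 64L, projHidden = 64L, batchSize = 64L,
                           epochs = 10L, lr = 0.05, sgdMomentum = 0.9,
                           tau = 0.2, m = 0.9, queueCapacity = 512L,
                           lambda = 5e-3, cropScale = c(0.6, 1.0),
                           hflipProb = 0.5, seed = 1L) {
  list(outputSize = as.integer(outputSize), channels = as.integer(channels),
       projDim = as.integer(projDim), projHidden = as.integer(projHidden),
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       lr = lr, sgdMomentum = sgdMomentum, tau = tau, m = m,
       queueCapacity = as.integer(queueCapacity), lambda = lambda,
       cropScale = cropScale, hflipProb = hflipProb, seed = as.integer(seed))
}

# fresh EncoderState under the config (seeded); momentum branch and queue
# only for the contrastive variant. Projector: 2-layer MLP head
# (hidden-ReLU-out) for the contrastive variant, three linear layers for the
# non-contrastive one.
initEncoderState <- function(variant = c("contrastive", "noncontrastive"),
                             config = pretrainConfig()) {
  variant <- match.arg(variant)
  withSeed(deriveSeed(config$seed, paste0("init-", variant)), {
    conv <- initEncoderParams(config$channels)
    nin <- config$channels[length(config$channels)]
    widths <- if (variant == "contrastive")
      c(config$projHidden, config$projDim)
    else c(config$projHidden, config$projHidden, config$projDim)
    proj <- initProjectorParams(nin, widths)
    params <- list(conv = conv, proj = proj)
    mom <- if (variant == "contrastive") params else list()
    queue <- matrix(0, config$projDim, 0)
    new("EncoderState", variant = variant, params = params,
        momentumParams = mom, queue = queue,
        queueCapacity = config$queueCapacity,
        hyper = list(tau = config$tau, m = config$m, lambda = config$lambda,
                     lr = config$lr, sgdMomentum = config$sgdMomentum),
        arch = list(channels = config$channels, projDim = config$projDim,
                    outputSize = config$outputSize),
        lossTrace = numeric(0), config = config)
  })
}

#' Self-supervised pretraining on unlabeled patches
#'
#' Learns representations from the patch set (its "repr" split when one is
#' assigned, otherwise all patches) with either the contrastive
#' momentum-queue objective or the non-contrastive cross-correlation
#' objective. Two stochastic views per patch per step; SGD with momentum;
#' per-epoch mean loss recorded in the returned state. With `epochs = 0` the
#' initialized state is returned untouched.
#'
#' @param ps a [PatchSet-class].
#' @param variant "contrastive" or "noncontrastive".
#' @param config a [pretrainConfig()].
#' @return A trained [EncoderState-class] with `lossTrace`.
#' @export
pretrainEncoder <- function(ps, variant = c("contrastive", "noncontrastive"),
                            config = pretrainConfig()) {
  variant <- match.arg(variant)
  idx <- if (any(ps@split == "repr")) which(ps@split == "repr") else seq_len(nPatches(ps))
  if (length(idx) == 0) .stopf("representation set is empty")
  if (config$batchSize > length(idx))
    .stopf("batch size (%d) exceeds the representation set size (%d)",
           config$batchSize, length(idx))
  state <- initEncoderState(variant, config)
  if (config$epochs == 0L) return(state)
  policy <- AugmentPolicy(cropScale = config$cropScale,
                          hflipProb = config$hflipProb,
                          outputSize = config$outputSize)
  px <- ps@pixels
  vel <- paramZero(state@params)
  trace <- numeric(config$epochs)
  withSeed(deriveSeed(config$seed, paste0("train-", variant)), {
    queue <- NegativeQueue(config$projDim, config$queueCapacity)
    if (variant == "contrastive") {
      # fill the queue with momentum-encoder keys before the first update so
      # every step (and every per-epoch mean loss) faces the same number of
      # negatives
      while (queueSize(queue) < config$queueCapacity) {
        sel <- idx[sample.int(length(idx), config$batchSize)]
        vs <- lapply(sel, function(i) .augmentOne(px[, , i], policy) / 255)
        encK <- encoderForward(state@momentumParams$conv, stackBatch(vs),
                               keepCache = FALSE)
        prK <- projForward(state@momentumParams$proj, encK$features)
        queue <- enqueueKeys(queue, t(l2NormalizeRows(prK$z)))
      }
    }
    for (ep in seq_len(config$epochs)) {
      ord <- idx[sample.int(length(idx))]
      nb <- floor(length(ord) / config$batchSize)
      losses <- numeric(nb)
      for (bi in seq_len(nb)) {
        sel <- ord[(bi - 1) * config$batchSize + seq_len(config$batchSize)]
        v1 <- vector("list", length(sel)); v2 <- v1
        for (t in seq_along(sel)) {
          v1[[t]] <- .augmentOne(px[, , sel[t]], policy) / 255
          v2[[t]] <- .augmentOne(px[, , sel[t]], policy) / 255
        }
        x1 <- stackBatch(v1); x2 <- stackBatch(v2)
        if (variant == "contrastive") {
          encQ <- encoderForward(state@params$conv, x1)
          prQ <- projForward(state@params$proj, encQ$features)
          q <- l2NormalizeRows(prQ$z)
          encK <- encoderForward(state@momentumParams$conv, x2, keepCache = FALSE)
          prK <- projForward(state@momentumParams$proj, encK$features)
          k <- l2NormalizeRows(prK$z)
          gr <- .infoNCEGrad(q, k, queue@keys, config$tau)
          losses[bi] <- gr$loss
          dz <- l2Backward(prQ$z, gr$dq)
          pb <- projBackward(state@params$proj, prQ, dz)
          cg <- encoderBackward(state@params$conv, encQ, pb$dx)
          st <- sgdStep(state@params, list(conv = cg, proj = pb$grads), vel,
                        config$lr, config$sgdMomentum)
          state@params <- st$params; vel <- st$vel
          state@momentumParams <- emaUpdate(state@momentumParams,
                                            state@params, config$m)
          queue <- enqueueKeys(queue, t(k))
        } else {
          encA <- encoderForward(state@params$conv, x1)
          prA <- projForward(state@params$proj, encA$features, bnHidden = TRUE)
          bnA <- bnForward(prA$z)
          encB <- encoderForward(state@params$conv, x2)
          prB <- projForward(state@params$proj, encB$features, bnHidden = TRUE)
          bnB <- bnForward(prB$z)
          gr <- .barlowGrad(bnA$zn, bnB$zn, config$lambda)
          losses[bi] <- gr$loss
          dzA <- bnBackward(bnA, gr$dzA)
          dzB <- bnBackward(bnB, gr$dzB)
          pbA <- projBackward(state@params$proj, prA, dzA)
          pbB <- projBackward(state@params$proj, prB, dzB)
          cgA <- encoderBackward(state@params$conv, encA, pbA$dx)
          cgB <- encoderBackward(state@params$conv, encB, pbB$dx)
          grads <- list(conv = paramMap2(cgA, cgB, `+`),
                        proj = paramMap2(pbA$grads, pbB$grads, `+`))
          st <- sgdStep(state@params, grads, vel, config$lr, config$sgdMomentum)
          state@params <- st$params; vel <- st$vel
        }
      }
      trace[ep] <- mean(losses)
    }
    if (variant == "contrastive") state@queue <- queue@keys
  })
  state@lossTrace <- trace
  validObject(state)
  state
}
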