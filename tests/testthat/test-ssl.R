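ns <- asNamespace("SEMBiofilm")

test_that("InfoNCE identities: uniform softmax and shift invariance", {
  # q orthogonal to the positive and to every negative: all similarities 0,
  # so the softmax is uniform over K + 1 keys and the loss is log(K + 1)
  for (K in c(1, 5, 32)) {
    D <- K + 2
    q <- diag(D)[1, ]
    kPos <- diag(D)[2, ]
    keys <- t(diag(D)[3:(K + 2), , drop = FALSE])
    expect_equal(infoNCE(q, kPos, keys, tau = 0.2), log(K + 1),
                 tolerance = 1e-12)
  }
  # appending a coordinate (a, c/a) to query and keys shifts every
  # similarity by the constant c and must leave the loss unchanged
  set.seed(3)
  q <- rnorm(6); kPos <- rnorm(6); keys <- matrix(rnorm(6 * 7), 6, 7)
  base <- infoNCE(q, kPos, keys, tau = 0.3)
  for (c0 in c(-2, 0.5, 10)) {
    q2 <- c(q, 1); kPos2 <- c(kPos, c0); keys2 <- rbind(keys, c0)
    expect_equal(infoNCE(q2, kPos2, keys2, tau = 0.3), base,
                 tolerance = 1e-10)
  }
})

test_that("InfoNCE equals softmax cross-entropy with the positive as class 0", {
  set.seed(11)
  for (rep in 1:100) {
    D <- sample(3:16, 1); K <- sample(1:20, 1)
    q <- ns$l2NormalizeRows(rnorm(D))
    kPos <- ns$l2NormalizeRows(rnorm(D))
    keys <- t(ns$l2NormalizeRows(matrix(rnorm(K * D), K, D)))
    tau <- runif(1, 0.05, 1)
    sims <- c(sum(q * kPos), as.numeric(q %*% keys)) / tau
    oracle <- -log(exp(sims[1]) / sum(exp(sims)))
    expect_equal(infoNCE(q, kPos, keys, tau), oracle, tolerance = 1e-6)
  }
  expect_error(infoNCE(rnorm(4), rnorm(4), matrix(rnorm(4), 4, 1), tau = 0),
               "tau")
  expect_error(infoNCE(rnorm(4), rnorm(4), matrix(0, 4, 0), tau = 0.2),
               "empty")
})

test_that("momentum update follows the EMA rule and leaves the query branch", {
  st <- ns$initEncoderState("contrastive", pretrainConfig(seed = 4))
  st@hyper$m <- 1
  expect_identical(momentumUpdate(st)@momentumParams, st@momentumParams)
  st@hyper$m <- 0
  expect_identical(momentumUpdate(st)@momentumParams, st@params)
  # elementwise arithmetic at m = 0.5
  mp <- list(a = matrix(2, 2, 2)); qp <- list(a = matrix(4, 2, 2))
  expect_equal(ns$emaUpdate(mp, qp, 0.5)$a, matrix(3, 2, 2))
  expect_error(ns$emaUpdate(list(a = matrix(0, 2, 2)),
                            list(a = matrix(0, 3, 3)), 0.5), "congruent")
  stq <- st@params
  invisible(momentumUpdate(st))
  expect_identical(st@params, stq)
})

test_that("the negative queue is FIFO and matches a list simulation", {
  q <- NegativeQueue(dim = 3, capacity = 4)
  q <- enqueueKeys(q, matrix(1:9, 3, 3))       # keys 1..3
  expect_identical(queueSize(q), 3L)
  q2 <- enqueueKeys(q, matrix(10:15, 3, 2))    # 3 + 2 -> evict oldest 1
  expect_identical(queueSize(q2), 4L)
  expect_equal(q2@keys[, 1], c(4, 5, 6))

  # reference list-slice simulation over a random enqueue sequence
  set.seed(9)
  qq <- NegativeQueue(dim = 2, capacity = 7)
  refList <- list()
  for (step in 1:20) {
    b <- sample(1:4, 1)
    keys <- matrix(rnorm(2 * b), 2, b)
    qq <- enqueueKeys(qq, keys)
    refList <- c(refList, lapply(seq_len(b), function(j) keys[, j]))
    if (length(refList) > 7) refList <- refList[(length(refList) - 6):length(refList)]
    expect_equal(qq@keys, do.call(cbind, refList))
  }
  expect_error(enqueueKeys(qq, matrix(0, 5, 1)), "dimension")
})

test_that("cross-correlation matches its definition and symmetry properties", {
  set.seed(21)
  zA <- ns$batchNormalize(matrix(rnorm(8 * 4), 8, 4))
  zB <- ns$batchNormalize(matrix(rnorm(8 * 4), 8, 4))
  C <- crossCorrelation(zA, zB)
  # brute-force double loop over the definition
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    ref[i, j] <- sum(zA[, i] * zB[, j]) /
      (sqrt(sum(zA[, i]^2)) * sqrt(sum(zB[, j]^2)))
  expect_equal(C, ref, tolerance = 1e-9)
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_equal(diag(crossCorrelation(zA, zA)), rep(1, 4), tolerance = 1e-12)
  expect_equal(diag(crossCorrelation(zA, -zA)), rep(-1, 4), tolerance = 1e-12)
  expect_equal(t(crossCorrelation(zA, zB)), crossCorrelation(zB, zA),
               tolerance = 1e-12)
  expect_error(crossCorrelation(zA, zB[1:4, ]), "shape")
  zZero <- zA; zZero[, 2] <- 0
  expect_error(crossCorrelation(zZero, zB), "zero-variance")
})

test_that("the twin loss evaluates its closed forms", {
  for (D in c(2, 8, 64)) {
    expect_equal(barlowTwinsLoss(diag(D)), 0)
    expect_equal(barlowTwinsLoss(matrix(0, D, D), lambda = 0.7), D)
  }
  set.seed(5)
  C <- matrix(runif(25, -1, 1), 5, 5)
  expect_equal(barlowTwinsLoss(C, lambda = 0), sum((1 - diag(C))^2))
  off <- C; diag(off) <- 0
  expect_equal(barlowTwinsLoss(C, lambda = 2),
               sum((1 - diag(C))^2) + 2 * sum(off^2))
  expect_error(barlowTwinsLoss(matrix(0, 2, 3)), "square")
})

test_that("the twin loss is invariant to joint sample permutation", {
  set.seed(6)
  zA <- ns$batchNormalize(matrix(rnorm(10 * 6), 10, 6))
  zB <- ns$batchNormalize(matrix(rnorm(10 * 6), 10, 6))
  base <- barlowTwinsLoss(crossCorrelation(zA, zB), 5e-3)
  for (rep in 1:5) {
    p <- sample(10)
    expect_equal(barlowTwinsLoss(crossCorrelation(zA[p, ], zB[p, ]), 5e-3),
                 base, tolerance = 1e-10)
  }
})

test_that("embedding normalizations satisfy their contracts", {
  set.seed(8)
  z <- matrix(rnorm(32 * 6, mean = 3, sd = 2), 32, 6)
  zn <- ns$batchNormalize(z)
  expect_true(all(abs(colMeans(zn)) < 1e-4))
  expect_true(all(abs(colMeans(zn^2) - 1) < 1e-4))
  l2 <- ns$l2NormalizeRows(z)
  expect_true(all(abs(sqrt(rowSums(l2^2)) - 1) < 1e-6))
})

test_that("augmented view pairs are deterministic and respect the policy", {
  patch <- matrix(runif(64 * 64) * 255, 64, 64)
  pol <- AugmentPolicy(outputSize = 32L)
  p1 <- augmentPair(patch, pol, seed = 7)
  p2 <- augmentPair(patch, pol, seed = 7)
  expect_identical(p1, p2)
  expect_identical(dim(p1$view1), c(32L, 32L))

  # degenerate policy: fixed full crop, no flip -> the two views coincide
  # and equal the whole patch rescaled
  degen <- AugmentPolicy(cropScale = c(1, 1), hflipProb = 0,
                         outputSize = 32L)
  d <- augmentPair(patch, degen, seed = 1)
  expect_identical(d$view1, d$view2)
  expect_equal(d$view1, ns$resizeBilinear(patch, 32, 32))
  same <- augmentPair(patch, AugmentPolicy(cropScale = c(1, 1), hflipProb = 0,
                                           outputSize = 64L), seed = 1)
  expect_equal(same$view1, patch)

  # certain flip with a full crop mirrors the columns
  flip <- augmentPair(patch, AugmentPolicy(cropScale = c(1, 1), hflipProb = 1,
                                           outputSize = 64L), seed = 2)
  expect_equal(flip$view1, patch[, 64:1])

  expect_error(augmentPair(matrix(0, 16, 16), pol, 1), "smaller")
})

test_that("pretraining honours the zero-epoch no-op and queue invariants", {
  ps <- tinyPatchSet()
  cfg <- pretrainConfig(epochs = 0L, batchSize = 16L, queueCapacity = 32L,
                        seed = 13)
  st0 <- pretrainEncoder(ps, "contrastive", cfg)
  init <- ns$initEncoderState("contrastive", cfg)
  expect_identical(st0@params, init@params)
  expect_length(st0@lossTrace, 0)
  expect_error(pretrainEncoder(ps, "contrastive",
                               pretrainConfig(batchSize = 10000L)),
               "batch size")
})

test_that("short pretraining reduces the loss and fills the queue", {
  ps <- tinyPatchSet(kernel = 32L, stride = 16L, nImages = 3)
  cfgB <- pretrainConfig(epochs = 6L, batchSize = 32L, lr = 0.1,
                         channels = c(6L, 12L), projDim = 16L,
                         projHidden = 16L, seed = 17)
  encB <- pretrainEncoder(ps, "noncontrastive", cfgB)
  expect_length(encB@lossTrace, 6)
  expect_lt(encB@lossTrace[6], encB@lossTrace[1])

  cfgC <- pretrainConfig(epochs = 2L, batchSize = 32L, lr = 0.1,
                         channels = c(6L, 12L), projDim = 16L,
                         projHidden = 16L, queueCapacity = 64L, seed = 17)
  encC <- pretrainEncoder(ps, "contrastive", cfgC)
  expect_identical(ncol(encC@queue), 64L)   # at capacity after warm-up
  expect_true(all(encC@lossTrace > 0))
})

test_that("twin pretraining improves embedding alignment on held-out patches", {
  ps <- tinyPatchSet(kernel = 32L, stride = 16L, nImages = 3)
  cfg <- pretrainConfig(epochs = 6L, batchSize = 32L, lr = 0.1,
                        channels = c(6L, 12L), projDim = 16L,
                        projHidden = 16L, seed = 23)
  held <- tinyPatchSet(kernel = 32L, stride = 32L, nImages = 1, seed = 99)
  alignment <- function(enc) {
    pol <- AugmentPolicy(outputSize = 32L)
    pairs <- lapply(seq_len(nPatches(held)), function(i)
      augmentPair(patchPixels(held)[, , i], pol, seed = i))
    zOf <- function(side) {
      x <- ns$stackBatch(lapply(pairs, function(p) p[[side]] / 255))
      f <- ns$encoderForward(enc@params$conv, x, keepCache = FALSE)$features
      ns$batchNormalize(ns$projForward(enc@params$proj, f, bnHidden = TRUE)$z)
    }
    mean(diag(crossCorrelation(zOf("view1"), zOf("view2"))))
  }
  a0 <- alignment(ns$initEncoderState("noncontrastive", cfg))
  a1 <- alignment(pretrainEncoder(ps, "noncontrastive", cfg))
  expect_gt(a1, a0)
})
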