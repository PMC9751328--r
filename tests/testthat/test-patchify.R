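test_that("sliding-window patch counts follow the closed form", {
  img <- flatImage(H = 128, W = 128)
  expect_identical(nPatches(extractPatches(img, 128, 64)), 1L)

  img2 <- flatImage(H = 256, W = 256)
  expect_identical(nPatches(extractPatches(img2, 128, 128)), 4L)

  expect_error(extractPatches(flatImage(H = 32, W = 32), 64, 8), "kernel")
})

test_that("patch count equals brute-force origin enumeration on random geometries", {
  set.seed(42)
  for (rep in 1:50) {
    H <- sample(20:120, 1); W <- sample(20:120, 1)
    k <- sample(4:min(H, W), 1); s <- sample(1:k, 1)
    ps <- extractPatches(flatImage(H = H, W = W), k, s)
    bruteForce <- 0L
    for (r in seq(0, H, by = s)) for (cc in seq(0, W, by = s))
      if (r + k <= H && cc + k <= W) bruteForce <- bruteForce + 1L
    expect_identical(nPatches(ps), bruteForce)
    org <- patchOrigins(ps)
    expect_true(all(org[, 1] %% s == 0 & org[, 2] %% s == 0))
    expect_true(all(org[, 1] + k <= H & org[, 2] + k <= W))
  }
})

test_that("patches carry the source pixels at their origins", {
  img <- tinyImage(seed = 3)
  ps <- extractPatches(img, 32, 16)
  org <- patchOrigins(ps)
  for (i in c(1L, nPatches(ps) %/% 2L, nPatches(ps))) {
    expect_identical(patchPixels(ps)[, , i],
                     imagePixels(img)[org[i, 1] + 1:32, org[i, 2] + 1:32])
    expect_identical(patchAnnotations(ps)[, , i],
                     imageAnnotation(img)[org[i, 1] + 1:32, org[i, 2] + 1:32])
  }
})

test_that("averaging overlapping patches reconstructs the source image", {
  img <- tinyImage(seed = 7)
  ps <- extractPatches(img, 32, 8)
  acc <- matrix(0, 160, 160); cnt <- matrix(0, 160, 160)
  org <- patchOrigins(ps)
  for (i in seq_len(nPatches(ps))) {
    rows <- org[i, 1] + 1:32; cols <- org[i, 2] + 1:32
    acc[rows, cols] <- acc[rows, cols] + patchPixels(ps)[, , i]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  covered <- cnt > 0
  expect_equal((acc / pmax(cnt, 1))[covered], imagePixels(img)[covered])
})

test_that("object masks partition each patch by class support", {
  ps <- tinyPatchSet()
  for (i in seq_len(min(nPatches(ps), 20L))) {
    p <- patchPixels(ps)[, , i]; a <- patchAnnotations(ps)[, , i]
    masks <- makeObjectMasks(p, a)
    # supports are pairwise disjoint and cover all nonzero source pixels
    nz <- lapply(masks, function(m) m != 0)
    expect_true(all((nz[[1]] + nz[[2]] + nz[[3]])[p > 0] == 1))
    for (k in 1:3)
      expect_true(all(a[nz[[k]]] == k))
    expect_equal(masks[[1]] + masks[[2]] + masks[[3]], p * (p > 0))
  }
  # a pure-Surface patch keeps its pixels only in the Surface mask
  p <- matrix(100, 8, 8); a <- matrix(3L, 8, 8)
  masks <- makeObjectMasks(p, a)
  expect_equal(masks$Surface, p)
  expect_true(all(masks$Byproduct == 0) && all(masks$Cell == 0))
  expect_error(makeObjectMasks(p, matrix(3L, 4, 4)), "misaligned")
})

test_that("multi-label derivation thresholds class pixel fractions", {
  a <- matrix(3L, 50, 50)
  expect_identical(unname(deriveLabels(a)), c(FALSE, FALSE, TRUE))

  # 10 Cell pixels of 2500 = 0.4%: below a 1% threshold, present at 0
  a[1, 1:10] <- 2L
  expect_false(deriveLabels(a, minFraction = 0.01)["Cell"])
  expect_true(deriveLabels(a, minFraction = 0)["Cell"])
  expect_error(deriveLabels(a, minFraction = 1), "minFraction")
})

test_that("deriveLabels is monotone in the presence threshold", {
  ps <- tinyPatchSet(minFraction = 0)
  thresholds <- c(0, 0.005, 0.01, 0.05, 0.2)
  labs <- lapply(thresholds, function(t) patchLabels(deriveLabels(ps, t)))
  for (i in seq_len(length(thresholds) - 1))
    expect_true(all(labs[[i]] | !labs[[i + 1]]))  # raising t never turns on
})

test_that("every patch from a fully annotated image carries at least one label", {
  ps <- tinyPatchSet()
  expect_true(all(rowSums(patchLabels(ps)) >= 1))
})

test_that("random splits have exact sizes and are seed-deterministic", {
  ps <- tinyPatchSet(kernel = 32L, stride = 32L, nImages = 4)
  n <- nPatches(ps)
  plan <- SplitPlan(seed = 31L)
  sp1 <- splitPatches(ps, plan)
  sizes <- table(patchSplit(sp1))
  expect_equal(unname(sizes["test"]), round(0.1 * n), tolerance = 0)
  expect_equal(unname(sizes["finetune"]), round(0.1 * n), tolerance = 0)
  expect_identical(sum(sizes), n)
  sp2 <- splitPatches(ps, plan)
  expect_identical(patchSplit(sp1), patchSplit(sp2))
  expect_false(identical(patchSplit(sp1),
                         patchSplit(splitPatches(ps, SplitPlan(seed = 99L)))))
  # folds cover 1..folds over the labeled pool
  expect_setequal(unique(sp1@fold[patchSplit(sp1) != "repr"]), 1:10)
  expect_error(splitPatches(tinyPatchSet(kernel = 96L, stride = 96L),
                            SplitPlan(folds = 10L)), "folds")
})

test_that("spatial_block splits never leak source pixels into held-out sets", {
  ps <- tinyPatchSet(kernel = 32L, stride = 16L, nImages = 4)
  sp <- splitPatches(ps, SplitPlan(strategy = "spatial_block", seed = 5L))
  org <- patchOrigins(sp); k <- 32
  split <- patchSplit(sp)
  overlap <- function(i, j)
    sp@sourceId[i] == sp@sourceId[j] &
      abs(org[i, 1] - org[j, 1]) < k & abs(org[i, 2] - org[j, 2]) < k
  idxT <- which(split == "test"); idxF <- which(split == "finetune")
  idxR <- which(split == "repr")
  crossPairs <- rbind(expand.grid(i = idxT, j = c(idxF, idxR)),
                      expand.grid(i = idxF, j = idxR))
  expect_identical(sum(overlap(crossPairs$i, crossPairs$j)), 0L)
  expect_true(length(idxT) > 0 && length(idxF) > 0)
})
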