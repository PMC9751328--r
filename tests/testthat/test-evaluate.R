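test_that("accuracy is correct/total and permutation-invariant", {
  expect_equal(classificationAccuracy(c(rep(TRUE, 9), FALSE), rep(TRUE, 10)), 0.9)
  expect_equal(classificationAccuracy(1:5, 1:5), 1.0)
  truth <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(classificationAccuracy(!truth, truth), 0.0)
  set.seed(2)
  pred <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  tr <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  p <- sample(50)
  expect_equal(classificationAccuracy(pred[p], tr[p]),
               classificationAccuracy(pred, tr))
  expect_error(classificationAccuracy(logical(0), logical(0)), "empty")
  expect_error(classificationAccuracy(1:3, 1:4), "length")
})

test_that("evaluation reports keep overall = mean of per-class means", {
  acc <- matrix(c(0.8832, 0.9104, 0.9621), 1, 3)  # one repeat
  rep1 <- evalReport(acc, protocol = "linear")
  expect_equal(rep1@overallMean, mean(c(88.32, 91.04, 96.21)),
               tolerance = 1e-9)
  expect_equal(rep1@overallSd, 0)
  set.seed(4)
  accs <- matrix(runif(30, 0.5, 1), 10, 3)
  repN <- evalReport(accs)
  expect_equal(repN@overallMean, mean(repN@perClassMean), tolerance = 1e-9)
  expect_equal(unname(repN@perClassSd),
               unname(apply(accs * 100, 2, sd)), tolerance = 1e-9)
  expect_true(validObject(repN))
})

test_that("cross-validation aggregates repeats like an independent fold loop", {
  # a deterministic pseudo-pipeline whose accuracy depends on the test fold
  fn <- function(train, test, seed) {
    v <- c(mean(test) / 100, length(test) / 100, 0.5)
    pmin(v, 1)
  }
  rep1 <- crossValidate(fn, n = 60, folds = 10L, seed = 3, scheme = "kfold")
  expect_identical(rep1@nRepeats, 10L)
  expect_identical(rep1@configEcho$folds, 10L)
  expect_identical(rep1@configEcho$seed, 3)
  # independent loop replaying the same derived fold assignment
  accs <- matrix(NA_real_, 10, 3)
  ns$withSeed(deriveSeed(3, "cv"), {
    foldId <- rep_len(1:10, 60)[sample.int(60)]
    for (r in 1:10) {
      test <- which(foldId == r)
      accs[r, ] <- fn(setdiff(1:60, test), test,
                      deriveSeed(3, paste0("cv-", r)))
    }
  })
  expect_equal(unname(rep1@perClassMean), unname(colMeans(accs) * 100),
               tolerance = 1e-12)
  expect_equal(unname(rep1@perClassSd), unname(apply(accs * 100, 2, sd)),
               tolerance = 1e-12)
})

test_that("a constant pipeline yields zero standard deviation over repeats", {
  fn <- function(train, test, seed) c(0.7, 0.8, 0.9)
  rep1 <- crossValidate(fn, n = 40, folds = 10L, seed = 1)
  expect_equal(unname(rep1@perClassSd), c(0, 0, 0))
  expect_equal(rep1@overallSd, 0)
  expect_equal(rep1@overallMean, 80)
  expect_error(crossValidate(fn, n = 5, folds = 10L, seed = 1), "insufficient")
})

test_that("report files carry the table layout and machine-readable form", {
  dir <- withr::local_tempdir()
  rep1 <- evalReport(matrix(c(0.8, 0.9, 0.95), 1, 3), protocol = "finetune")
  paths <- writeEvalReport(rep1, file.path(dir, "report"), method = "Twin")
  txt <- readLines(paths[1])
  expect_match(txt[1], "Byproduct\tCell\tSurface\tOverall")
  expect_match(txt[2], "^Twin\t")
  tb <- read.delim(paths[2])
  expect_identical(tb$class, c("Byproduct", "Cell", "Surface", "Overall"))
  expect_equal(tb$mean_pct[4], mean(c(80, 90, 95)))
})

test_that("CAMs have the patch shape, unit range, and constant fallback", {
  ps <- separablePatchSet(n = 20)
  m <- trainBinaryHead(smallEncoder(), ps, "Cell",
                       ProbeConfig(mode = "linear_frozen", epochs = 5L,
                                   seed = 2))
  patch <- patchPixels(ps)[, , 1]
  cam <- generateCAM(m, patch)
  expect_identical(dim(cam), dim(patch))
  expect_gte(min(cam), 0); expect_lte(max(cam), 1)

  # zero conv weights on a constant patch: uniform maps, uniform CAM
  mZero <- m
  for (l in seq_along(mZero$encoder@params$conv))
    mZero$encoder@params$conv[[l]]$W[] <- 0
  camZ <- generateCAM(mZero, matrix(128, 32, 32))
  expect_true(all(camZ == 0.5))
  expect_error(generateCAM(m, matrix(0, 33, 33)), "divisible")
  expect_error(generateCAM(list(), patch), "feature maps")
})

test_that("the Cell CAM concentrates on a bright cell in one quadrant", {
  # train a probe on patches whose positives carry a bright blob in the
  # top-left quadrant, then integrate the CAM by quadrant
  set.seed(31)
  k <- 32L; n <- 60
  y <- rep(c(TRUE, FALSE), length.out = n)
  px <- array(matrix(runif(k * k * n, 40, 80), k * k, n), c(k, k, n))
  an <- array(3L, c(k, k, n))
  for (i in which(y)) {
    px[3:10, 3:10, i] <- 220
    an[3:10, 3:10, i] <- 2L
  }
  ps <- new("PatchSet", pixels = px, annotations = an,
            origins = matrix(0L, n, 2), sourceId = rep("s", n), kernel = k,
            stride = k,
            labels = cbind(Byproduct = !y, Cell = y, Surface = rep(TRUE, n)),
            split = rep("finetune", n), fold = rep(1L, n))
  m <- trainBinaryHead(smallEncoder(9), ps, "Cell",
                       ProbeConfig(mode = "linear_frozen", epochs = 40L,
                                   seed = 3))
  cam <- generateCAM(m, px[, , which(y)[1]])
  q <- c(sum(cam[1:16, 1:16]), sum(cam[1:16, 17:32]),
         sum(cam[17:32, 1:16]), sum(cam[17:32, 17:32]))
  expect_gte(q[1] / sum(q), 0.5)
})

test_that("heatmaps from the oracle model equal the ground-truth label table", {
  img <- tinyImage(seed = 14)
  hms <- classDistributionHeatmap(img, oracleModel(0.01), kernel = 32,
                                  stride = 16)
  ps <- deriveLabels(extractPatches(img, 32, 16), 0.01)
  lab <- patchLabels(ps)
  nR <- length(unique(patchOrigins(ps)[, 1]))
  nC <- length(unique(patchOrigins(ps)[, 2]))
  expect_identical(dim(hms$Cell@decisions), c(nR, nC))
  for (cl in semClasses())
    expect_identical(as.vector(hms[[cl]]@decisions), unname(lab[, cl]))
})

test_that("an all-Surface scene maps to a pure Surface heatmap", {
  img <- generateScene(tinySpec(nCells = 0L, nClusters = 0L,
                                nByproductBlobs = 0L), 5)
  hms <- classDistributionHeatmap(img, oracleModel(0.01), 32, 32)
  expect_true(all(hms$Surface@decisions))
  expect_false(any(hms$Cell@decisions))
  expect_false(any(hms$Byproduct@decisions))
  dir <- withr::local_tempdir()
  paths <- writeHeatmap(hms$Surface, file.path(dir, "surface"))
  expect_true(all(file.exists(paths)))
  tb <- read.delim(paths[2])
  expect_identical(nrow(tb), length(hms$Surface@decisions))
})
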