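# the conv/pool kernels and the hand-derived backward passes are validated
# against finite differences and direct R reimplementations

ns <- asNamespace("SEMBiofilm")

test_that("compiled convolution matches a direct R computation", {
  set.seed(1)
  H <- 6L; W <- 5L; Cin <- 2L; Cout <- 3L; B <- 2L
  x <- array(rnorm(H * W * Cin * B), c(H, W, Cin, B))
  w <- array(rnorm(3 * 3 * Cin * Cout), c(3, 3, Cin, Cout))
  b <- rnorm(Cout)
  y <- ns$cpp_conv2d_forward(x, w, b, 1L)
  expect_identical(dim(y), c(H, W, Cout, B))
  # direct same-padding convolution at a handful of positions
  xp <- array(0, c(H + 2, W + 2, Cin, B))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  for (pos in list(c(1, 1, 1, 1), c(3, 4, 2, 2), c(6, 5, 3, 1))) {
    r <- pos[1]; cc <- pos[2]; co <- pos[3]; bb <- pos[4]
    ref <- sum(xp[r:(r + 2), cc:(cc + 2), , bb] * w[, , , co]) + b[co]
    expect_equal(y[r, cc, co, bb], ref, tolerance = 1e-12)
  }
})

test_that("conv backward agrees with finite differences on a smooth loss", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  w <- array(rnorm(9 * 1 * 3, 0, 0.5), c(3, 3, 1, 3))
  b <- rnorm(3)
  loss <- function(x, w, b) sum(ns$cpp_conv2d_forward(x, w, b, 1L)^2) / 2
  y <- ns$cpp_conv2d_forward(x, w, b, 1L)
  g <- ns$cpp_conv2d_backward(x, w, y, 1L)   # dL/dy = y for this loss
  eps <- 1e-6
  for (t in 1:10) {
    i <- sample(length(w), 1)
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    expect_equal(g$dw[i], (loss(x, wp, b) - loss(x, wm, b)) / (2 * eps),
                 tolerance = 1e-4)
    j <- sample(length(x), 1)
    xp2 <- x; xp2[j] <- xp2[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    expect_equal(g$dx[j], (loss(xp2, w, b) - loss(xm, w, b)) / (2 * eps),
                 tolerance = 1e-4)
  }
  expect_equal(g$db, apply(y, 3, sum), tolerance = 1e-10)
})

test_that("max pooling forward/backward route values and gradients correctly", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  pl <- ns$cpp_maxpool2_forward(x)
  expect_equal(pl$y[, , 1, 1], matrix(c(6, 8, 14, 16), 2, 2))
  dy <- pl$y; dy[] <- 1
  dx <- ns$cpp_maxpool2_backward(pl$idx, dy, dim(x))
  expect_equal(sum(dx), 4)
  expect_true(all(dx[x %in% c(6, 8, 14, 16)] == 1))
  expect_true(all(dx[!x %in% c(6, 8, 14, 16)] == 0))
})

test_that("full encoder+projector backward matches finite differences", {
  set.seed(42)
  conv <- ns$initEncoderParams(c(3L, 4L))
  proj <- ns$initProjectorParams(4L, c(5L, 4L))
  x1 <- array(runif(8 * 8 * 3), c(8, 8, 1, 3))
  x2 <- array(runif(8 * 8 * 3), c(8, 8, 1, 3))
  lossOf <- function(conv, proj) {
    pA <- ns$projForward(proj, ns$encoderForward(conv, x1)$features)
    pB <- ns$projForward(proj, ns$encoderForward(conv, x2)$features)
    bA <- ns$bnForward(pA$z); bB <- ns$bnForward(pB$z)
    ns$.barlowGrad(bA$zn, bB$zn, 5e-3)$loss
  }
  eA <- ns$encoderForward(conv, x1); pA <- ns$projForward(proj, eA$features)
  eB <- ns$encoderForward(conv, x2); pB <- ns$projForward(proj, eB$features)
  bA <- ns$bnForward(pA$z); bB <- ns$bnForward(pB$z)
  g <- ns$.barlowGrad(bA$zn, bB$zn, 5e-3)
  pbA <- ns$projBackward(proj, pA, ns$bnBackward(bA, g$dzA))
  pbB <- ns$projBackward(proj, pB, ns$bnBackward(bB, g$dzB))
  cg <- ns$paramMap2(ns$encoderBackward(conv, eA, pbA$dx),
                     ns$encoderBackward(conv, eB, pbB$dx), `+`)
  pg <- ns$paramMap2(pbA$grads, pbB$grads, `+`)
  eps <- 1e-5
  checks <- 0
  set.seed(7)
  for (t in 1:24) {
    inConv <- t %% 2 == 0
    l <- sample(2, 1); nm <- "W"   # conv biases are absorbed by batch norm
    tgt <- if (inConv) cg[[l]][[nm]] else pg[[l]][[nm]]
    i <- sample(length(tgt), 1)
    # skip near-zero gradients where relative error is meaningless
    if (abs(tgt[i]) < 1e-4) next
    perturb <- function(d) {
      cv <- conv; pj <- proj
      if (inConv) cv[[l]][[nm]][i] <- cv[[l]][[nm]][i] + d
      else pj[[l]][[nm]][i] <- pj[[l]][[nm]][i] + d
      lossOf(cv, pj)
    }
    num <- (perturb(eps) - perturb(-eps)) / (2 * eps)
    expect_equal(num, tgt[i], tolerance = 2e-2)
    checks <- checks + 1
  }
  expect_gte(checks, 5)
})

test_that("bilinear and bicubic resizing reproduce exact references", {
  m <- matrix(as.numeric(1:16), 4, 4)
  expect_equal(ns$resizeBilinear(m, 4, 4), m)
  up <- ns$nearestUpscale(m, 2)
  expect_identical(dim(up), c(8L, 8L))
  expect_equal(up[1:2, 1:2], matrix(m[1, 1], 2, 2))
  # constant images stay constant under every resampler
  k <- matrix(5, 6, 6)
  expect_true(all(abs(ns$resizeBilinear(k, 11, 13) - 5) < 1e-12))
  expect_true(all(abs(ns$bicubicUpscale(k, 3) - 5) < 1e-9))
  # bicubic interpolates a linear ramp exactly away from borders
  ramp <- matrix(rep(seq(0, 30, length.out = 16), 16), 16, 16, byrow = TRUE)
  up2 <- ns$bicubicUpscale(ramp, 2)
  inner <- up2[10:20, 10:20]
  expect_equal(max(abs(diff(t(inner)))) , 1, tolerance = 1e-6)
})
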