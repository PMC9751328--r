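# Small convolutional encoder + linear projector with hand-derived
# backpropagation, batched over R arrays [H, W, C, B]. Convolution and max
# pooling run in compiled code (src/conv.cpp); everything else is matrix
# algebra. SGD with classical momentum.

# He-style initialisation under the current RNG stream
.initConv <- function(kh, kw, cin, cout) {
  list(W = array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

.initLinear <- function(nin, nout) {
  list(W = matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

# encoder: [conv 3x3 same -> ReLU -> maxpool 2x2] per channel spec, then
# global average pooling of the final feature maps
initEncoderParams <- function(channels = c(8L, 16L, 32L)) {
  cin <- 1L
  conv <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    conv[[i]] <- .initConv(3L, 3L, cin, channels[i])
    cin <- channels[i]
  }
  conv
}

initProjectorParams <- function(nin, widths) {
  proj <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    proj[[i]] <- .initLinear(nin, widths[i])
    nin <- widths[i]
  }
  proj
}

# encoder block: conv -> channel batch-norm -> ReLU -> maxpool. Batch
# statistics (over batch and spatial positions jointly) are used in every
# pass, so even single-image passes are well-defined.
encoderForward <- function(conv, x, keepCache = TRUE) {
  caches <- if (keepCache) vector("list", length(conv)) else NULL
  for (i in seq_along(conv)) {
    pre <- cpp_conv2d_forward(x, conv[[i]]$W, conv[[i]]$b, 1L)
    bn <- cpp_chanbn_forward(pre, 1e-8)
    pl <- cpp_maxpool2_forward(bn$act)
    if (keepCache)
      caches[[i]] <- list(x = x, zn = bn$zn, sd = bn$sd, idx = pl$idx,
                          actDim = dim(bn$act))
    x <- pl$y
  }
  d <- dim(x)                       # [h, w, C, B]
  fm <- x
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  feat <- matrix(colMeans(x), d[3], d[4])   # C x B
  list(features = t(feat), maps = fm, caches = caches, mapDim = d)
}

encoderBackward <- function(conv, fwd, dFeatures) {
  d <- fwd$mapDim
  dmap <- array(rep(t(dFeatures) / (d[1] * d[2]), each = d[1] * d[2]), d)
  grads <- vector("list", length(conv))
  for (i in rev(seq_along(conv))) {
    ca <- fwd$caches[[i]]
    dact <- cpp_maxpool2_backward(ca$idx, dmap, ca$actDim)
    dpre <- cpp_chanbn_backward(ca$zn, ca$sd, dact)
    g <- cpp_conv2d_backward(ca$x, conv[[i]]$W, dpre, 1L)
    grads[[i]] <- list(W = g$dw, b = g$db)
    dmap <- g$dx
  }
  grads
}

# projector: linear layers with ReLU between (not after the last); with
# bnHidden the hidden activations are batch-normalized before the ReLU
# (the twin-objective projector's published layout)
projForward <- function(proj, f, bnHidden = FALSE) {
  hs <- vector("list", length(proj))
  x <- f
  for (i in seq_along(proj)) {
    z <- sweep(x %*% proj[[i]]$W, 2, proj[[i]]$b, "+")
    if (i < length(proj)) {
      bn <- if (bnHidden) bnForward(z) else NULL
      a <- if (bnHidden) bn$zn else z
      hs[[i]] <- list(x = x, bn = bn, a = a)
      x <- a * (a > 0)
    } else {
      hs[[i]] <- list(x = x)
      x <- z
    }
  }
  list(z = x, hs = hs, bnHidden = bnHidden)
}

projBackward <- function(proj, fwd, dz) {
  grads <- vector("list", length(proj))
  for (i in rev(seq_along(proj))) {
    h <- fwd$hs[[i]]
    if (i < length(proj)) {
      dz <- dz * (h$a > 0)
      if (fwd$bnHidden) dz <- bnBackward(h$bn, dz)
    }
    grads[[i]] <- list(W = crossprod(h$x, dz), b = colSums(dz))
    dz <- dz %*% t(proj[[i]]$W)
  }
  list(grads = grads, dx = dz)
}

#' Batch-normalize an embedding batch per dimension
#'
#' Centers and scales each embedding dimension to mean 0 and unit variance
#' over the batch (population statistics), as used by the twin-branch
#' cross-correlation objective.
#'
#' @param z numeric matrix B x D.
#' @param eps numerical floor for the variance.
#' @return Matrix of the same shape.
#' @export
batchNormalize <- function(z, eps = 1e-8) {
  mu <- colMeans(z)
  zc <- sweep(z, 2, mu)
  v <- colMeans(zc^2)
  sweep(zc, 2, sqrt(v + eps), "/")
}

bnForward <- function(z, eps = 1e-8) {
  mu <- colMeans(z)
  zc <- sweep(z, 2, mu)
  v <- colMeans(zc^2)
  zn <- sweep(zc, 2, sqrt(v + eps), "/")
  list(zn = zn, sd = sqrt(v + eps))
}

bnBackward <- function(cache, dzn) {
  zn <- cache$zn
  t1 <- sweep(dzn, 2, colMeans(dzn))
  t2 <- sweep(zn, 2, colMeans(dzn * zn), "*")
  sweep(t1 - t2, 2, cache$sd, "/")
}

#' L2-normalize the rows of an embedding batch
#'
#' @param z numeric matrix B x D (or a vector treated as one row).
#' @return Matrix with unit-norm rows.
#' @export
l2NormalizeRows <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  z / pmax(sqrt(rowSums(z^2)), 1e-12)
}

l2Backward <- function(z, dn) {
  nrm <- pmax(sqrt(rowSums(z^2)), 1e-12)
  n <- z / nrm
  (dn - n * rowSums(dn * n)) / nrm
}

# ---- parameter-tree arithmetic (recursive over nested lists of arrays) ----

paramMap2 <- function(a, b, f) {
  if (is.list(a)) return(Map(function(x, y) paramMap2(x, y, f), a, b))
  f(a, b)
}

paramZero <- function(a) {
  if (is.list(a)) return(lapply(a, paramZero))
  a * 0
}

sgdStep <- function(params, grads, vel, lr, momentum = 0.9) {
  vel <- paramMap2(vel, grads, function(v, g) momentum * v + g)
  params <- paramMap2(params, vel, function(p, v) p - lr * v)
  list(params = params, vel = vel)
}

# elementwise EMA: m * old + (1 - m) * new, with shape checking
emaUpdate <- function(momentumParams, queryParams, m) {
  if (!.congruent(momentumParams, queryParams))
    .stopf("momentum and query parameters are not shape-congruent")
  paramMap2(momentumParams, queryParams, function(a, b) m * a + (1 - m) * b)
}

# stack a list of matrices into an [H, W, 1, B] batch
stackBatch <- function(mats) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(H, W, 1L, length(mats)))
}

# deterministic evaluation view: center crop at 90% of the patch side (the
# midpoint of the training crop-scale range), rescaled to the network input
# size so train and eval views share one scale distribution
evalView <- function(patch, outputSize) {
  side <- min(min(dim(patch)), max(outputSize, round(0.9 * min(dim(patch)))))
  resizeBilinear(centerCrop(patch, side), outputSize, outputSize)
}

# features of raw patches under the deterministic eval view
encodeFeatures <- function(conv, pixArray, idx, outputSize, batch = 256L) {
  feats <- NULL
  for (start in seq(1L, length(idx), by = batch)) {
    sel <- idx[start:min(start + batch - 1L, length(idx))]
    views <- lapply(sel, function(i) evalView(pixArray[, , i], outputSize) / 255)
    f <- encoderForward(conv, stackBatch(views), keepCache = FALSE)$features
    feats <- rbind(feats, f)
  }
  feats
}
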