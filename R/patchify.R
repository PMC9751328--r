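# Sliding-window decomposition of annotated images into patches, per-class
# object masks, image-level multi-labels, and the 80/10/10 split into
# representation-learning / fine-tune / test subsets.

#' Extract overlapping square patches by sliding window
#'
#' Windows of size `kernel` are anchored at origins `(i*stride, j*stride)`
#' (0-based) wherever the window fits; the count is
#' `(floor((H-k)/s)+1) * (floor((W-k)/s)+1)` per image. Annotation patches
#' are cut at the same coordinates so labels stay aligned.
#'
#' @param img an [AnnotatedImage-class] or a named list of them.
#' @param kernel patch side m in pixels (`m << min(H, W)` in intended use).
#' @param stride step in pixels (>= 1).
#' @return A [PatchSet-class].
#' @export
#' @examples
#' img <- generateScene(SceneSpec(width = 256L, height = 256L, nCells = 8L,
#'                                metaStripHeight = 0L), seed = 1)
#' extractPatches(img, kernel = 64, stride = 64)
extractPatches <- function(img, kernel, stride) {
  if (is.list(img)) {
    ids <- names(img)
    if (is.null(ids)) ids <- sprintf("img-%02d", seq_along(img))
    parts <- Map(function(x, id) extractPatches1(x, kernel, stride, id),
                 img, ids)
    return(do.call(combinePatchSets, unname(parts)))
  }
  extractPatches1(img, kernel, stride, "img-01")
}

extractPatches1 <- function(img, kernel, stride, sourceId) {
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  H <- nrow(img@pixels); W <- ncol(img@pixels)
  if (stride < 1L) .stopf("stride must be >= 1")
  if (kernel > min(H, W))
    .stopf("kernel (%d) exceeds the smallest image dimension (%d)", kernel, min(H, W))
  r0 <- seq(0L, H - kernel, by = stride)
  c0 <- seq(0L, W - kernel, by = stride)
  n <- length(r0) * length(c0)
  px <- array(0, c(kernel, kernel, n))
  an <- array(0L, c(kernel, kernel, n))
  org <- matrix(0L, n, 2L, dimnames = list(NULL, c("row", "col")))
  i <- 0L
  for (cc in c0) for (rr in r0) {
    i <- i + 1L
    px[, , i] <- img@pixels[(rr + 1):(rr + kernel), (cc + 1):(cc + kernel)]
    an[, , i] <- img@annotation[(rr + 1):(rr + kernel), (cc + 1):(cc + kernel)]
    org[i, ] <- c(rr, cc)
  }
  new("PatchSet", pixels = px, annotations = an, origins = org,
      sourceId = rep(sourceId, n), kernel = kernel, stride = stride,
      labels = matrix(logical(0), 0, 3), split = rep("", n),
      fold = rep(0L, n))
}

#' Combine patch sets cut with the same kernel and stride
#'
#' @param ... [PatchSet-class] objects.
#' @return A single concatenated [PatchSet-class].
#' @export
combinePatchSets <- function(...) {
  sets <- list(...)
  k <- unique(vapply(sets, function(s) s@kernel, 0L))
  s <- unique(vapply(sets, function(s) s@stride, 0L))
  if (length(k) != 1L || length(s) != 1L)
    .stopf("patch sets must share kernel and stride to be combined")
  n <- sum(vapply(sets, nPatches, 0L))
  px <- array(0, c(k, k, n)); an <- array(0L, c(k, k, n))
  off <- 0L
  for (st in sets) {
    idx <- off + seq_len(nPatches(st))
    px[, , idx] <- st@pixels; an[, , idx] <- st@annotations
    off <- off + nPatches(st)
  }
  lab <- do.call(rbind, lapply(sets, function(x) x@labels))
  if (is.null(lab)) lab <- matrix(logical(0), 0, 3)
  new("PatchSet", pixels = px, annotations = an,
      origins = do.call(rbind, lapply(sets, function(x) x@origins)),
      sourceId = unlist(lapply(sets, function(x) x@sourceId), use.names = FALSE),
      kernel = k, stride = s, labels = lab,
      split = unlist(lapply(sets, function(x) x@split), use.names = FALSE),
      fold = unlist(lapply(sets, function(x) x@fold), use.names = FALSE))
}

#' Per-class object masks of one patch
#'
#' For each class, renders the patch with only that class's pixels kept at
#' their source intensity and everything else black (0), using the aligned
#' pixel-level annotation. The three supports are pairwise disjoint and
#' jointly cover the patch. Masks serve ground-truth derivation and auditing;
#' the classifier consumes the original patch.
#'
#' @param patch numeric matrix of patch grey levels.
#' @param annPatch integer matrix of class codes, same shape.
#' @return Named list of three masked matrices (Byproduct, Cell, Surface).
#' @export
makeObjectMasks <- function(patch, annPatch) {
  if (!all(dim(patch) == dim(annPatch)))
    .stopf("patch and annotation patch are misaligned: %s vs %s",
           paste(dim(patch), collapse = "x"), paste(dim(annPatch), collapse = "x"))
  out <- lapply(1:3, function(k) patch * (annPatch == k))
  names(out) <- .semClasses
  out
}

#' @describeIn deriveLabels image-level multi-label of one annotation patch:
#'   a class is present iff its pixel fraction is at least `minFraction`
#'   (`minFraction = 0` means at least one pixel).
#' @export
setMethod("deriveLabels", "matrix", function(object, minFraction = 0.01) {
  if (minFraction < 0 || minFraction >= 1)
    .stopf("minFraction must lie in [0, 1)")
  fr <- tabulate(object, 3L) / length(object)
  lab <- if (minFraction == 0) fr > 0 else fr >= minFraction
  names(lab) <- .semClasses
  lab
})

#' Multi-label ground truth
#'
#' Assigns each patch up to three binary presence flags (Byproduct, Cell,
#' Surface) from its pixel-level annotation. Raising `minFraction` can only
#' turn flags off (monotone thresholding).
#'
#' @param object a [PatchSet-class] or an annotation matrix.
#' @param minFraction minimum class pixel fraction for presence (default 1%,
#'   which suppresses single-pixel annotation specks).
#' @return For a `PatchSet`: the set with its `labels` slot filled.
#' @name deriveLabels
#' @export
setMethod("deriveLabels", "PatchSet", function(object, minFraction = 0.01) {
  n <- nPatches(object)
  lab <- matrix(FALSE, n, 3L, dimnames = list(NULL, .semClasses))
  for (i in seq_len(n))
    lab[i, ] <- deriveLabels(object@annotations[, , i], minFraction)
  object@labels <- lab
  object
})

# overlap-connected components of window origins within one source image:
# windows overlap iff |d_row| < kernel and |d_col| < kernel
.overlapComponents <- function(origins, kernel, stride) {
  n <- nrow(origins)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  key <- paste(origins[, 1], origins[, 2])
  idx <- stats::setNames(seq_len(n), key)
  steps <- seq_len(max(0L, ceiling(kernel / stride) - 1L)) * stride
  for (i in seq_len(n)) {
    for (dr in c(0L, steps)) for (dc in steps) {
      j <- idx[paste(origins[i, 1] + dr, origins[i, 2] + dc)]
      if (!is.na(j)) { a <- find(i); b <- find(j); if (a != b) comp[a] <- b }
    }
    for (dr in steps) {
      j <- idx[paste(origins[i, 1] + dr, origins[i, 2])]
      if (!is.na(j)) { a <- find(i); b <- find(j); if (a != b) comp[a] <- b }
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Split patches into representation-learning, fine-tune and test subsets
#'
#' `random_patch` shuffles patches and cuts 80/10/10 (sizes exact up to
#' rounding by one patch), mirroring patch-wise sampling. `spatial_block`
#' first groups patches into overlap-connected components of their source
#' windows and assigns whole components, so no held-out patch shares any
#' source pixel with a patch of another subset (no leakage through window
#' overlap); fractions are then met only as closely as component sizes
#' allow. Fold numbers `1..folds` are assigned cyclically over the shuffled
#' fine-tune and test patches. Deterministic given `plan@seed`.
#'
#' @param ps a labeled [PatchSet-class].
#' @param plan a [SplitPlan()].
#' @return The [PatchSet-class] with `split` and `fold` filled.
#' @export
splitPatches <- function(ps, plan = SplitPlan()) {
  validObject(plan)
  n <- nPatches(ps)
  nTest <- round(n * plan@testFraction)
  nFt <- round(n * plan@finetuneFraction)
  if (nFt + nTest < plan@folds)
    .stopf("too few patches (%d labeled) for %d folds", nFt + nTest, plan@folds)
  splitVec <- rep("repr", n)
  withSeed(plan@seed, {
    if (plan@strategy == "random_patch") {
      ord <- sample.int(n)
      splitVec[ord[seq_len(nTest)]] <- "test"
      splitVec[ord[nTest + seq_len(nFt)]] <- "finetune"
    } else {
      comp <- rep(NA_integer_, n)
      off <- 0L
      for (sid in unique(ps@sourceId)) {
        sel <- which(ps@sourceId == sid)
        comp[sel] <- off + .overlapComponents(ps@origins[sel, , drop = FALSE],
                                              ps@kernel, ps@stride)
        off <- max(comp[sel])
      }
      groups <- split(seq_len(n), comp)
      groups <- groups[sample.int(length(groups))]
      assigned <- c(test = 0L, finetune = 0L)
      for (g in groups) {
        if (assigned["test"] < nTest) {
          splitVec[g] <- "test"; assigned["test"] <- assigned["test"] + length(g)
        } else if (assigned["finetune"] < nFt) {
          splitVec[g] <- "finetune"; assigned["finetune"] <- assigned["finetune"] + length(g)
        }
      }
    }
    lab <- which(splitVec != "repr")
    lab <- lab[sample.int(length(lab))]
    ps@fold[lab] <- rep_len(seq_len(plan@folds), length(lab))
  })
  ps@split <- splitVec
  validObject(ps)
  ps
}

#' Subset a patch set by split membership
#'
#' @param ps a [PatchSet-class].
#' @param which one or more of "repr", "finetune", "test".
#' @return The subset [PatchSet-class].
#' @export
subsetPatches <- function(ps, which) {
  idx <- which(ps@split %in% which)
  indexPatches(ps, idx)
}

# positional subset (internal but reused by evaluation)
indexPatches <- function(ps, idx) {
  new("PatchSet", pixels = ps@pixels[, , idx, drop = FALSE],
      annotations = ps@annotations[, , idx, drop = FALSE],
      origins = ps@origins[idx, , drop = FALSE], sourceId = ps@sourceId[idx],
      kernel = ps@kernel, stride = ps@stride,
      labels = if (nrow(ps@labels)) ps@labels[idx, , drop = FALSE] else ps@labels,
      split = ps@split[idx], fold = ps@fold[idx])
}

#' Write the patch label table
#'
#' Tab-delimited with columns (source_id, row, col, kernel, byproduct, cell,
#' surface, split, fold).
#'
#' @param ps a labeled [PatchSet-class].
#' @param path output file.
#' @return Invisibly, the table.
#' @export
writeLabelTable <- function(ps, path) {
  stopifnot(nrow(ps@labels) == nPatches(ps))
  tb <- data.frame(source_id = ps@sourceId, row = ps@origins[, 1],
                   col = ps@origins[, 2], kernel = ps@kernel,
                   byproduct = ps@labels[, 1], cell = ps@labels[, 2],
                   surface = ps@labels[, 3], split = ps@split, fold = ps@fold)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tb)
}
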