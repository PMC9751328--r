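# End-to-end orchestration with reproducible configuration and seeding.
# Stages: synth -> preprocess -> patchify -> pretrain (per variant) ->
# finetune -> baseline -> evaluate (-> heatmap). Each stage derives its own
# seed from the global seed and stage name, and leaves a manifest (config
# echo, seed, input/output hashes) when an output directory is given.

#' Default run configuration
#'
#' Desk-scale study conditions: 12 synthetic 512 x 512 scenes, 64 px patches
#' at half-kernel stride, 80/10/10 split, both SSL variants pretrained for
#' 10 epochs at batch 64 over 32 px views, three binary heads fine-tuned for
#' 20 epochs on the 10% fine-tune split, accuracy scored on the held-out 10%.
#'
#' @param seed global integer seed.
#' @return Nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(nImages = 12L, width = 512L, height = 472L, nCells = 40L,
                 nClusters = 8L, clusterSizeRange = c(8L, 18L),
                 nByproductBlobs = 22L, byproductRadiusRange = c(15, 75),
                 cellAxisRange = c(10, 28), metaStripHeight = 40L,
                 magnificationLabel = 436, scaleUm = 10),
    preprocess = list(claheClipLimit = 2, claheTileGrid = c(8L, 8L),
                      srFactor = 1L, srBackend = "classical_bicubic",
                      srScaleThresholdUm = 10, srMagnificationThreshold = 1000),
    patchify = list(kernel = 64L, overlap = 0.5, minFraction = 0.01,
                    reprFraction = 0.8, finetuneFraction = 0.1,
                    testFraction = 0.1, strategy = "random_patch",
                    folds = 10L),
    ssl = list(outputSize = 32L, channels = c(8L, 16L, 32L), projDim = 64L,
               batchSize = 64L, epochs = 10L, lr = 0.05, tau = 0.2, m = 0.9,
               queueCapacity = 512L, lambda = 5e-3),
    downstream = list(epochs = 20L, lr = 0.1, batchSize = 64L,
                      labelFraction = 1, threshold = 0.5,
                      classWeighting = TRUE)
  )
}

.manifest <- function(outDir, stage, seed, cfg, inputs, outputs = list()) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(file.path(outDir, stage), recursive = TRUE, showWarnings = FALSE)
  man <- list(stage = stage, seed = seed, config = cfg,
              inputHashes = lapply(inputs, rlang::hash),
              outputHashes = lapply(outputs, rlang::hash),
              packageVersion = as.character(utils::packageVersion("SEMBiofilm")))
  jsonlite::write_json(man, file.path(outDir, stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Run one pipeline stage
#'
#' Executes a single stage against the accumulated pipeline `state`
#' (a named list of upstream outputs); raises a dependency error naming the
#' stage when an upstream output is missing. Returns the updated state.
#'
#' @param stage one of "synth", "preprocess", "patchify",
#'   "pretrain_contrastive", "pretrain_noncontrastive", "finetune",
#'   "baseline", "evaluate".
#' @param config a [defaultRunConfig()]-shaped list.
#' @param state named list carried between stages (empty to start).
#' @param outDir optional directory for artifacts and manifests.
#' @return The updated state list.
#' @export
runStage <- function(stage, config = defaultRunConfig(), state = list(),
                     outDir = NULL) {
  need <- function(what, from) {
    if (is.null(state[[what]]))
      .stopf("stage '%s' requires output '%s' of stage '%s' which has not run",
             stage, what, from)
    state[[what]]
  }
  seed <- deriveSeed(config$seed, stage)
  if (stage == "synth") {
    sc <- config$synth
    spec <- SceneSpec(width = sc$width, height = sc$height, nCells = sc$nCells,
                      nClusters = sc$nClusters,
                      clusterSizeRange = sc$clusterSizeRange,
                      nByproductBlobs = sc$nByproductBlobs,
                      byproductRadiusRange = sc$byproductRadiusRange,
                      cellAxisRange = sc$cellAxisRange,
                      metaStripHeight = sc$metaStripHeight,
                      magnificationLabel = sc$magnificationLabel,
                      scaleUm = sc$scaleUm)
    state$images <- generateDataset(sc$nImages, spec, seed,
                                    dir = if (is.null(outDir)) NULL
                                          else file.path(outDir, "synth"))
    .manifest(outDir, stage, seed, sc, list(), list(images = state$images))
  } else if (stage == "preprocess") {
    imgs <- need("images", "synth")
    pc <- config$preprocess
    cfg <- PreprocessConfig(claheClipLimit = pc$claheClipLimit,
                            claheTileGrid = pc$claheTileGrid,
                            srFactor = pc$srFactor, srBackend = pc$srBackend,
                            srScaleThresholdUm = pc$srScaleThresholdUm,
                            srMagnificationThreshold = pc$srMagnificationThreshold)
    state$preprocessed <- lapply(imgs, preprocessImage, cfg = cfg)
    .manifest(outDir, stage, seed, pc, list(images = imgs),
              list(preprocessed = state$preprocessed))
  } else if (stage == "patchify") {
    imgs <- need("preprocessed", "preprocess")
    pc <- config$patchify
    stride <- max(1L, as.integer(round(pc$kernel * (1 - pc$overlap))))
    ps <- extractPatches(imgs, kernel = pc$kernel, stride = stride)
    ps <- deriveLabels(ps, pc$minFraction)
    ps <- splitPatches(ps, SplitPlan(reprFraction = pc$reprFraction,
                                     finetuneFraction = pc$finetuneFraction,
                                     testFraction = pc$testFraction,
                                     strategy = pc$strategy, seed = seed,
                                     folds = pc$folds))
    state$patches <- ps
    if (!is.null(outDir)) {
      dir.create(file.path(outDir, stage), recursive = TRUE, showWarnings = FALSE)
      writeLabelTable(ps, file.path(outDir, stage, "patch_labels.tsv"))
    }
    .manifest(outDir, stage, seed, pc, list(preprocessed = imgs),
              list(patches = state$patches))
  } else if (stage %in% c("pretrain_contrastive", "pretrain_noncontrastive")) {
    ps <- need("patches", "patchify")
    variant <- sub("pretrain_", "", stage)
    sc <- config$ssl
    pcfg <- pretrainConfig(outputSize = sc$outputSize, channels = sc$channels,
                           projDim = sc$projDim, batchSize = sc$batchSize,
                           epochs = sc$epochs, lr = sc$lr, tau = sc$tau,
                           m = sc$m, queueCapacity = sc$queueCapacity,
                           lambda = sc$lambda, seed = seed)
    enc <- pretrainEncoder(ps, variant, pcfg)
    state[[paste0("encoder_", variant)]] <- enc
    if (!is.null(outDir)) {
      dir.create(file.path(outDir, stage), recursive = TRUE, showWarnings = FALSE)
      write.table(data.frame(epoch = seq_along(enc@lossTrace),
                             mean_loss = enc@lossTrace),
                  file.path(outDir, stage, "loss_trace.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    .manifest(outDir, stage, seed, sc, list(patches = ps), list(encoder = enc))
  } else if (stage == "finetune") {
    ps <- need("patches", "patchify")
    dc <- config$downstream
    ft <- subsetPatches(ps, "finetune")
    for (variant in c("contrastive", "noncontrastive")) {
      enc <- need(paste0("encoder_", variant), paste0("pretrain_", variant))
      cfg <- ProbeConfig(mode = "finetune", labelFraction = dc$labelFraction,
                         epochs = dc$epochs, seed = seed, lr = dc$lr,
                         batchSize = dc$batchSize, threshold = dc$threshold,
                         classWeighting = dc$classWeighting)
      state[[paste0("models_", variant)]] <- trainMultiLabel(enc, ft, cfg)
    }
    .manifest(outDir, stage, seed, dc, list(patches = ft),
              list(contrastive = state$models_contrastive,
                   noncontrastive = state$models_noncontrastive))
  } else if (stage == "baseline") {
    ps <- need("patches", "patchify")
    dc <- config$downstream
    ft <- subsetPatches(ps, "finetune")
    cfg <- ProbeConfig(mode = "finetune", labelFraction = dc$labelFraction,
                       epochs = dc$epochs, seed = seed, lr = dc$lr,
                       batchSize = dc$batchSize, threshold = dc$threshold,
                       classWeighting = dc$classWeighting)
    sc <- config$ssl
    state$models_supervised <-
      trainSupervisedBaseline(ft, cfg,
                              pretrainConfig(outputSize = sc$outputSize,
                                             channels = sc$channels,
                                             projDim = sc$projDim,
                                             seed = seed))
    .manifest(outDir, stage, seed, dc, list(patches = ft),
              list(supervised = state$models_supervised))
  } else if (stage == "evaluate") {
    ps <- need("patches", "patchify")
    for (mdl in c("models_contrastive", "models_noncontrastive",
                  "models_supervised"))
      if (is.null(state[[mdl]]))
        .stopf("stage 'evaluate' requires '%s' from the finetune/baseline stages", mdl)
    test <- subsetPatches(ps, "test")
    truth <- patchLabels(test)
    res <- list()
    for (mdl in c("models_contrastive", "models_noncontrastive",
                  "models_supervised")) {
      pred <- predictMultilabel(state[[mdl]], test)
      perClass <- vapply(.semClasses, function(cl)
        classificationAccuracy(pred$decisions[, cl], truth[, cl]), 0)
      res[[sub("models_", "", mdl)]] <-
        list(perClass = perClass, overall = mean(perClass))
    }
    state$evaluation <- res
    .manifest(outDir, stage, seed, list(), list(test = test),
              list(evaluation = res))
  } else {
    .stopf("unknown stage '%s'", stage)
  }
  state
}

#' Run the full pipeline
#'
#' Convenience wrapper running synth, preprocess, patchify, both pretraining
#' variants, fine-tuning, the supervised baseline and evaluation in order.
#'
#' @param config a [defaultRunConfig()]-shaped list (or a YAML path).
#' @param outDir optional artifact directory.
#' @return The final state list (see [runStage()]); `$evaluation` holds the
#'   per-method per-class and overall accuracies on the held-out test split.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  state <- list()
  for (stage in c("synth", "preprocess", "patchify", "pretrain_contrastive",
                  "pretrain_noncontrastive", "finetune", "baseline",
                  "evaluate"))
    state <- runStage(stage, config, state, outDir)
  state
}
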