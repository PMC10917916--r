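# End-to-end orchestration: simulate -> split -> augment -> train ->
# extract -> fuse -> select -> classify -> t-test (-> Grad-CAM), with one
# global seed fanned out to fixed per-stage seeds, per-stage artifacts on
# disk, file-hash manifest, and resume from the feature stage onward.

#' Default pipeline configuration
#'
#' Nested list of per-stage settings. The defaults run the full-scale
#' protocol (both 227 x 227 architectures, 50 epochs, augmentation on);
#' desk-scale runs override `train$epochs`, `select$iters` and friends.
#'
#' @param outDir output directory.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a `pipelineConfig` list.
#' @export
defaultPipelineConfig <- function(outDir = "mammofuse_run", seed = 1L) {
  structure(list(
    outDir = outDir,
    seed = as.integer(seed),
    resume = TRUE,
    simulate = list(nPerClass = 50L, size = c(227L, 227L), effect = 0.9,
                    writeImages = FALSE),
    split = list(fraction = 0.5),
    augment = list(enabled = TRUE),
    train = list(epochs = 50L, minibatch = 64L,
                 learningRate = 0.000241, momentum = 0.776,
                 bayesBudget = 0L),
    extract = list(batch = 8L),
    fuse = list(sigma = NULL, reg = 1e-3, bins = 256L),
    select = list(n = 20L, iters = 30L, folds = 3L,
                  classifierCfg = list(preset = "narrow", maxit = 80L,
                                       lambda = 1e-3)),
    classify = list(presets = c("medium", "trilayered"), folds = 10L,
                    partition = "test"),
    gradcam = list(enabled = FALSE, nImages = 4L)
  ), class = "pipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips through YAML; unknown keys are rejected so typos fail early.
#'
#' @param path YAML file path.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- defaultPipelineConfig()
  checkKeys <- function(x, ref, where) {
    bad <- setdiff(names(x), names(ref))
    stopIfNot(length(bad) == 0L,
              paste0("unknown config key(s) in ", where, ": ",
                     paste(bad, collapse = ", ")))
    for (k in names(x))
      if (is.list(ref[[k]]) && is.list(x[[k]]) && k != "classifierCfg")
        checkKeys(x[[k]], ref[[k]], paste0(where, "$", k))
  }
  checkKeys(raw, base, "config")
  cfg <- modifyList(base, raw)
  # modifyList drops NULLs; restore explicit NULL-able field
  if (!is.null(raw$fuse) && !("sigma" %in% names(raw$fuse)))
    cfg$fuse$sigma <- base$fuse$sigma
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @rdname readPipelineConfig
#' @param config a `pipelineConfig` list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

fileHashes <- function(paths) {
  h <- tools::md5sum(paths[file.exists(paths)])
  as.list(h)
}

#' Run the full classification pipeline
#'
#' Executes, in order: synthetic image simulation, stratified 50:50 split,
#' augmentation of the training partition only (no test-set leakage),
#' training of the three-block and four-block networks (optionally after
#' Bayesian hyperparameter search), GAP feature extraction for all images,
#' kernel-CCA + entropy fusion, quantum-GNDO wrapper selection driven by
#' the training rows, cross-validated evaluation of the configured
#' classifier presets on four feature sets (each network alone, fused,
#' selected), and the paired t analysis of the two presets across those
#' four experiments. Feature/fusion/selection artifacts are written as TSV
#' under `outDir` and reloaded on resume, so deleting a downstream artifact
#' re-executes only the stages after it.
#'
#' @param config a `pipelineConfig` list (see [defaultPipelineConfig()]).
#' @return list with `metrics` (per experiment and preset), `ttest`,
#'   `selection`, `fusion` diagnostics and `manifest` (per-stage seeds,
#'   parameters and output file hashes).
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  cfg <- config
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulate = deriveSeed(cfg$seed, "simulate"),
                split = deriveSeed(cfg$seed, "split"),
                train3 = deriveSeed(cfg$seed, "train-three"),
                train4 = deriveSeed(cfg$seed, "train-four"),
                select = deriveSeed(cfg$seed, "select"),
                classify = deriveSeed(cfg$seed, "classify"))
  manifest <- list(config = unclass(cfg), seeds = seeds,
                   started = format(Sys.time()), stages = list())
  pth <- function(f) file.path(cfg$outDir, f)

  featPaths <- c(pth("features_three_block.tsv"),
                 pth("features_four_block.tsv"))
  splitPath <- pth("split.tsv")

  needFeatures <- !(cfg$resume && all(file.exists(featPaths)) &&
                      file.exists(splitPath))
  if (needFeatures) {
    iset <- generateMammoImages(cfg$simulate$nPerClass,
                                size = cfg$simulate$size,
                                effect = cfg$simulate$effect,
                                seed = seeds$simulate)
    if (isTRUE(cfg$simulate$writeImages))
      writeImageSet(iset, pth("images"))
    sp <- splitDataset(iset, seed = seeds$split,
                       fraction = cfg$split$fraction)
    trainSet <- subsetImages(iset, sp$trainIds)
    if (isTRUE(cfg$augment$enabled)) trainSet <- augmentImages(trainSet)

    hp <- hyperParams(learningRate = cfg$train$learningRate,
                      momentum = cfg$train$momentum,
                      epochs = cfg$train$epochs,
                      minibatch = cfg$train$minibatch)
    nets <- list()
    for (arch in c("three_block", "four_block")) {
      sd <- if (arch == "three_block") seeds$train3 else seeds$train4
      if (cfg$train$bayesBudget >= 1L)
        hp <- bayesOptimize(arch, trainSet, budget = cfg$train$bayesBudget,
                            seed = sd)
      net <- buildNetwork(arch, seed = sd)
      net <- trainNetwork(net, trainSet, hp, seed = sd)
      nets[[arch]] <- net
      F <- extractFeatures(net, iset, batch = cfg$extract$batch)
      writeFeatureMatrix(
        F, pth(paste0("features_", arch, ".tsv")))
    }
    write.table(data.frame(sample_id = sprintf("s%04d", seq_len(nImages(iset))),
                           class = as.character(imageLabels(iset)),
                           partition = ifelse(seq_len(nImages(iset)) %in%
                                                sp$trainIds, "train", "test")),
                splitPath, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$train <- list(
      lossThree = nets$three_block@history$loss,
      lossFour = nets$four_block@history$loss)
    if (isTRUE(cfg$gradcam$enabled)) {
      dir.create(pth("gradcam"), showWarnings = FALSE)
      mal <- which(imageLabels(iset) == "malignant")
      for (i in head(mal, cfg$gradcam$nImages))
        writeHeatmapPNG(
          gradCAM(nets$four_block, images(iset)[[i]], "malignant"),
          pth(file.path("gradcam", sprintf("cam_s%04d.png", i))))
    }
  }

  F1 <- readFeatureMatrix(featPaths[1])
  F2 <- readFeatureMatrix(featPaths[2])
  splitInfo <- read.delim(splitPath)
  y <- factor(splitInfo$class, levels = c("benign", "malignant"))
  trainRows <- splitInfo$partition == "train"

  fusedPath <- pth("features_fused.tsv")
  fuseReportPath <- pth("fusion_report.json")
  if (!(cfg$resume && file.exists(fusedPath) &&
          file.exists(fuseReportPath))) {
    fused <- fuseFeatures(F1, F2, sigma = cfg$fuse$sigma,
                          reg = cfg$fuse$reg, bins = cfg$fuse$bins)
    writeFeatureMatrix(fusedValues(fused), fusedPath)
    jsonlite::write_json(
      list(rho = fused@kcca@rho, sigma = fused@sigma, reg = cfg$fuse$reg,
           entropySummary = summary(fused@weights)),
      fuseReportPath, auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  Ffused <- readFeatureMatrix(fusedPath)
  fuseReport <- jsonlite::read_json(fuseReportPath)

  maskPath <- pth("selection_mask.tsv")
  histPath <- pth("selection_history.tsv")
  if (!(cfg$resume && file.exists(maskPath) && file.exists(histPath))) {
    sel <- selectFeatures(
      Ffused[trainRows, , drop = FALSE], y[trainRows],
      cfg = c(cfg$select, list(seed = seeds$select)))
    write.table(data.frame(feature_id = colnames(Ffused),
                           selected = as.integer(selectionMask(sel))),
                maskPath, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(iteration = seq_along(selectionHistory(sel)),
                           bestCost = selectionHistory(sel),
                           fitnessRatio = sel@fitnessRatio),
                histPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  maskDf <- read.delim(maskPath)
  mask <- maskDf$selected == 1L

  evalRows <- if (identical(cfg$classify$partition, "all")) rep(TRUE, length(y))
              else !trainRows
  sets <- list(three_block = F1[evalRows, , drop = FALSE],
               four_block = F2[evalRows, , drop = FALSE],
               fused = Ffused[evalRows, , drop = FALSE],
               selected = Ffused[evalRows, mask, drop = FALSE])
  metrics <- list()
  accTable <- matrix(NA_real_, length(cfg$classify$presets), length(sets),
                     dimnames = list(cfg$classify$presets, names(sets)))
  for (p in cfg$classify$presets) {
    for (s in names(sets)) {
      rep_ <- crossvalEvaluate(sets[[s]], y[evalRows], preset = p,
                               folds = cfg$classify$folds,
                               seed = seeds$classify)
      metrics[[paste(p, s, sep = ".")]] <- rep_
      accTable[p, s] <- metricValues(rep_)[["accuracy"]]
    }
  }
  jsonlite::write_json(
    lapply(metrics, function(m) as.list(metricValues(m))),
    pth("metrics.json"), auto_unbox = TRUE, digits = NA)

  tt <- if (nrow(accTable) >= 2)
    pairedTTest(accTable[1, ], accTable[2, ], labels = colnames(accTable))
  else NULL

  outputs <- c(featPaths, splitPath, fusedPath, fuseReportPath, maskPath,
               histPath, pth("metrics.json"))
  manifest$stages$outputs <- fileHashes(outputs)
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, pth("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(metrics = metrics, accuracies = accTable, ttest = tt,
       selection = list(mask = mask, nSelected = sum(mask)),
       fusion = fuseReport, manifest = manifest)
}
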