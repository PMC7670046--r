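#' Default pipeline configuration
#'
#' Returns the configuration list understood by [runPipeline()], with the
#' study defaults: 56 apathy + 122 non-apathy synthetic walks on a
#' 256x256 canvas, the 48/102/8/20 stratified split, all four
#' binarization channels, the 50..220 threshold ladder, the 4x4 strip
#' grid and all seven models.
#'
#' @param ... named overrides of the default keys.
#' @return Named list of configuration values.
#' @examples
#' cfg <- pipelineConfig(models = c("nn", "knn"), thresholds = c(150, 160))
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    nApathy = 56L,
    nNonapathy = 122L,
    datasetSeed = 1L,
    splitSeed = 1L,
    modelSeed = 1L,
    canvas = c(256L, 256L),
    classEffect = 0.7,
    gaitParams = list(),
    channels = c("red", "green", "blue", "Y"),
    thresholds = thresholdLadder(),
    grid = c(4L, 4L),
    models = modelNames(),
    normalize = TRUE,
    split = list(nTrainApathy = 48L, nTrainNonapathy = 102L,
                 nTestApathy = 8L, nTestNonapathy = 20L),
    writeImages = FALSE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, overrides)
}

#' Read a pipeline configuration file
#'
#' Accepts JSON (`.json`) or YAML (`.yml`/`.yaml`); keys must be a subset
#' of the [pipelineConfig()] schema — unknown keys fail fast with their
#' names.
#'
#' @param path configuration file path.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

provenanceHeader <- function(cfg, configHash) {
  c(sprintf("# config_hash: %s", configHash),
    sprintf("# dataset_seed: %d split_seed: %d model_seed: %d",
            cfg$datasetSeed, cfg$splitSeed, cfg$modelSeed))
}

writeCsvWithProvenance <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write a dataset manifest (and optionally the PNG images)
#'
#' The manifest CSV has one row per sample: `filename`, `label`,
#' `q1`..`q14` and the questionnaire total `score`.
#'
#' @param dataset a [SpectrogramSet-class].
#' @param outDir output directory (created if missing).
#' @param writeImages also write each spectrogram as a PNG.
#' @return Invisibly, the manifest data.frame.
#' @export
writeManifest <- function(dataset, outDir, writeImages = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset)
  resp <- questionnaireResponses(dataset)
  colnames(resp) <- paste0("q", seq_len(ncol(resp)))
  manifest <- data.frame(
    filename = sprintf("sample_%03d.png", seq_len(n)),
    label = as.character(apathyLabels(dataset)),
    resp,
    score = rowSums(resp),
    stringsAsFactors = FALSE)
  if (writeImages) {
    imgs <- spectrograms(dataset)
    for (i in seq_len(n))
      png::writePNG(imgs[[i]] / 255,
                    file.path(outDir, manifest$filename[i]))
  }
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Run the whole pipeline: simulate, score, extract, train, sweep, report
#'
#' End-to-end seeded run that leaves four artifacts in `outDir`:
#' `manifest.csv` (per-sample label, questionnaire items and score),
#' `features.csv` (per sample, channel and threshold strip features),
#' `sweep.csv` (one [runSweep()] record per configuration),
#' `summary.json` (best configuration per model plus provenance), and
#' `config.json` (the resolved configuration). Every CSV carries comment
#' lines with the config hash and the seeds; rereads need
#' `read.csv(..., comment.char = "#")`.
#'
#' @param config a configuration list from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outDir output directory.
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list with the dataset, the sweep data.frame and
#'   the summary list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, quiet = FALSE) {
  config <- do.call(pipelineConfig, config)   # validates keys + fills gaps
  if (length(config$models) < 1L) stop("config 'models' must be non-empty")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  configPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, configPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  configHash <- unname(tools::md5sum(configPath))
  header <- provenanceHeader(config, configHash)

  say("simulate: %d apathy + %d non-apathy walks (seed %d)",
      config$nApathy, config$nNonapathy, config$datasetSeed)
  params <- do.call(gaitParams, config$gaitParams)
  dataset <- simulateDataset(config$nApathy, config$nNonapathy,
                             seed = config$datasetSeed, params = params,
                             canvas = config$canvas,
                             classEffect = config$classEffect)

  say("score: writing manifest for %d samples", length(dataset))
  manifest <- writeManifest(dataset, outDir,
                            writeImages = isTRUE(config$writeImages))
  writeCsvWithProvenance(manifest, file.path(outDir, "manifest.csv"),
                         header)

  say("extract: %d channels x %d thresholds", length(config$channels),
      length(config$thresholds))
  featRows <- list()
  d <- config$grid[2] + config$grid[1]
  for (channel in config$channels) {
    planes <- lapply(spectrograms(dataset), extractChannel,
                     channel = channel)
    for (threshold in config$thresholds) {
      x <- featureMatrixFromPlanes(planes, threshold,
                                   as.integer(config$grid),
                                   config$normalize)
      colnames(x) <- paste0("f", seq_len(d))
      featRows[[length(featRows) + 1L]] <- data.frame(
        filename = manifest$filename, channel = channel,
        threshold = threshold, x, label = manifest$label,
        stringsAsFactors = FALSE)
    }
  }
  writeCsvWithProvenance(do.call(rbind, featRows),
                         file.path(outDir, "features.csv"), header)

  say("sweep: %d models on split seed %d (model seed %d)",
      length(config$models), config$splitSeed, config$modelSeed)
  sweep <- runSweep(dataset, channels = config$channels,
                    thresholds = config$thresholds,
                    models = config$models, grid = as.integer(config$grid),
                    split = config$split, splitSeed = config$splitSeed,
                    modelSeed = config$modelSeed,
                    normalize = config$normalize)
  writeCsvWithProvenance(sweep, file.path(outDir, "sweep.csv"), header)

  best <- lapply(split(sweep, sweep$model), function(df) {
    top <- df[order(-df$totalAccuracy, df$threshold), ][1, ]
    list(channel = top$channel, threshold = top$threshold,
         totalAccuracy = top$totalAccuracy, apathyC = top$apathyC,
         nonapathyC = top$nonapathyC)
  })
  summary <- list(configHash = configHash,
                  seeds = list(dataset = config$datasetSeed,
                               split = config$splitSeed,
                               model = config$modelSeed),
                  nRecords = nrow(sweep),
                  bestPerModel = best)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d sweep records", nrow(sweep))
  invisible(list(dataset = dataset, sweep = sweep, summary = summary))
}
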