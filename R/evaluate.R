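#' Stratified train/test split
#'
#' Draws a seeded, per-class shuffled split with exactly the requested
#' numbers of training and test samples per class. The defaults reproduce
#' the study protocol: 150 training images (48 apathy, 102 non-apathy)
#' and 28 test images (8 apathy, 20 non-apathy).
#'
#' @param dataset a [SpectrogramSet-class], or a factor/character vector
#'   of labels.
#' @param nTrainApathy,nTrainNonapathy,nTestApathy,nTestNonapathy
#'   per-class counts.
#' @param seed integer shuffle seed.
#' @return List with integer index vectors `train` and `test` (disjoint).
#' @examples
#' labs <- rep(c("apathy", "non-apathy"), c(56, 122))
#' sp <- stratifiedSplit(labs, seed = 1)
#' lengths(sp)  # 150, 28
#' @export
stratifiedSplit <- function(dataset, nTrainApathy = 48L,
                            nTrainNonapathy = 102L, nTestApathy = 8L,
                            nTestNonapathy = 20L, seed = 1L) {
  labels <- if (is(dataset, "SpectrogramSet")) apathyLabels(dataset)
            else asLabelFactor(dataset)
  counts <- c(nTrainApathy, nTrainNonapathy, nTestApathy, nTestNonapathy)
  if (any(counts < 0)) stop("split counts must be non-negative")
  set.seed(as.integer(seed))
  idxAp <- sample(which(labels == "apathy"))
  idxNo <- sample(which(labels == "non-apathy"))
  if (length(idxAp) < nTrainApathy + nTestApathy)
    stop(sprintf("need %d apathy samples, have %d",
                 nTrainApathy + nTestApathy, length(idxAp)))
  if (length(idxNo) < nTrainNonapathy + nTestNonapathy)
    stop(sprintf("need %d non-apathy samples, have %d",
                 nTrainNonapathy + nTestNonapathy, length(idxNo)))
  list(train = c(idxAp[seq_len(nTrainApathy)],
                 idxNo[seq_len(nTrainNonapathy)]),
       test = c(idxAp[nTrainApathy + seq_len(nTestApathy)],
                idxNo[nTrainNonapathy + seq_len(nTestNonapathy)]))
}

#' Per-class classification rates over the test set
#'
#' All four rates are fractions of the whole test set, so they always sum
#' to one: `apathyC` (apathy, called correctly), `apathyM` (apathy,
#' missed), `nonapathyC` and `nonapathyM` analogously. The total accuracy
#' is `apathyC + nonapathyC`, i.e. the overall fraction correct; a
#' constant non-apathy predictor on the default 8/20 test split therefore
#' scores exactly 20/28.
#'
#' @param predictions,truths equal-length label vectors.
#' @return Named numeric vector with components `apathyC`, `apathyM`,
#'   `nonapathyC`, `nonapathyM`, `totalAccuracy`.
#' @examples
#' truth <- rep(c("apathy", "non-apathy"), c(8, 20))
#' computeMetrics(rep("non-apathy", 28), truth)["totalAccuracy"]
#' @export
computeMetrics <- function(predictions, truths) {
  predictions <- asLabelFactor(predictions)
  truths <- asLabelFactor(truths)
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  n <- length(truths)
  if (n == 0L) stop("empty test set")
  correct <- predictions == truths
  ap <- truths == "apathy"
  c(apathyC = sum(ap & correct) / n,
    apathyM = sum(ap & !correct) / n,
    nonapathyC = sum(!ap & correct) / n,
    nonapathyM = sum(!ap & !correct) / n,
    totalAccuracy = sum(correct) / n)
}

## feature matrix for every sample of a dataset at one (channel, threshold,
## grid) configuration; planes may be precomputed with extractChannel
featureMatrixFromPlanes <- function(planes, threshold, grid, normalize) {
  d <- grid[2] + grid[1]
  t(vapply(planes, function(pl) {
    counts <- gridCounts(binarize(pl, threshold), grid)
    if (normalize) counts <- counts / stripAreas(nrow(pl), ncol(pl), grid)
    counts
  }, numeric(d)))
}

#' Feature matrix for a whole dataset
#'
#' @param dataset a [SpectrogramSet-class].
#' @param channel,threshold,grid,normalize see [extractFeatures()].
#' @return Numeric matrix, one row per sample, `grid[2] + grid[1]`
#'   columns.
#' @export
featureMatrix <- function(dataset, channel, threshold, grid = c(4L, 4L),
                          normalize = TRUE) {
  stopifnot(is(dataset, "SpectrogramSet"))
  grid <- as.integer(grid)
  planes <- lapply(spectrograms(dataset), extractChannel, channel = channel)
  featureMatrixFromPlanes(planes, threshold, grid, normalize)
}

## fit the requested models for one configuration, sharing base fits with
## the ensemble so its members are trained exactly once
fitConfigModels <- function(models, xTrain, yTrain, seed, modelControl) {
  ensembleMembers <- c("svm", "random_forest", "nn", "knn")
  baseNeeded <- union(setdiff(models, "ensemble"),
                      if ("ensemble" %in% models) ensembleMembers)
  fits <- lapply(baseNeeded, function(mn)
    fitApathyModel(mn, xTrain, yTrain, seed = seed,
                   control = modelControl[[mn]] %||% list()))
  names(fits) <- baseNeeded
  if ("ensemble" %in% models) {
    fits[["ensemble"]] <- new("ApathyModel", modelName = "ensemble",
                              fit = NULL, members = fits[ensembleMembers],
                              seed = as.integer(seed),
                              decisionThreshold = 0.5,
                              featureLength = ncol(xTrain),
                              control = list(members = ensembleMembers))
  }
  fits[models]
}

#' Sweep channels, thresholds and models
#'
#' Runs the full evaluation protocol on one seeded stratified split:
#' for every combination of binarization channel and threshold, extracts
#' the strip-count features, trains every requested model on the training
#' partition and records its test-set [computeMetrics()] rates. The
#' default axes (4 channels x 18 thresholds x 7 models) produce 504
#' records.
#'
#' @param dataset a [SpectrogramSet-class].
#' @param channels character vector of binarization channels.
#' @param thresholds integer vector of binarization thresholds.
#' @param models character vector of model names, see [modelNames()].
#' @param grid strip grid `c(rows, cols)`.
#' @param split named list of per-class split counts
#'   (`nTrainApathy`, `nTrainNonapathy`, `nTestApathy`,
#'   `nTestNonapathy`); defaults to the 48/102/8/20 protocol.
#' @param splitSeed,modelSeed seeds for the split shuffle and the
#'   stochastic model fits.
#' @param normalize use area-normalized strip fractions (default) or raw
#'   counts.
#' @param modelControl named list of per-model `control` lists passed to
#'   [fitApathyModel()].
#' @return A data.frame with one row per (channel, threshold, model):
#'   the configuration, the five metric columns and the seeds used.
#' @export
runSweep <- function(dataset,
                     channels = c("red", "green", "blue", "Y"),
                     thresholds = thresholdLadder(),
                     models = modelNames(),
                     grid = c(4L, 4L),
                     split = list(),
                     splitSeed = 1L, modelSeed = 1L,
                     normalize = TRUE,
                     modelControl = list()) {
  stopifnot(is(dataset, "SpectrogramSet"))
  if (length(channels) < 1L || length(thresholds) < 1L || length(models) < 1L)
    stop("channels, thresholds and models must be non-empty")
  models <- vapply(models, match.arg, character(1), choices = modelNames())
  grid <- as.integer(grid)
  splitArgs <- utils::modifyList(
    list(nTrainApathy = 48L, nTrainNonapathy = 102L,
         nTestApathy = 8L, nTestNonapathy = 20L), split)
  sp <- do.call(stratifiedSplit,
                c(list(dataset = dataset, seed = splitSeed), splitArgs))
  labels <- apathyLabels(dataset)
  yTrain <- labels[sp$train]
  yTest <- labels[sp$test]
  rows <- vector("list", length(channels) * length(thresholds) *
                   length(models))
  k <- 0L
  for (channel in channels) {
    planes <- lapply(spectrograms(dataset), extractChannel,
                     channel = channel)
    for (threshold in thresholds) {
      x <- featureMatrixFromPlanes(planes, threshold, grid, normalize)
      fits <- fitConfigModels(models, x[sp$train, , drop = FALSE], yTrain,
                              modelSeed, modelControl)
      for (mn in models) {
        pred <- predict(fits[[mn]], x[sp$test, , drop = FALSE])
        met <- computeMetrics(pred, yTest)
        k <- k + 1L
        rows[[k]] <- data.frame(channel = channel, threshold = threshold,
                                model = mn, gridRows = grid[1],
                                gridCols = grid[2], t(met),
                                splitSeed = as.integer(splitSeed),
                                modelSeed = as.integer(modelSeed),
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeat the sweep over several strip grids
#'
#' The feature-vector length follows the grid (`cols + rows`: 8 for 4x4,
#' 9 for 4x5, 10 for 5x5) and every model, including the network's input
#' width, adapts to it.
#'
#' @param dataset a [SpectrogramSet-class].
#' @param grids list of `c(rows, cols)` grids.
#' @param ... further arguments passed to [runSweep()].
#' @return A data.frame: the [runSweep()] records of all grids, with a
#'   leading `grid` label column like `"4x4"`.
#' @export
gridComparison <- function(dataset,
                           grids = list(c(4L, 4L), c(4L, 5L), c(5L, 5L)),
                           ...) {
  out <- do.call(rbind, lapply(grids, function(g) {
    res <- runSweep(dataset, grid = g, ...)
    cbind(grid = sprintf("%dx%d", g[1], g[2]), res,
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
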