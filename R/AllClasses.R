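#' @import methods
NULL

APATHY_LEVELS <- c("apathy", "non-apathy")

#' Gait parameters for the synthetic spectrogram generator
#'
#' Container for the kinematic and noise parameters of the simulated
#' walking micro-Doppler signature. Velocities are expressed in spectrogram
#' rows (the vertical axis of the image is Doppler velocity, zero at the
#' bottom edge), horizontal positions in columns (the horizontal axis is
#' time).
#'
#' @slot torsoVelocityMean mean torso velocity, in rows above the bottom
#'   (zero-velocity) edge.
#' @slot strideFrequency number of gait cycles across the image width; the
#'   torso trace oscillates at this frequency.
#' @slot limbBurstAmplitude vertical extent of the limb-swing bursts above
#'   the torso velocity, in rows.
#' @slot limbBurstWidth temporal width (standard deviation, in columns) of
#'   each limb burst.
#' @slot noiseLevel additive uniform noise amplitude as a fraction of the
#'   full intensity scale, in `[0, 1]`.
#' @slot nSteps number of steps, i.e. limb bursts, across the image.
#'
#' @seealso [gaitParams()], [simulateSpectrogram()]
#' @export
setClass("GaitParams",
  representation(
    torsoVelocityMean = "numeric",
    strideFrequency   = "numeric",
    limbBurstAmplitude = "numeric",
    limbBurstWidth    = "numeric",
    noiseLevel        = "numeric",
    nSteps            = "integer"
  )
)

setValidity("GaitParams", function(object) {
  msgs <- character()
  for (s in c("torsoVelocityMean", "strideFrequency", "limbBurstAmplitude",
              "limbBurstWidth")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      msgs <- c(msgs, sprintf("'%s' must be a single non-negative number", s))
  }
  nl <- object@noiseLevel
  if (length(nl) != 1L || is.na(nl) || nl < 0 || nl > 1)
    msgs <- c(msgs, "'noiseLevel' must lie in [0, 1]")
  if (length(object@nSteps) != 1L || is.na(object@nSteps) || object@nSteps < 1L)
    msgs <- c(msgs, "'nSteps' must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct gait parameters
#'
#' Defaults describe a typical unimpaired walk on the default 256x256
#' canvas: torso trace around row 60 above the bottom edge, two full gait
#' cycles across the image, four step bursts reaching about 110 rows above
#' the torso trace, and 5% additive noise.
#'
#' @param torsoVelocityMean,strideFrequency,limbBurstAmplitude,limbBurstWidth,noiseLevel,nSteps
#'   see [GaitParams-class].
#' @return A [GaitParams-class] object.
#' @examples
#' gaitParams(noiseLevel = 0)
#' @export
gaitParams <- function(torsoVelocityMean = 60, strideFrequency = 2,
                       limbBurstAmplitude = 110, limbBurstWidth = 14,
                       noiseLevel = 0.05, nSteps = 4L) {
  new("GaitParams",
      torsoVelocityMean = as.numeric(torsoVelocityMean),
      strideFrequency = as.numeric(strideFrequency),
      limbBurstAmplitude = as.numeric(limbBurstAmplitude),
      limbBurstWidth = as.numeric(limbBurstWidth),
      noiseLevel = as.numeric(noiseLevel),
      nSteps = as.integer(nSteps))
}

#' Labelled set of synthetic spectrograms with questionnaire responses
#'
#' The central data container: a list of RGB spectrogram images (H x W x 3
#' integer arrays, 8 bits per channel), one class label per image, and the
#' 14-item Apathy Scale response each label was derived from. Validity
#' enforces that the label stored for every sample equals the label implied
#' by its questionnaire total (apathy iff the total is 16 or more).
#'
#' @slot images list of H x W x 3 arrays with values in 0..255.
#' @slot labels factor with levels `apathy`, `non-apathy`.
#' @slot responses integer matrix, one row per sample, 14 columns with
#'   values in 0..3.
#' @slot seed integer seed the set was generated from (NA when assembled
#'   by hand).
#'
#' @seealso [simulateDataset()], [spectrograms()], [apathyLabels()],
#'   [questionnaireResponses()]
#' @export
setClass("SpectrogramSet",
  representation(
    images = "list",
    labels = "factor",
    responses = "matrix",
    seed = "integer"
  )
)

setValidity("SpectrogramSet", function(object) {
  n <- length(object@images)
  msgs <- character()
  if (length(object@labels) != n || nrow(object@responses) != n)
    msgs <- c(msgs, "images, labels and responses must have equal length")
  if (!identical(levels(object@labels), APATHY_LEVELS))
    msgs <- c(msgs, "labels must be a factor with levels apathy, non-apathy")
  if (ncol(object@responses) != 14L && n > 0L)
    msgs <- c(msgs, "responses must have 14 columns")
  if (n > 0L) {
    bad <- !vapply(object@images, function(im)
      is.array(im) && length(dim(im)) == 3L && dim(im)[3] == 3L &&
        min(im) >= 0 && max(im) <= 255, logical(1))
    if (any(bad))
      msgs <- c(msgs, "every image must be an HxWx3 array with values in 0..255")
    scores <- rowSums(object@responses)
    implied <- ifelse(scores >= 16, "apathy", "non-apathy")
    if (!all(implied == as.character(object@labels)))
      msgs <- c(msgs, "stored labels must match the questionnaire-derived labels")
  }
  if (length(msgs)) msgs else TRUE
})

#' Assemble a SpectrogramSet
#'
#' @param images list of H x W x 3 arrays (values 0..255).
#' @param labels character or factor of class labels.
#' @param responses integer matrix of questionnaire items (n x 14, values
#'   0..3).
#' @param seed integer provenance seed, or `NA`.
#' @return A [SpectrogramSet-class].
#' @export
SpectrogramSet <- function(images, labels, responses, seed = NA_integer_) {
  new("SpectrogramSet",
      images = images,
      labels = factor(as.character(labels), levels = APATHY_LEVELS),
      responses = responses,
      seed = as.integer(seed))
}

#' A fitted apathy classifier
#'
#' Uniform wrapper around the seven supported model families. Obtain one
#' with [fitApathyModel()]; predict labels (and, where available,
#' apathy probabilities) with [predict()][predict,ApathyModel-method].
#'
#' @slot modelName one of `svm`, `knn`, `naive_bayes`, `decision_tree`,
#'   `random_forest`, `nn`, `ensemble`.
#' @slot fit the underlying fitted object (model-family specific).
#' @slot members list of member [ApathyModel-class] objects (ensemble only).
#' @slot seed integer seed used for stochastic fits.
#' @slot decisionThreshold probability cutoff for the neural network; an
#'   apathy probability strictly greater than this yields an apathy call.
#' @slot featureLength expected length of feature vectors at predict time.
#' @slot control list of resolved hyperparameters.
#' @export
setClass("ApathyModel",
  representation(
    modelName = "character",
    fit = "ANY",
    members = "list",
    seed = "integer",
    decisionThreshold = "numeric",
    featureLength = "integer",
    control = "list"
  )
)

setValidity("ApathyModel", function(object) {
  msgs <- character()
  if (!object@modelName %in% modelNames())
    msgs <- c(msgs, sprintf("unknown model name '%s'", object@modelName))
  if (object@decisionThreshold <= 0 || object@decisionThreshold >= 1)
    msgs <- c(msgs, "decisionThreshold must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Supported model names
#'
#' @return Character vector of the seven model identifiers.
#' @export
modelNames <- function() {
  c("svm", "knn", "naive_bayes", "decision_tree", "random_forest",
    "nn", "ensemble")
}

#' @describeIn SpectrogramSet-class number of samples
#' @param x a `SpectrogramSet`.
#' @export
setMethod("length", "SpectrogramSet", function(x) length(x@images))

#' Accessors for SpectrogramSet
#'
#' @param x a [SpectrogramSet-class].
#' @return `spectrograms()` the list of image arrays; `apathyLabels()` the
#'   label factor; `questionnaireResponses()` the n x 14 item matrix;
#'   `datasetSeed()` the generation seed.
#' @name SpectrogramSet-accessors
NULL

#' @rdname SpectrogramSet-accessors
#' @export
spectrograms <- function(x) {
  stopifnot(is(x, "SpectrogramSet"))
  x@images
}

#' @rdname SpectrogramSet-accessors
#' @export
apathyLabels <- function(x) {
  stopifnot(is(x, "SpectrogramSet"))
  x@labels
}

#' @rdname SpectrogramSet-accessors
#' @export
questionnaireResponses <- function(x) {
  stopifnot(is(x, "SpectrogramSet"))
  x@responses
}

#' @rdname SpectrogramSet-accessors
#' @export
datasetSeed <- function(x) {
  stopifnot(is(x, "SpectrogramSet"))
  x@seed
}

#' @describeIn SpectrogramSet-class subset samples
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SpectrogramSet", function(x, i, j, ..., drop = FALSE) {
  new("SpectrogramSet",
      images = x@images[i],
      labels = x@labels[i],
      responses = x@responses[i, , drop = FALSE],
      seed = x@seed)
})

setMethod("show", "SpectrogramSet", function(object) {
  n <- length(object)
  cat(sprintf("SpectrogramSet with %d sample%s", n, if (n == 1) "" else "s"))
  if (n > 0) {
    d <- dim(object@images[[1]])
    tab <- table(object@labels)
    cat(sprintf(" (%d x %d px): %d apathy, %d non-apathy",
                d[1], d[2], tab[["apathy"]], tab[["non-apathy"]]))
  }
  cat("\n")
  if (!is.na(object@seed)) cat(sprintf("  seed: %d\n", object@seed))
  invisible(object)
})

setMethod("show", "ApathyModel", function(object) {
  cat(sprintf("ApathyModel '%s' (features: %d, seed: %d)\n",
              object@modelName, object@featureLength, object@seed))
  if (object@modelName == "ensemble")
    cat("  members:", paste(vapply(object@members, slot, character(1),
                                   "modelName"), collapse = ", "), "\n")
  invisible(object)
})
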