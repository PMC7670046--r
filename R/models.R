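featureColnames <- function(d) paste0("f", seq_len(d))

asLabelFactor <- function(labels) {
  f <- factor(as.character(labels), levels = APATHY_LEVELS)
  if (anyNA(f)) stop("labels must be 'apathy' or 'non-apathy'")
  f
}

#' Fit one of the seven apathy classifiers
#'
#' Uniform training entry point for the model families compared in the
#' pipeline:
#' \describe{
#'   \item{svm}{linear support vector machine, cost 1 (e1071).}
#'   \item{knn}{k-nearest neighbours, Euclidean distance, single `k`
#'     (default 5, odd so binary votes cannot tie); vote ties and distance
#'     ties are broken deterministically toward apathy / the earlier
#'     training sample.}
#'   \item{naive_bayes}{Gaussian naive Bayes (e1071) with a small
#'     standard-deviation floor (`sdFloor`, default 1e-3) so strips that
#'     are constant within a class keep a proper density.}
#'   \item{decision_tree}{binary-threshold splits chosen by information
#'     gain (rpart, `split = "information"`), grown without a depth or
#'     complexity limit.}
#'   \item{random_forest}{100 bootstrap trees, `floor(sqrt(d))` candidate
#'     features per split (randomForest).}
#'   \item{nn}{the feed-forward network of [nnFit()], trained for 50
#'     epochs with Adam (learning rate 0.001) on mini-batches of 32;
#'     apathy is called when the sigmoid output exceeds
#'     `decisionThreshold` (default 0.5, strictly greater).}
#'   \item{ensemble}{majority vote over member models (default SVM,
#'     random forest, NN, KNN); ties go to apathy.}
#' }
#'
#' @param name model identifier, see [modelNames()].
#' @param x numeric feature matrix, one row per sample.
#' @param y class labels (`apathy` / `non-apathy`); both classes must be
#'   present.
#' @param seed integer seed for the stochastic fits (random forest, nn).
#' @param control named list of hyperparameter overrides: `cost` (svm),
#'   `k` (knn), `sdFloor` (naive_bayes), `ntree`/`mtry` (random_forest),
#'   `hidden`, `epochs`, `lr`, `batchSize`, `decisionThreshold` (nn),
#'   `members` (ensemble, character vector of member names).
#' @return An [ApathyModel-class] object.
#' @examples
#' x <- rbind(matrix(0.2, 5, 2), matrix(0.8, 5, 2))
#' y <- rep(c("apathy", "non-apathy"), each = 5)
#' fit <- fitApathyModel("svm", x, y)
#' predict(fit, x)
#' @export
fitApathyModel <- function(name, x, y, seed = 1L, control = list()) {
  name <- match.arg(name, modelNames())
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- asLabelFactor(y)
  if (nrow(x) != length(y))
    stop("number of feature rows and labels differ")
  if (nlevels(droplevels(y)) < 2L)
    stop("training set must contain both classes")
  colnames(x) <- featureColnames(ncol(x))
  seed <- as.integer(seed)
  fit <- NULL
  members <- list()
  threshold <- control$decisionThreshold %||% 0.5
  ctl <- control
  if (name == "svm") {
    fit <- e1071::svm(x, y, kernel = "linear",
                      cost = control$cost %||% 1, scale = FALSE)
    ctl$cost <- control$cost %||% 1
  } else if (name == "knn") {
    ctl$k <- as.integer(control$k %||% 5L)
    if (ctl$k < 1L || ctl$k > nrow(x)) stop("invalid 'k'")
    fit <- list(x = x, y = y, k = ctl$k)
  } else if (name == "naive_bayes") {
    fit <- e1071::naiveBayes(x, y)
    sdFloor <- control$sdFloor %||% 1e-3
    fit$tables <- lapply(fit$tables, function(tab) {
      tab[, 2] <- pmax(tab[, 2], sdFloor)
      tab
    })
    ctl$sdFloor <- sdFloor
  } else if (name == "decision_tree") {
    df <- data.frame(label = y, x, check.names = FALSE)
    fit <- rpart::rpart(label ~ ., data = df, method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(
                          minsplit = 2L, minbucket = 1L, cp = 0,
                          maxdepth = 30L, xval = 0L,
                          maxcompete = 0L, maxsurrogate = 0L))
  } else if (name == "random_forest") {
    ctl$ntree <- control$ntree %||% 100L
    ctl$mtry <- control$mtry %||% max(1L, floor(sqrt(ncol(x))))
    set.seed(seed)
    fit <- randomForest::randomForest(x, y, ntree = ctl$ntree,
                                      mtry = ctl$mtry)
  } else if (name == "nn") {
    fit <- nnFit(x, as.numeric(y == "apathy"),
                 hidden = control$hidden %||% c(16L, 32L, 64L),
                 epochs = control$epochs %||% 50L,
                 lr = control$lr %||% 1e-3,
                 seed = seed,
                 batchSize = control$batchSize %||% 32L)
  } else if (name == "ensemble") {
    memberNames <- control$members %||% c("svm", "random_forest", "nn", "knn")
    if (length(memberNames) < 1L) stop("ensemble needs at least one member")
    memberControl <- control$memberControl %||% list()
    members <- lapply(memberNames, function(mn)
      fitApathyModel(mn, x, y, seed = seed,
                     control = memberControl[[mn]] %||% list()))
    names(members) <- memberNames
    ctl$members <- memberNames
  }
  new("ApathyModel", modelName = name, fit = fit, members = members,
      seed = seed, decisionThreshold = threshold,
      featureLength = ncol(x), control = ctl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic k-nearest-neighbour vote: Euclidean distance, distance
## ties broken by training-sample order, vote ties toward apathy
knnPredictOne <- function(fit, xrow) {
  d2 <- colSums((t(fit$x) - xrow)^2)
  nn <- order(d2)[seq_len(fit$k)]
  votes <- table(fit$y[nn])
  if (votes[["apathy"]] >= votes[["non-apathy"]]) "apathy" else "non-apathy"
}

#' Majority vote over member predictions
#'
#' Counts apathy votes (`apVote`) and non-apathy votes (`noapVote`) and
#' returns apathy when `apVote >= noapVote` — a tie is resolved toward
#' apathy, the clinically conservative call.
#'
#' @param votes character or factor vector of member labels.
#' @return `"apathy"` or `"non-apathy"`.
#' @examples
#' majorityVote(c("apathy", "apathy", "non-apathy", "non-apathy"))  # tie
#' @export
majorityVote <- function(votes) {
  votes <- as.character(votes)
  if (length(votes) < 1L) stop("empty vote list")
  if (!all(votes %in% APATHY_LEVELS)) stop("unknown vote label")
  apVote <- sum(votes == "apathy")
  noapVote <- sum(votes == "non-apathy")
  if (apVote >= noapVote) "apathy" else "non-apathy"
}

#' Predict apathy labels from a fitted model
#'
#' @param object an [ApathyModel-class] from [fitApathyModel()].
#' @param newdata numeric feature matrix (or a single feature vector) with
#'   the same number of features the model was trained on.
#' @param type `"label"` (default) for class labels, `"prob"` for apathy
#'   probabilities (available for `nn`, `naive_bayes` and
#'   `random_forest`).
#' @return Factor of labels (levels `apathy`, `non-apathy`) or a numeric
#'   probability vector.
#' @export
setMethod("predict", "ApathyModel",
  function(object, newdata, type = c("label", "prob")) {
    type <- match.arg(type)
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
    newdata <- as.matrix(newdata)
    storage.mode(newdata) <- "double"
    if (ncol(newdata) != object@featureLength)
      stop(sprintf("model expects %d features, got %d",
                   object@featureLength, ncol(newdata)))
    colnames(newdata) <- featureColnames(ncol(newdata))
    name <- object@modelName
    if (type == "prob") {
      p <- switch(name,
        nn = nnPredictProb(object@fit, newdata),
        naive_bayes = predict(object@fit, newdata,
                              type = "raw")[, "apathy"],
        random_forest = predict(object@fit, newdata,
                                type = "prob")[, "apathy"],
        stop(sprintf("probabilities are not available for '%s'", name)))
      return(unname(p))
    }
    lab <- switch(name,
      svm = as.character(predict(object@fit, newdata)),
      knn = apply(newdata, 1L, function(r) knnPredictOne(object@fit, r)),
      naive_bayes = as.character(predict(object@fit, newdata,
                                         type = "class")),
      decision_tree = as.character(predict(object@fit,
                                           as.data.frame(newdata),
                                           type = "class")),
      random_forest = as.character(predict(object@fit, newdata)),
      nn = ifelse(nnPredictProb(object@fit, newdata) >
                    object@decisionThreshold, "apathy", "non-apathy"),
      ensemble = ensemblePredict(object@members, newdata))
    factor(as.character(lab), levels = APATHY_LEVELS)
  })

#' Majority-vote ensemble prediction
#'
#' Applies each fitted member to the feature rows and combines the member
#' labels with [majorityVote()] (apathy wins ties). The default ensemble
#' members are SVM, random forest, NN and KNN; a two-member naive Bayes +
#' NN variant can be built by passing those members to
#' [fitApathyModel()].
#'
#' @param members non-empty list of fitted [ApathyModel-class] objects.
#' @param newdata feature matrix or single feature vector.
#' @return Factor of labels.
#' @export
ensemblePredict <- function(members, newdata) {
  if (length(members) < 1L) stop("ensemble needs at least one fitted member")
  if (!all(vapply(members, is, logical(1), "ApathyModel")))
    stop("all members must be fitted ApathyModel objects")
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  votes <- vapply(members, function(m)
    as.character(predict(m, newdata, type = "label")),
    character(nrow(newdata)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  factor(apply(votes, 1L, majorityVote), levels = APATHY_LEVELS)
}

#' Save / load a fitted model
#'
#' `saveApathyModel()` serializes the fitted model to `path` and writes a
#' JSON sidecar (`<path>.json`) recording the model name, seed, feature
#' length, decision threshold and hyperparameters for provenance.
#'
#' @param model an [ApathyModel-class].
#' @param path file path for the serialized model (conventionally `.rds`).
#' @return `saveApathyModel()` returns `path` invisibly;
#'   `loadApathyModel()` returns the restored [ApathyModel-class].
#' @export
saveApathyModel <- function(model, path) {
  stopifnot(is(model, "ApathyModel"))
  saveRDS(model, path)
  sidecar <- list(modelName = model@modelName, seed = model@seed,
                  featureLength = model@featureLength,
                  decisionThreshold = model@decisionThreshold,
                  control = model@control)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname saveApathyModel
#' @export
loadApathyModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "ApathyModel"))
  model
}
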