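# small separable training fixture shared by the model contract tests
separableData <- function(n = 10, d = 4, gap = 0.5, seed = 3) {
  set.seed(seed)
  x <- rbind(matrix(runif(n / 2 * d, 0, 0.3), n / 2),
             matrix(runif(n / 2 * d, 0.3 + gap, 1), n / 2))
  y <- rep(c("apathy", "non-apathy"), each = n / 2)
  list(x = x, y = y)
}

test_that("every model family learns a separable training set", {
  dat <- separableData(n = 20)
  for (mn in modelNames()) {
    fit <- fitApathyModel(mn, dat$x, dat$y, seed = 1)
    expect_s4_class(fit, "ApathyModel")
    pred <- predict(fit, dat$x)
    expect_equal(as.character(pred), dat$y, label = mn)
  }
})

test_that("knn with k = 1 reproduces the training labels exactly", {
  set.seed(14)
  x <- matrix(runif(40), 20)
  y <- sample(c("apathy", "non-apathy"), 20, replace = TRUE)
  while (length(unique(y)) < 2)
    y <- sample(c("apathy", "non-apathy"), 20, replace = TRUE)
  fit <- fitApathyModel("knn", x, y, control = list(k = 1))
  expect_equal(as.character(predict(fit, x)), y)
})

test_that("naive Bayes assigns a deep in-class point to that class", {
  # two well separated Gaussian clumps; the test point sits at one centre
  set.seed(6)
  x <- rbind(matrix(rnorm(40, mean = 0, sd = 0.05), 20),
             matrix(rnorm(40, mean = 1, sd = 0.05), 20))
  y <- rep(c("apathy", "non-apathy"), each = 20)
  fit <- fitApathyModel("naive_bayes", x, y)
  expect_equal(as.character(predict(fit, rep(0, 2))), "apathy")
  expect_equal(as.character(predict(fit, rep(1, 2))), "non-apathy")
  expect_gt(predict(fit, rep(0, 2), type = "prob"), 0.99)
})

test_that("the tree's root split maximizes the information gain", {
  # 10-sample toy table: feature 1 separates the classes much better than
  # feature 2; verify against a brute-force gain computation
  x <- cbind(f1 = c(0.1, 0.2, 0.15, 0.9, 0.85, 0.95, 0.8, 0.88, 0.92, 0.87),
             f2 = c(0.5, 0.6, 0.4, 0.55, 0.45, 0.5, 0.6, 0.4, 0.52, 0.48))
  y <- c(rep("apathy", 3), rep("non-apathy", 7))
  bestGain <- vapply(1:2, function(j) {
    cuts <- sort(unique(x[, j]))
    max(vapply(cuts[-1], function(cc) infoGain(x[, j], y, cc), numeric(1)))
  }, numeric(1))
  expect_gt(bestGain[1], bestGain[2])
  fit <- fitApathyModel("decision_tree", x, y)
  rootVar <- as.character(fit@fit$frame$var[1])
  expect_equal(rootVar, "f1")
  expect_equal(as.character(predict(fit, c(0.12, 0.5))), "apathy")
})

test_that("stochastic fits are reproducible under a fixed seed", {
  dat <- separableData(n = 30, gap = 0.1)
  probe <- matrix(runif(40, 0, 1), 10)
  for (mn in c("random_forest", "nn")) {
    a <- predict(fitApathyModel(mn, dat$x, dat$y, seed = 7), probe)
    b <- predict(fitApathyModel(mn, dat$x, dat$y, seed = 7), probe)
    expect_identical(a, b, label = mn)
  }
})

test_that("fit validates its inputs", {
  dat <- separableData()
  expect_error(fitApathyModel("svm", dat$x, rep("apathy", nrow(dat$x))),
               "both classes")
  expect_error(fitApathyModel("svm", dat$x, dat$y[-1]), "differ")
  expect_error(fitApathyModel("boost", dat$x, dat$y), "arg")
  fit <- fitApathyModel("knn", dat$x, dat$y)
  expect_error(predict(fit, matrix(0, 1, 3)), "expects 4 features")
})

test_that("majority vote counts apathy vs non-apathy with ties to apathy", {
  combos <- expand.grid(rep(list(c("apathy", "non-apathy")), 4),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    votes <- unlist(combos[i, ])
    apVote <- sum(votes == "apathy")
    noapVote <- 4 - apVote
    expected <- if (apVote >= noapVote) "apathy" else "non-apathy"
    expect_equal(majorityVote(votes), expected)
  }
  expect_error(majorityVote(character(0)), "empty")
  expect_error(majorityVote(c("apathy", "unsure")), "unknown")
})

test_that("the ensemble aggregates its members' predictions by vote", {
  dat <- separableData(n = 20)
  fit <- fitApathyModel("ensemble", dat$x, dat$y, seed = 2)
  expect_equal(vapply(fit@members, slot, character(1), "modelName"),
               c(svm = "svm", random_forest = "random_forest",
                 nn = "nn", knn = "knn"))
  probe <- dat$x[c(1, 11), ]
  memberVotes <- vapply(fit@members, function(m)
    as.character(predict(m, probe)), character(2))
  expected <- apply(memberVotes, 1, majorityVote)
  expect_equal(as.character(predict(fit, probe)), unname(expected))
  expect_equal(as.character(ensemblePredict(fit@members, probe)),
               unname(expected))
  expect_error(ensemblePredict(list(), probe), "at least one")
  # the two-member naive Bayes + NN variant ties toward apathy
  nb_nn <- fitApathyModel("ensemble", dat$x, dat$y, seed = 2,
                          control = list(members = c("naive_bayes", "nn")))
  expect_length(nb_nn@members, 2)
  expect_s3_class(predict(nb_nn, probe), "factor")
})

test_that("models round-trip through save and load with provenance", {
  dat <- separableData(n = 20)
  fit <- fitApathyModel("nn", dat$x, dat$y, seed = 5)
  path <- tempfile(fileext = ".rds")
  saveApathyModel(fit, path)
  restored <- loadApathyModel(path)
  expect_identical(predict(restored, dat$x, type = "prob"),
                   predict(fit, dat$x, type = "prob"))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$modelName, "nn")
  expect_equal(sidecar$seed, 5)
  unlink(c(path, paste0(path, ".json")))
})
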