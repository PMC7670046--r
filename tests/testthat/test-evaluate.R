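test_that("the stratified split reproduces the 48/102/8/20 protocol", {
  ds <- defaultSynthData()
  sp <- stratifiedSplit(ds, seed = 1)
  labels <- apathyLabels(ds)
  expect_length(sp$train, 150)
  expect_length(sp$test, 28)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sum(labels[sp$train] == "apathy"), 48)
  expect_equal(sum(labels[sp$test] == "apathy"), 8)
  expect_identical(sp, stratifiedSplit(ds, seed = 1))
  expect_false(identical(sp, stratifiedSplit(ds, seed = 2)))
})

test_that("a split requesting more samples than available errors", {
  labs <- rep(c("apathy", "non-apathy"), c(56, 122))
  expect_error(stratifiedSplit(labs, nTrainApathy = 60), "apathy samples")
  expect_error(stratifiedSplit(labs, nTestNonapathy = 30), "non-apathy")
  expect_error(stratifiedSplit(labs, nTrainApathy = -1), "non-negative")
})

test_that("metrics are fractions of the whole test set and sum to one", {
  truth <- rep(c("apathy", "non-apathy"), c(8, 20))
  m <- computeMetrics(rep("non-apathy", 28), truth)
  expect_equal(unname(m["totalAccuracy"]), 20 / 28)
  expect_equal(unname(m["apathyC"]), 0)
  expect_equal(unname(m["apathyC"] + m["apathyM"]), 8 / 28)
  expect_equal(unname(sum(m[1:4])), 1)

  perfect <- computeMetrics(truth, truth)
  expect_equal(unname(perfect["totalAccuracy"]), 1)

  set.seed(61)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    t2 <- sample(c("apathy", "non-apathy"), n, replace = TRUE)
    p2 <- sample(c("apathy", "non-apathy"), n, replace = TRUE)
    m2 <- computeMetrics(p2, t2)
    expect_equal(unname(sum(m2[1:4])), 1)
    expect_equal(unname(m2["totalAccuracy"]),
                 unname(m2["apathyC"] + m2["nonapathyC"]))
  }
  expect_error(computeMetrics(truth[-1], truth), "length")
  expect_error(computeMetrics(character(0), character(0)), "empty")
})

test_that("a constant predictor scores exactly its class's test share", {
  ds <- smallSynthData()
  sp <- stratifiedSplit(ds, nTrainApathy = 9, nTrainNonapathy = 15,
                        nTestApathy = 3, nTestNonapathy = 5, seed = 3)
  truth <- apathyLabels(ds)[sp$test]
  mAp <- computeMetrics(rep("apathy", 8), truth)
  mNo <- computeMetrics(rep("non-apathy", 8), truth)
  expect_equal(unname(mAp["totalAccuracy"]), 3 / 8)
  expect_equal(unname(mNo["totalAccuracy"]), 5 / 8)
})

test_that("the sweep emits one record per configuration", {
  ds <- smallSynthData()
  small <- list(nTrainApathy = 9, nTrainNonapathy = 15,
                nTestApathy = 3, nTestNonapathy = 5)
  one <- runSweep(ds, channels = "red", thresholds = 150, models = "knn",
                  split = small)
  expect_equal(nrow(one), 1)
  expect_named(one, c("channel", "threshold", "model", "gridRows",
                      "gridCols", "apathyC", "apathyM", "nonapathyC",
                      "nonapathyM", "totalAccuracy", "splitSeed",
                      "modelSeed"))
  many <- runSweep(ds, channels = c("red", "Y"),
                   thresholds = c(100, 150, 200),
                   models = c("svm", "knn", "naive_bayes"), split = small)
  expect_equal(nrow(many), 2 * 3 * 3)
  expect_equal(unname(rowSums(many[, c("apathyC", "apathyM", "nonapathyC",
                                       "nonapathyM")])), rep(1, 18))
  expect_error(runSweep(ds, channels = character(0), split = small),
               "non-empty")
})

test_that("the sweep is reproducible from its seeds", {
  ds <- smallSynthData()
  small <- list(nTrainApathy = 9, nTrainNonapathy = 15,
                nTestApathy = 3, nTestNonapathy = 5)
  args <- list(ds, channels = "green", thresholds = c(120, 160),
               models = c("random_forest", "nn", "ensemble"),
               split = small, splitSeed = 4, modelSeed = 9)
  expect_identical(do.call(runSweep, args), do.call(runSweep, args))
})

test_that("grid comparison adapts the feature length per grid", {
  ds <- smallSynthData()
  small <- list(nTrainApathy = 9, nTrainNonapathy = 15,
                nTestApathy = 3, nTestNonapathy = 5)
  grids <- list(c(4L, 4L), c(4L, 5L), c(5L, 5L))
  out <- gridComparison(ds, grids = grids, channels = "red",
                        thresholds = c(150, 180),
                        models = c("knn", "nn"), split = small)
  expect_equal(nrow(out), 3 * 1 * 2 * 2)
  expect_equal(unique(out$grid), c("4x4", "4x5", "5x5"))
  # feature lengths follow cols + rows
  expect_equal(ncol(featureMatrix(ds, "red", 150, grid = c(4, 5))), 9)
  expect_equal(ncol(featureMatrix(ds, "red", 150, grid = c(5, 5))), 10)
  # single-grid comparison reduces to the plain sweep
  single <- gridComparison(ds, grids = list(c(4L, 4L)), channels = "red",
                           thresholds = 150, models = "knn", split = small)
  plain <- runSweep(ds, channels = "red", thresholds = 150, models = "knn",
                    split = small)
  expect_equal(single[, names(plain)], plain)
})
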