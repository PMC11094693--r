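# tiny configuration used throughout: big enough to learn single-token
# motifs, small enough for second-scale tests
tinyConfig <- function(..., dropout = 0) {
  encoderConfig(layers = 1L, heads = 2L, embeddingDim = 16L, ffnDim = 32L,
                maxLength = 16L, dropout = dropout, learningRate = 3e-3,
                batchSize = 16L, ...)
}

tinyTask <- function(seed = 4, nMolecules = 50) {
  b <- generateBenchmark(fixtureConfig(nClasses = 13, maxDepth = 2,
                                       nLabelClasses = 4,
                                       moleculesPerLabel = c(5, 25),
                                       nMolecules = nMolecules,
                                       fillerLength = c(1L, 2L), seed = seed))
  train <- datasetPartition(b$dataset, "train")
  vocab <- buildVocabulary(lapply(molecules(train)$smiles, tokenizeSmiles))
  list(bench = b, train = train,
       validation = datasetPartition(b$dataset, "validation"),
       test = datasetPartition(b$dataset, "test"), vocab = vocab)
}

test_that("a small encoder overfits a 50-molecule task", {
  tk <- tinyTask(seed = 4, nMolecules = 50)
  # validate on the training set itself: this is a capacity check, and the
  # returned checkpoint should be the best-fitting one
  m <- trainClassifier(tk$train, tk$train, tk$vocab, NULL,
                       tinyConfig(epochs = 200L, seed = 0L))
  preds <- predict(m, molecules(tk$train)$smiles)
  rep <- f1Report(preds, tk$train)
  expect_gte(microF1(rep), 0.95)
})

test_that("training is deterministic: same seed, same loss trajectory", {
  tk <- tinyTask(seed = 6, nMolecules = 40)
  cfg <- tinyConfig(epochs = 4L, seed = 123L, dropout = 0.1)
  m1 <- trainClassifier(tk$train, tk$validation, tk$vocab, NULL, cfg)
  m2 <- trainClassifier(tk$train, tk$validation, tk$vocab, NULL, cfg)
  expect_identical(trainingLog(m1)$trainLoss, trainingLog(m2)$trainLoss)
  expect_identical(m1@params, m2@params)
})

test_that("training loss decreases over the first epochs on the benchmark", {
  tk <- tinyTask(seed = 9, nMolecules = 120)
  m <- trainClassifier(tk$train, tk$validation, tk$vocab, NULL,
                       tinyConfig(epochs = 5L, seed = 2L))
  log <- trainingLog(m)
  expect_identical(nrow(log), 5L)
  expect_lt(log$trainLoss[5], log$trainLoss[1])
})

test_that("a zero-parameter model yields probability one half everywhere", {
  m <- zeroLogitModel(labels = c("L:1", "L:2"))
  p <- predict(m, c("CO", "C"), threshold = 0.5)
  expect_true(all(predictionProbabilities(p) == 0.5))
  # >= rule: at threshold 0.5 all labels predicted, at 0.51 none
  expect_identical(predictedSets(p)[[1]], c("L:1", "L:2"))
  p51 <- predict(m, "CO", threshold = 0.51)
  expect_identical(predictedSets(p51)[[1]], character())
})

test_that("prediction handles empty input and per-item failures without aborting", {
  m <- zeroLogitModel()
  p0 <- predict(m, character())
  expect_length(predictedSets(p0), 0L)

  p <- predict(m, c("CC", "C?C", "OO"))
  expect_identical(itemErrors(p)$index, 2L)
  expect_match(itemErrors(p)$message, "tokenization error")
  expect_true(all(is.na(predictionProbabilities(p)[2, ])))
  expect_false(anyNA(predictionProbabilities(p)[c(1, 3), ]))
  expect_identical(predictedSets(p)[[2]], character())
})

test_that("predicted sets are antitone in the threshold", {
  tk <- tinyTask(seed = 12, nMolecules = 60)
  m <- trainClassifier(tk$train, tk$validation, tk$vocab, NULL,
                       tinyConfig(epochs = 12L, seed = 5L))
  sm <- molecules(tk$test)$smiles
  pLo <- predictedSets(predict(m, sm, threshold = 0.3))
  pMid <- predictedSets(predict(m, sm, threshold = 0.5))
  pHi <- predictedSets(predict(m, sm, threshold = 0.7))
  for (i in seq_along(sm)) {
    expect_true(all(pMid[[i]] %in% pLo[[i]]))
    expect_true(all(pHi[[i]] %in% pMid[[i]]))
  }
})

test_that("inference probabilities do not depend on the batch size", {
  tk <- tinyTask(seed = 3, nMolecules = 60)
  m <- trainClassifier(tk$train, tk$validation, tk$vocab, NULL,
                       tinyConfig(epochs = 3L, seed = 7L))
  sm <- molecules(tk$test)$smiles
  p1 <- predictionProbabilities(predict(m, sm, batchSize = 1L))
  p64 <- predictionProbabilities(predict(m, sm, batchSize = 64L))
  expect_equal(p1, p64, tolerance = 1e-6)
})

test_that("attention maps are normalized distributions of the right shape", {
  tk <- tinyTask(seed = 5, nMolecules = 40)
  m <- trainClassifier(tk$train, tk$validation, tk$vocab, NULL,
                       tinyConfig(epochs = 2L, seed = 9L))
  s <- molecules(tk$test)$smiles[1]
  A <- attentionMaps(m, s)
  Tlen <- length(tokens(tokenizeSmiles(s))) + 1L
  expect_identical(dim(A), c(1L, 2L, Tlen, Tlen))
  for (h in 1:2) {
    expect_equal(unname(rowSums(A[1, h, , ])), rep(1, Tlen), tolerance = 1e-6)
  }
  # deterministic in evaluation mode
  expect_identical(A, attentionMaps(m, s))
})

test_that("models persist to a directory and restore identically", {
  tk <- tinyTask(seed = 2, nMolecules = 40)
  m <- trainClassifier(tk$train, tk$validation, tk$vocab, NULL,
                       tinyConfig(epochs = 2L, seed = 3L))
  dir <- withr::local_tempdir()
  saveModel(m, dir)
  m2 <- loadModel(dir)
  sm <- molecules(tk$test)$smiles
  expect_equal(predictionProbabilities(predict(m2, sm)),
               predictionProbabilities(predict(m, sm)))
  expect_identical(m2@labelOrder, m@labelOrder)
  expect_identical(m2@vocabHash, m@vocabHash)
})

test_that("training rejects empty or misaligned partitions", {
  tk <- tinyTask(seed = 2, nMolecules = 40)
  empty <- tk$train[, FALSE]
  expect_error(trainClassifier(empty, tk$validation, tk$vocab, NULL,
                               tinyConfig(epochs = 1L)),
               "empty training partition")
})
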