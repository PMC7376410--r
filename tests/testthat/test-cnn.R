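test_that("activation functions evaluate the standard closed forms", {
  expect_identical(relu(-2), 0)
  expect_identical(relu(3.5), 3.5)
  expect_identical(relu(0), 0)
  expect_equal(softplus(0), log(2))
  for (x in c(-5, 0, 5)) expect_gt(softplus(x), relu(x))
  expect_lt(abs(softplus(1000) - 1000), 1e-9)   # overflow-safe asymptote
  expect_equal(softplus(-1000), 0)
})

test_that("training validates its inputs", {
  cohort <- generateCohort(2, tinyPhantomConfig(), seed = 1)
  noTruth <- CaseRecord("x", volumes(cohort[[1]]))
  expect_error(trainCNN(list(noTruth), tinyCnnConfig()), "ground truth")
  # a class absent from the training pixels is named
  allBg <- CaseRecord("bg", volumes(cohort[[1]]),
                      truth = LabelMap(array(0L, dim = c(32, 32)), "BRATS"))
  expect_error(trainCNN(list(allBg), tinyCnnConfig(), quiet = TRUE),
               "class.*1")
})

test_that("an untrained model (epochs = 0) refuses to predict", {
  cohort <- generateCohort(1, tinyPhantomConfig(), seed = 2)
  model <- trainCNN(cohort, tinyCnnConfig(epochs = 0L), quiet = TRUE)
  expect_false(isTrained(model))
  expect_error(predictProba(model, cohort[[1]]), "not trained")
})

# one small trained model shared by the remaining blocks
cohortTrain <- generateCohort(3, tinyPhantomConfig(noiseSd = 0.1), seed = 3)
modelShared <- trainCNN(cohortTrain, tinyCnnConfig(epochs = 5L, seed = 4),
                        quiet = TRUE)

test_that("training is seeded and reproducible", {
  again <- trainCNN(cohortTrain, tinyCnnConfig(epochs = 5L, seed = 4),
                    quiet = TRUE)
  expect_equal(modelShared@lossHistory, again@lossHistory, tolerance = 1e-12)
  p1 <- predictProba(modelShared, cohortTrain[[1]])
  p2 <- predictProba(again, cohortTrain[[1]])
  expect_identical(p1, p2)
})

test_that("probabilities normalize and labels are their argmax", {
  probs <- predictProba(modelShared, cohortTrain[[2]])
  sums <- apply(probs, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(probs >= 0))
  labs <- predictLabels(modelShared, cohortTrain[[2]])
  # recompute the argmax independently
  flat <- matrix(probs, ncol = dim(probs)[3])
  want <- apply(flat, 1, which.max) - 1L
  expect_identical(as.vector(imageData(labs)), as.integer(want))
})

test_that("exact probability ties resolve to the lower class index", {
  tie <- array(0.5, dim = c(2, 2, 2))
  expect_true(all(imageData(cascadeSeg:::probaToLabels(tie, 2L)) == 0L))
  sure <- array(rep(c(0.2, 0.8), each = 4), dim = c(2, 2, 2))
  expect_true(all(imageData(cascadeSeg:::probaToLabels(sure, 2L)) == 1L))
})

test_that("a noiseless phantom cohort is learned almost perfectly", {
  cohort <- generateCohort(3, phantomConfig(noiseSd = 0), seed = 5)
  model <- trainCNN(cohort, cnnConfig(epochs = 5L, seed = 6), quiet = TRUE)
  accs <- dscs <- c()
  for (cs in cohort) {
    pred <- predictLabels(model, cs)
    tb <- binarizeWholeTumor(truth(cs))
    accs <- c(accs, mean(imageData(pred) == imageData(tb)))
    dscs <- c(dscs, dsc(confusionCounts(pred, tb)))
  }
  expect_gte(mean(accs), 0.95)   # training pixel accuracy
  expect_gte(mean(dscs), 0.90)   # overlap with the truth
})

test_that("segmentation quality degrades monotonically with noise", {
  meanDsc <- function(noise) {
    cohort <- generateCohort(3, phantomConfig(noiseSd = noise), seed = 7)
    model <- trainCNN(cohort[1:2], cnnConfig(epochs = 5L, seed = 8),
                      quiet = TRUE)
    mean(vapply(cohort, function(cs)
      dsc(confusionCounts(predictLabels(model, cs),
                          binarizeWholeTumor(truth(cs)))), numeric(1)))
  }
  expect_gte(meanDsc(0), meanDsc(0.5))
})
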