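test_that("ROI dilation uses the exact Euclidean disc", {
  empty <- LabelMap(matrix(0L, 7, 7))
  expect_identical(imageData(makeROI(empty, 2)), imageData(empty))
  one <- matrix(0L, 7, 7); one[4, 4] <- 1L
  oneMap <- LabelMap(one)
  expect_identical(imageData(makeROI(oneMap, 0)), one)
  plus <- imageData(makeROI(oneMap, 1))
  expect_identical(sum(plus), 5L)   # radius-1 disc is the plus shape
  expect_identical(plus[4, 4] + plus[3, 4] + plus[5, 4] + plus[4, 3] + plus[4, 5], 5L)
  disc2 <- imageData(makeROI(oneMap, 2))
  expect_identical(sum(disc2), 13L)  # |{di^2+dj^2 <= 4}|
  expect_error(makeROI(oneMap, -1), "nonnegative")
  brats <- LabelMap(matrix(c(0L, 2L), 1, 2), "BRATS")
  expect_error(makeROI(brats, 1), "BINARY")
})

# one small trained pipeline shared across the blocks below
cohortSmall <- generateCohort(5, tinyPhantomConfig(noiseSd = 0.3,
                                                   biasAmplitude = 0.1),
                              seed = 30)
cfgSmall <- tinyCascadeConfig(seed = 31)
modelsSmall <- fitPipeline(cohortSmall[1:4], cfgSmall, quiet = TRUE)
testCase <- cohortSmall[[5]]

test_that("degenerate cascade settings reproduce their identities", {
  cfg0 <- tinyCascadeConfig(seed = 31, maxIterations = 0L)
  res0 <- runCase(modelsSmall$cnn, modelsSmall$svm, testCase, cfg0)
  expect_identical(res0@iterationsRun, 0L)
  expect_identical(imageData(res0@final), imageData(res0@presegmentation))
  # an immediately satisfied convergence test still runs exactly one pass
  cfg1 <- tinyCascadeConfig(seed = 31, convergenceTol = 1.0)
  res1 <- runCase(modelsSmall$cnn, modelsSmall$svm, testCase, cfg1)
  expect_identical(res1@iterationsRun, 1L)
})

test_that("refinement never touches pixels outside the ROI", {
  res <- runCase(modelsSmall$cnn, modelsSmall$svm, testCase, cfgSmall)
  current <- imageData(res@presegmentation)
  for (it in seq_len(res@iterationsRun)) {
    roi <- imageData(makeROI(LabelMap(current), cfgSmall@roiDilation))
    nxt <- imageData(res@refined[[it]])
    expect_true(all(nxt[roi == 0L] == current[roi == 0L]))
    # the recorded change fraction is recomputable from consecutive maps
    expect_equal(res@perIterationChange[it], mean(nxt != current))
    current <- nxt
  }
  expect_lte(res@iterationsRun, cfgSmall@maxIterations)
  expect_identical(imageData(res@final),
                   imageData(res@refined[[res@iterationsRun]]))
})

test_that("the fitted pipeline is deterministic end to end", {
  again <- fitPipeline(cohortSmall[1:4], cfgSmall, quiet = TRUE)
  r1 <- runCase(modelsSmall$cnn, modelsSmall$svm, testCase, cfgSmall)
  r2 <- runCase(again$cnn, again$svm, testCase, cfgSmall)
  expect_identical(imageData(r1@final), imageData(r2@final))
  expect_identical(imageData(r1@presegmentation), imageData(r2@presegmentation))
})

test_that("an SVM trained on CNN labels differs from one trained on truth", {
  # stage 2 consumes the presegmentation label; replacing it with the truth
  # label column must change the learned refinement on a noisy cohort
  cs <- cohortSmall[[1]]
  stack <- cascadeSeg:::buildChannelStack(cs)
  sl <- cascadeSeg:::sliceStack(stack, 1)
  feat <- cascadeSeg:::sliceFeatureMatrix(sl, stack$modalities, cfgSmall@feature)
  tb <- imageData(binarizeWholeTumor(truth(cs)))
  pre <- imageData(predictLabels(modelsSmall$cnn, cs))
  n <- length(tb)
  mk <- function(lab) new("PixelFeatureTable",
                          coords = cbind(row = seq_len(n), col = rep(1L, n)),
                          features = cbind(feat, label = as.numeric(lab)),
                          gridDim = c(as.integer(n), 1L))
  cfgS <- svmEnsembleConfig(nMembers = 2L, maxTrainPixels = 1500L, seed = 5)
  mCnn <- trainEnsemble(mk(pre), as.integer(tb), cfgS)
  mTruth <- trainEnsemble(mk(tb), as.integer(tb), cfgS)
  # the learned decision functions differ (hard labels can coincide at this
  # scale because the two label columns disagree on few pixels)
  probe <- mk(pre)
  scaleRows <- function(m, X) sweep(sweep(X, 2, m@center, "-"), 2, m@scale, "/")
  dvCnn <- rowMeans(sapply(mCnn@members, function(mb)
    cascadeSeg:::memberDecision(mb, scaleRows(mCnn, featureMatrix(probe)))))
  dvTruth <- rowMeans(sapply(mTruth@members, function(mb)
    cascadeSeg:::memberDecision(mb, scaleRows(mTruth, featureMatrix(probe)))))
  expect_false(isTRUE(all.equal(dvCnn, dvTruth)))
})

test_that("cross-validation folds partition the cohort reproducibly", {
  folds <- withr::with_seed(1, {
    reports <- crossValidate(cohortSmall, tinyCascadeConfig(seed = 32),
                             k = 5L, quiet = TRUE)
    attr(reports, "folds")
  })
  expect_identical(sort(unique(folds)), 1:5)          # leave-one-out here
  expect_identical(as.integer(table(folds)), rep(1L, 5))
  again <- crossValidate(cohortSmall, tinyCascadeConfig(seed = 32),
                         k = 5L, quiet = TRUE)
  expect_identical(attr(again, "folds"), folds)
  expect_error(crossValidate(cohortSmall, cfgSmall, k = 6L), "exceeds")
  expect_error(crossValidate(cohortSmall, cfgSmall, k = 1L), ">= 2")
})

test_that("trained models survive the save/load round trip", {
  tmp <- withr::local_tempfile(fileext = ".rds")
  saveModels(modelsSmall, tmp)
  back <- loadModels(tmp)
  r1 <- runCase(modelsSmall$cnn, modelsSmall$svm, testCase, cfgSmall)
  r2 <- runCase(back$cnn, back$svm, testCase, cfgSmall)
  expect_identical(imageData(r1@final), imageData(r2@final))
})
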