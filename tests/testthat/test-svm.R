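# Two well-separated 2-D Gaussian blobs plus a label column, as a feature
# table on a dummy 1-column grid.
blobTable <- function(n = 120, seed = 10) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n / 2, -2, 0.3), rnorm(n / 2, -2, 0.3)),
             cbind(rnorm(n / 2, 2, 0.3), rnorm(n / 2, 2, 0.3)))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(X, label = as.numeric(y))
  tab <- new("PixelFeatureTable",
             coords = cbind(row = seq_len(n), col = rep(1L, n)),
             features = X, gridDim = c(as.integer(n), 1L))
  list(table = tab, y = y)
}

test_that("separable blobs are fit perfectly and deterministically", {
  b <- blobTable()
  cfg <- svmEnsembleConfig(nMembers = 3L, subsample = 0.6, seed = 2)
  m1 <- trainEnsemble(b$table, b$y, cfg)
  pred <- imageData(predictEnsemble(m1, b$table))[, 1]
  expect_identical(as.integer(pred), b$y)   # includes the support points
  m2 <- trainEnsemble(b$table, b$y, cfg)
  expect_identical(imageData(predictEnsemble(m2, b$table)),
                   imageData(predictEnsemble(m1, b$table)))
})

test_that("a 1-member full-sample ensemble equals a single SVM fit", {
  b <- blobTable(seed = 11)
  model <- trainEnsemble(b$table, b$y,
                         svmEnsembleConfig(nMembers = 1L, subsample = 1.0,
                                           seed = 3))
  got <- as.integer(imageData(predictEnsemble(model, b$table))[, 1])
  # reference: one libsvm fit on the identically rescaled rows
  X <- featureMatrix(b$table)
  lo <- apply(X, 2, min); rg <- apply(X, 2, max) - lo
  rg[rg == 0] <- 1
  Xs <- sweep(sweep(X, 2, lo, "-"), 2, rg, "/")
  ref <- e1071::svm(Xs, factor(b$y, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * 0.1^2), cost = 1000, scale = FALSE)
  want <- as.integer(as.character(predict(ref, Xs)))
  expect_identical(got, want)
})

test_that("binary aggregation is the sign of the mean decision value", {
  b <- blobTable(seed = 12)
  model <- trainEnsemble(b$table, b$y,
                         svmEnsembleConfig(nMembers = 3L, subsample = 0.5,
                                           seed = 4))
  X <- featureMatrix(b$table)
  Xs <- sweep(sweep(X, 2, model@center, "-"), 2, model@scale, "/")
  dv <- sapply(model@members, function(mb) cascadeSeg:::memberDecision(mb, Xs))
  want <- ifelse(rowMeans(dv) >= 0, 1L, 0L)
  got <- as.integer(imageData(predictEnsemble(model, b$table))[, 1])
  expect_identical(got, want)
  # permuting the members never changes predictions
  perm <- model
  perm@members <- model@members[c(3, 1, 2)]
  expect_identical(imageData(predictEnsemble(perm, b$table)),
                   imageData(predictEnsemble(model, b$table)))
})

test_that("training and prediction validate their inputs", {
  b <- blobTable(seed = 13)
  expect_error(trainEnsemble(b$table, rep(0L, nrow(featureMatrix(b$table)))),
               "single class")
  empty <- new("PixelFeatureTable",
               coords = matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("row", "col"))),
               features = matrix(numeric(0), 0, 3), gridDim = c(1L, 1L))
  expect_error(trainEnsemble(empty, integer(0)), "empty")
  model <- trainEnsemble(b$table, b$y, svmEnsembleConfig(nMembers = 1L))
  narrow <- new("PixelFeatureTable", coords = pixelCoords(b$table),
                features = featureMatrix(b$table)[, 1:2],
                gridDim = b$table@gridDim)
  expect_error(predictEnsemble(model, narrow), "expected 3, got 2")
})
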