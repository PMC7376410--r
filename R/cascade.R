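#' @include AllClasses.R
NULL

## Three-stage pipeline: CNN presegmentation -> ROI-restricted SVM
## refinement with a confidence-gated CNN veto, iterated to convergence.

discOffsets <- function(radius) {
  r <- as.integer(radius)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off[off$di^2 + off$dj^2 <= r^2, , drop = FALSE]
}

dilateSlice <- function(mask, offsets) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets$di[k]; dj <- offsets$dj[k]
    srcR <- max(1L, 1L - di):min(nr, nr - di)
    srcC <- max(1L, 1L - dj):min(nc, nc - dj)
    out[srcR + di, srcC + dj] <- out[srcR + di, srcC + dj] |
      (mask[srcR, srcC] != 0L)
  }
  out
}

#' Region of interest around a presegmentation
#'
#' Morphological dilation of the foreground by a Euclidean disc of the
#' given radius (offsets \eqn{(di, dj)} with \eqn{di^2 + dj^2 \le r^2});
#' radius 0 returns the foreground unchanged. 3-D maps are dilated slice
#' by slice with the 2-D disc, matching the pipeline's per-slice
#' processing unit.
#'
#' @param preseg a \code{BINARY} [LabelMap-class].
#' @param radius nonnegative integer dilation radius in pixels.
#' @return A \code{BINARY} [LabelMap-class] ROI mask.
#' @examples
#' m <- LabelMap(matrix(c(rep(0, 12), 1, rep(0, 12)), 5, 5))
#' sum(imageData(makeROI(m, 1)))  # 5-pixel plus shape
#' @export
makeROI <- function(preseg, radius) {
  stopifnot(is(preseg, "LabelMap"))
  if (preseg@scheme != "BINARY")
    stop("presegmentation must use the BINARY scheme", call. = FALSE)
  if (length(radius) != 1L || !is.finite(radius) || radius < 0)
    stop("radius must be a nonnegative integer", call. = FALSE)
  if (radius == 0) return(preseg)
  offs <- discOffsets(radius)
  dm <- dim(preseg@data)
  if (length(dm) == 2L) {
    roi <- dilateSlice(preseg@data, offs)
  } else {
    roi <- array(FALSE, dim = dm)
    for (s in seq_len(dm[3L])) roi[, , s] <- dilateSlice(preseg@data[, , s], offs)
  }
  LabelMap(array(as.integer(roi), dim = dm), scheme = "BINARY")
}

# Full-image SVM feature matrix for one 2-D channel stack, rows in
# column-major (linear-index) pixel order; columns are the per-modality
# (gray, mean, median) triplets in canonical modality order.
sliceFeatureMatrix <- function(slice, mods, featureCfg) {
  C <- dim(slice)[3L]
  cols <- vector("list", C)
  for (ch in seq_len(C)) {
    # slices of the stack are already normalized; features on raw values
    vol <- ImageVolume(slice[, , ch], modality = mods[ch])
    tab <- pixelFeatures(vol, featureConfig(window = featureCfg@window,
                                            normalize = FALSE))
    f <- tab@features
    f <- f[order(coordsToLinear(tab@coords, dim(slice)[1:2])), , drop = FALSE]
    colnames(f) <- paste(tolower(mods[ch]), colnames(f), sep = "_")
    cols[[ch]] <- f
  }
  do.call(cbind, cols)
}

# Core of the iterative refinement for one 2-D slice. Returns the label
# history and change fractions.
refineSlice <- function(modelCnn, modelSvm, slice, mods, config, preseg) {
  labels <- preseg
  refined <- list()
  changes <- numeric(0)
  if (config@maxIterations == 0L)
    return(list(refined = refined, changes = changes, final = labels))
  feat <- sliceFeatureMatrix(slice, mods, config@feature)
  for (it in seq_len(config@maxIterations)) {
    roi <- makeROI(LabelMap(labels, scheme = "BINARY"), config@roiDilation)
    roiIdx <- which(roi@data != 0L)
    newLabels <- labels
    if (length(roiIdx) > 0L) {
      X <- cbind(feat[roiIdx, , drop = FALSE], label = as.numeric(labels[roiIdx]))
      svmLab <- ensemblePredictRows(modelSvm, X)
      newLabels[roiIdx] <- as.integer(svmLab)
      # CNN re-scores the ROI; its argmax overrides where it is confident
      rr <- ((roiIdx - 1L) %% nrow(slice[, , 1L])) + 1L
      cc <- ((roiIdx - 1L) %/% nrow(slice[, , 1L])) + 1L
      probs <- cnnPredictPixels(modelCnn, slice, rr, cc)
      conf <- apply(probs, 1L, max)
      cls <- max.col(probs, ties.method = "first") - 1L
      veto <- conf >= config@cnnVetoThreshold
      newLabels[roiIdx[veto]] <- cls[veto]
    }
    change <- mean(newLabels != labels)
    labels <- newLabels
    refined[[it]] <- labels
    changes <- c(changes, change)
    if (change < config@convergenceTol) break
  }
  list(refined = refined, changes = changes, final = labels)
}

#' Segment one case with the trained cascade
#'
#' Stage 1: the convolutional classifier labels every pixel (the
#' presegmentation). Stage 2/3, iterated: the current map is dilated into
#' a region of interest (ROI); inside it the SVM ensemble re-classifies
#' each pixel from its feature triplets plus the current label, then the
#' network re-scores the ROI and its argmax overrides the SVM wherever its
#' maximum class probability reaches \code{cnnVetoThreshold}. Pixels
#' outside the ROI are never modified. Iteration stops when the fraction
#' of pixels changing (measured on the whole image) drops below
#' \code{convergenceTol} or after \code{maxIterations}. 3-D volumes are
#' processed slice by slice and restacked.
#'
#' @param modelCnn a trained [CNNModel-class].
#' @param modelSvm a trained [SVMEnsembleModel-class].
#' @param image a [CaseRecord-class], [ImageVolume-class] or list of
#'   volumes.
#' @param config a [CascadeConfig-class].
#' @return A [CascadeResult-class] holding the presegmentation, every
#'   intermediate map, the final map, and the per-iteration change
#'   fractions.
#' @export
runCase <- function(modelCnn, modelSvm, image, config = cascadeConfig()) {
  stopifnot(is(modelCnn, "CNNModel"), is(modelSvm, "SVMEnsembleModel"),
            is(config, "CascadeConfig"))
  validObject(config)
  if (!isTRUE(modelCnn@trained))
    stop("the CNN model is not trained", call. = FALSE)
  stack <- buildChannelStack(image)
  checkPredictable(modelCnn, stack)
  dm <- stack$dim
  nSlices <- if (length(dm) == 2L) 1L else dm[3L]
  coords <- rowMajorCoords(dm[1:2])

  presegArr <- array(0L, dim = dm)
  sliceResults <- vector("list", nSlices)
  for (s in seq_len(nSlices)) {
    sl <- sliceStack(stack, s)
    probs <- cnnPredictPixels(modelCnn, sl, coords[, 1L], coords[, 2L])
    cls <- max.col(probs, ties.method = "first") - 1L
    pre <- array(0L, dim = dm[1:2])
    pre[cbind(coords[, 1L], coords[, 2L])] <- as.integer(cls)
    if (length(dm) == 2L) presegArr <- pre else presegArr[, , s] <- pre
    sliceResults[[s]] <- refineSlice(modelCnn, modelSvm, sl, stack$modalities,
                                     config, pre)
  }

  nIter <- max(0L, vapply(sliceResults, function(r) length(r$refined), integer(1L)))
  refined <- vector("list", nIter)
  changes <- numeric(nIter)
  for (it in seq_len(nIter)) {
    arr <- array(0L, dim = dm)
    for (s in seq_len(nSlices)) {
      r <- sliceResults[[s]]
      m <- if (length(r$refined) >= it) r$refined[[it]] else r$final
      if (length(dm) == 2L) arr <- m else arr[, , s] <- m
    }
    prev <- if (it == 1L) presegArr else refined[[it - 1L]]@data
    refined[[it]] <- LabelMap(arr, scheme = "BINARY")
    changes[it] <- mean(arr != prev)
  }
  finalMap <- if (nIter > 0L) refined[[nIter]] else LabelMap(presegArr, "BINARY")
  new("CascadeResult", presegmentation = LabelMap(presegArr, "BINARY"),
      refined = refined, final = finalMap, iterationsRun = as.integer(nIter),
      perIterationChange = changes)
}

#' Train both cascade stages end to end
#'
#' Stage 1 trains the convolutional classifier on the training cases.
#' Stage 2 computes each training case's presegmentation with that
#' network, builds the per-pixel feature tables augmented with the
#' presegmentation label, pools a class-balanced seeded sample of rows
#' over the cases, and trains the SVM ensemble against the ground truth.
#'
#' @param trainCases list of [CaseRecord-class] objects with ground truth.
#' @param config a [CascadeConfig-class].
#' @param quiet suppress training progress messages.
#' @return List with elements \code{cnn} ([CNNModel-class]) and \code{svm}
#'   ([SVMEnsembleModel-class]).
#' @export
fitPipeline <- function(trainCases, config = cascadeConfig(), quiet = FALSE) {
  stopifnot(length(trainCases) >= 1L, is(config, "CascadeConfig"))
  validObject(config)
  cnn <- trainCNN(trainCases, config@cnn, quiet = quiet)
  Xs <- list(); ys <- list()
  for (cs in trainCases) {
    stack <- buildChannelStack(cs)
    dm <- stack$dim
    nSlices <- if (length(dm) == 2L) 1L else dm[3L]
    coords <- rowMajorCoords(dm[1:2])
    truthBin <- binarizeWholeTumor(cs@truth)@data
    for (s in seq_len(nSlices)) {
      sl <- sliceStack(stack, s)
      probs <- cnnPredictPixels(cnn, sl, coords[, 1L], coords[, 2L])
      cls <- max.col(probs, ties.method = "first") - 1L
      pre <- array(0L, dim = dm[1:2])
      pre[cbind(coords[, 1L], coords[, 2L])] <- as.integer(cls)
      feat <- sliceFeatureMatrix(sl, stack$modalities, config@feature)
      X <- cbind(feat, label = as.numeric(pre))
      y <- if (length(dm) == 2L) truthBin else truthBin[, , s]
      # train the refinement stage on the pixels it will see at test time:
      # the dilated neighborhood of the presegmentation
      roi <- makeROI(LabelMap(pre, "BINARY"), config@roiDilation)
      keep <- which(roi@data != 0L)
      if (length(keep) == 0L) keep <- seq_along(y)
      Xs[[length(Xs) + 1L]] <- X[keep, , drop = FALSE]
      ys[[length(ys) + 1L]] <- as.integer(y)[keep]
    }
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  # seeded cap on the pooled ROI rows, preserving their natural class mix
  rows <- withSeed(config@seed, {
    cap <- 2L * config@svm@maxTrainPixels
    if (length(y) > cap) sort(sample(length(y), cap)) else seq_along(y)
  })
  dmDummy <- c(length(rows), 1L)
  table <- new("PixelFeatureTable",
               coords = cbind(row = seq_along(rows), col = rep(1L, length(rows))),
               features = X[rows, , drop = FALSE],
               gridDim = as.integer(dmDummy))
  svm <- trainEnsemble(table, y[rows], config@svm)
  list(cnn = cnn, svm = svm)
}

#' Case-level k-fold cross-validation of the cascade
#'
#' Splits the cohort into \code{k} seeded folds, trains the full pipeline
#' on each training split, segments the held-out cases, and reports
#' per-fold cohort metrics. Folds partition the cohort exactly and the
#' assignment is reproducible for a given config seed.
#'
#' @param cases list of [CaseRecord-class] objects with ground truth.
#' @param config a [CascadeConfig-class].
#' @param k number of folds (2 <= k <= number of cases).
#' @param quiet suppress progress messages.
#' @return List of [MetricReport-class], one per fold, with the fold
#'   assignment attached as \code{attr(, "folds")}.
#' @export
crossValidate <- function(cases, config = cascadeConfig(), k = 3L, quiet = FALSE) {
  n <- length(cases)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("k (%d) exceeds the number of cases (%d)", k, n),
                  call. = FALSE)
  folds <- withSeed(config@seed, sample(rep(seq_len(k), length.out = n)))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    trainIdx <- which(folds != f)
    testIdx <- which(folds == f)
    models <- fitPipeline(cases[trainIdx], config, quiet = quiet)
    rows <- lapply(testIdx, function(i) {
      res <- runCase(models$cnn, models$svm, cases[[i]], config)
      counts <- confusionCounts(res@final, binarizeWholeTumor(cases[[i]]@truth))
      data.frame(case_id = cases[[i]]@caseId, dsc = dsc(counts),
                 sensitivity = sensitivity(counts),
                 specificity = specificity(counts))
    })
    reports[[f]] <- cohortReport(do.call(rbind, rows))
  }
  attr(reports, "folds") <- folds
  reports
}

#' Save trained cascade models to a single file
#'
#' @param models list with \code{cnn} and \code{svm} as returned by
#'   [fitPipeline()].
#' @param path destination file (RDS container).
#' @return Invisibly, \code{path}.
#' @export
saveModels <- function(models, path) {
  stopifnot(is(models$cnn, "CNNModel"), is(models$svm, "SVMEnsembleModel"))
  saveRDS(models, path)
  invisible(path)
}

#' Load cascade models saved by [saveModels()]
#'
#' @param path file written by [saveModels()].
#' @return List with \code{cnn} and \code{svm}.
#' @export
loadModels <- function(path) {
  models <- readRDS(path)
  stopifnot(is(models$cnn, "CNNModel"), is(models$svm, "SVMEnsembleModel"))
  models
}
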