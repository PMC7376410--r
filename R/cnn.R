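#' @include AllClasses.R cnn-net.R
NULL

#' Rectified linear unit
#'
#' \eqn{f(x) = max(0, x)}, the standard convolutional-layer activation.
#'
#' @param x numeric vector of finite values.
#' @return \code{pmax(x, 0)}.
#' @export
relu <- function(x) pmax(x, 0)

#' Softplus activation
#'
#' \eqn{f(x) = log(1 + e^x)}, evaluated overflow-safely as
#' \eqn{max(x, 0) + log(1 + e^{-|x|})} so large arguments return their
#' asymptote instead of \code{Inf}.
#'
#' @param x numeric vector of finite values.
#' @return Softplus of \code{x}.
#' @examples
#' softplus(0)     # log(2)
#' softplus(1000)  # 1000, no overflow
#' @export
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## Channel stacks ------------------------------------------------------------

# Normalize each modality and stack as channels: H x W x C (2-D input) or
# H x W x D x C (3-D input). Accepts a CaseRecord, ImageVolume, or a list
# of ImageVolumes; modalities are ordered canonically (T1, T1CE, T2, FLAIR).
buildChannelStack <- function(image, normalize = TRUE) {
  vols <- if (is(image, "CaseRecord")) image@volumes
  else if (is(image, "ImageVolume")) list(image)
  else if (is.list(image)) image
  else stop("image must be a CaseRecord, ImageVolume, or list of ImageVolumes",
            call. = FALSE)
  if (normalize) vols <- lapply(vols, normalizeIntensity)
  dm <- dim(vols[[1L]]@data)
  arr <- array(0, dim = c(dm, length(vols)))
  if (length(dm) == 2L) {
    for (i in seq_along(vols)) arr[, , i] <- vols[[i]]@data
  } else {
    for (i in seq_along(vols)) arr[, , , i] <- vols[[i]]@data
  }
  mods <- vapply(vols, function(v) v@modality, character(1L))
  list(data = arr, dim = dm, modalities = mods)
}

# Per-slice channel stack as H x W x C.
sliceStack <- function(stack, s) {
  dm <- stack$dim
  if (length(dm) == 2L) return(stack$data)
  stack$data[, , s, , drop = TRUE] |> array(dim = c(dm[1L], dm[2L],
                                                    dim(stack$data)[4L]))
}

# Class targets on the grid: binary whole tumor, or BraTS codes remapped to
# consecutive classes 0..3 when nClasses > 2.
truthTargets <- function(tr, nClasses) {
  if (nClasses == 2L) {
    binarizeWholeTumor(tr)@data
  } else {
    map <- c(`0` = 0L, `1` = 1L, `2` = 2L, `4` = 3L)
    array(map[as.character(tr@data)], dim = dim(tr@data))
  }
}

#' Train the convolutional pixel classifier
#'
#' Trains a small LeNet-style network on square intensity patches centered
#' on a class-balanced, seeded sample of pixels pooled over the training
#' cases (per case, all tumor pixels up to \code{pixelsPerClass} and an
#' equal number of background pixels). Intensities are standardized over
#' nonzero pixels per modality before patch extraction. Training is fully
#' deterministic given (data, config, seed); the mean cross-entropy per
#' epoch is recorded in the returned model and logged.
#'
#' @param cases list of [CaseRecord-class] objects, all with ground truth
#'   and the same modality set.
#' @param config a [CNNConfig-class]; with \code{epochs = 0} the returned
#'   model is flagged untrained and prediction refuses to run.
#' @param quiet suppress per-epoch loss messages.
#' @return A [CNNModel-class].
#' @seealso [predictProba()], [predictLabels()]
#' @export
trainCNN <- function(cases, config = cnnConfig(), quiet = FALSE) {
  stopifnot(length(cases) >= 1L, is(config, "CNNConfig"))
  validObject(config)
  if (!all(vapply(cases, function(cs) !is.null(cs@truth), logical(1L))))
    stop("every training case must carry ground truth", call. = FALSE)
  stacks <- lapply(cases, buildChannelStack)
  mods <- stacks[[1L]]$modalities
  if (!all(vapply(stacks, function(s) identical(s$modalities, mods), logical(1L))))
    stop("all training cases must share one modality set", call. = FALSE)
  channels <- length(mods)

  withSeed(config@seed, {
    # class-balanced pixel sampling, pooled over cases
    Xs <- list(); ys <- list()
    for (ci in seq_along(cases)) {
      targ <- truthTargets(cases[[ci]]@truth, config@nClasses)
      dm <- stacks[[ci]]$dim
      nSlices <- if (length(dm) == 2L) 1L else dm[3L]
      for (s in seq_len(nSlices)) {
        sl <- sliceStack(stacks[[ci]], s)
        tg <- if (length(dm) == 2L) targ else targ[, , s]
        picked <- integer(0)
        fg <- which(tg != 0L)
        if (length(fg) > config@pixelsPerClass)
          fg <- sort(sample(fg, config@pixelsPerClass))
        bg <- which(tg == 0L)
        nbg <- min(length(bg), max(length(fg), 1L))
        if (length(bg) > nbg) bg <- sort(sample(bg, nbg))
        picked <- c(fg, bg)
        if (length(picked) == 0L) next
        rr <- ((picked - 1L) %% dm[1L]) + 1L
        cc <- ((picked - 1L) %/% dm[1L]) + 1L
        Xs[[length(Xs) + 1L]] <- extractPatches(sl, rr, cc, config@patchSize)
        ys[[length(ys) + 1L]] <- as.integer(tg[picked])
      }
    }
    X <- do.call(rbind, Xs)
    y <- unlist(ys)
    present <- sort(unique(y))
    missing <- setdiff(0:(config@nClasses - 1L), present)
    if (length(missing))
      stop("class(es) absent from the training pixels: ",
           paste(missing, collapse = ", "), call. = FALSE)

    params <- netInit(config, channels)
    lossHistory <- numeric(0)
    trained <- FALSE
    if (config@epochs > 0L) {
      vel <- netZeroVel(params)
      y1hot <- matrix(0, length(y), config@nClasses)
      y1hot[cbind(seq_along(y), y + 1L)] <- 1
      for (ep in seq_len(config@epochs)) {
        ord <- sample.int(nrow(X))
        r <- netEpoch(params, vel, config, X, y1hot, ord)
        params <- r$params; vel <- r$vel
        lossHistory <- c(lossHistory, r$loss)
        if (!quiet)
          message(sprintf("epoch %d/%d: cross-entropy %.4f", ep,
                          config@epochs, r$loss))
      }
      trained <- TRUE
    }
    new("CNNModel", config = config, params = params, trained = trained,
        channels = as.integer(channels), modalities = mods,
        lossHistory = lossHistory)
  })
}

# Forward-only prediction for explicit pixels of a 2-D channel stack.
cnnPredictPixels <- function(model, slice, rows, cols, chunk = 1024L) {
  n <- length(rows)
  probs <- matrix(0, n, model@config@nClasses)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    X <- extractPatches(slice, rows[sel], cols[sel], model@config@patchSize)
    probs[sel, ] <- netForward(model@params, model@config, X)$probs
  }
  probs
}

checkPredictable <- function(model, stack) {
  if (!isTRUE(model@trained))
    stop("model is not trained (epochs = 0?); refusing to predict",
         call. = FALSE)
  C <- dim(stack$data)[length(dim(stack$data))]
  if (C != model@channels)
    stop(sprintf("model expects %d channel(s) but the input has %d",
                 model@channels, C), call. = FALSE)
}

#' Per-pixel class probabilities from the convolutional classifier
#'
#' Runs the softmax classifier over a patch centered on every pixel
#' (reflect padding at borders; 3-D volumes are processed slice by slice).
#' Probabilities at each pixel are nonnegative and sum to one.
#'
#' @param model a trained [CNNModel-class].
#' @param image a [CaseRecord-class], [ImageVolume-class], or list of
#'   [ImageVolume-class] matching the model's channel count.
#' @return Array of probabilities: \code{H x W x nClasses} for 2-D input,
#'   \code{H x W x D x nClasses} for 3-D.
#' @export
predictProba <- function(model, image) {
  stopifnot(is(model, "CNNModel"))
  stack <- buildChannelStack(image)
  checkPredictable(model, stack)
  dm <- stack$dim
  K <- model@config@nClasses
  coords <- rowMajorCoords(dm[1:2])
  if (length(dm) == 2L) {
    p <- cnnPredictPixels(model, sliceStack(stack, 1L), coords[, 1L], coords[, 2L])
    out <- array(0, dim = c(dm, K))
    for (k in seq_len(K)) out[cbind(coords, k)] <- p[, k]
    out
  } else {
    out <- array(0, dim = c(dm, K))
    for (s in seq_len(dm[3L])) {
      p <- cnnPredictPixels(model, sliceStack(stack, s), coords[, 1L], coords[, 2L])
      for (k in seq_len(K)) out[cbind(coords[, 1L], coords[, 2L], s, k)] <- p[, k]
    }
    out
  }
}

probaToLabels <- function(probs, nClasses) {
  dm <- dim(probs)
  K <- dm[length(dm)]
  flat <- matrix(probs, ncol = K)
  cls <- max.col(flat, ties.method = "first") - 1L   # ties -> lower class
  gridDim <- dm[-length(dm)]
  if (nClasses == 2L) {
    LabelMap(array(cls, dim = gridDim), scheme = "BINARY")
  } else {
    codes <- c(0L, 1L, 2L, 4L)
    LabelMap(array(codes[cls + 1L], dim = gridDim), scheme = "BRATS")
  }
}

#' Hard label map from the convolutional classifier
#'
#' The argmax of [predictProba()] at every pixel; exact probability ties
#' break toward the lower class index (background first).
#'
#' @inheritParams predictProba
#' @return A [LabelMap-class] (\code{BINARY} for 2 classes, \code{BRATS}
#'   codes otherwise).
#' @export
predictLabels <- function(model, image) {
  probaToLabels(predictProba(model, image), model@config@nClasses)
}
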