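#' @include AllClasses.R
NULL

## Bagged ensemble of RBF-kernel SVMs refining the presegmentation.

# Fit one member on the given standardized rows. Binary members record the
# sign convention that makes positive decision values mean the higher
# (tumor) class.
fitMember <- function(X, y, config, classLevels) {
  fit <- e1071::svm(x = X, y = factor(y, levels = classLevels),
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * config@sigma^2), cost = config@C,
                    scale = FALSE)
  flip <- 1
  if (length(classLevels) == 2L) {
    pr <- stats::predict(fit, X[1L, , drop = FALSE], decision.values = TRUE)
    cn <- colnames(attr(pr, "decision.values"))
    # libsvm's positive side is the class named first in "A/B"
    first <- strsplit(cn, "/", fixed = TRUE)[[1L]][1L]
    flip <- if (identical(first, as.character(classLevels[2L]))) 1 else -1
  }
  list(fit = fit, flip = flip)
}

memberDecision <- function(member, X) {
  pr <- stats::predict(member$fit, X, decision.values = TRUE)
  member$flip * as.numeric(attr(pr, "decision.values"))
}

#' Train the bagged RBF-SVM refinement ensemble
#'
#' Each of the \code{nMembers} members is an RBF-kernel SVM
#' (\eqn{k(u, v) = exp(-||u - v||^2 / (2\sigma^2))}, penalty \eqn{C})
#' trained on an independent seeded subsample of the feature rows, capped
#' at \code{maxTrainPixels} rows per member. With \code{subsample = 1}
#' every row is used exactly once (so a 1-member ensemble equals a single
#' SVM fit); fractions below 1 draw bootstrap samples. Each feature column
#' is rescaled to [0, 1] over the full training table — the compact scale
#' on which the narrow default kernel width (\eqn{\sigma = 0.1}) is
#' meaningful — and the rescaling is stored with the model and replayed at
#' prediction time.
#'
#' @param table a [PixelFeatureTable-class], normally carrying the
#'   presegmentation \code{label} column from [augmentWithLabels()].
#' @param targets integer class value per table row (e.g. the binary
#'   ground-truth label); at least two classes must be present.
#' @param config an [SVMEnsembleConfig-class].
#' @return An [SVMEnsembleModel-class].
#' @export
trainEnsemble <- function(table, targets, config = svmEnsembleConfig()) {
  stopifnot(is(table, "PixelFeatureTable"), is(config, "SVMEnsembleConfig"))
  validObject(config)
  X <- table@features
  if (nrow(X) == 0L) stop("empty feature table", call. = FALSE)
  if (!all(is.finite(X))) stop("feature rows must be finite", call. = FALSE)
  targets <- as.integer(targets)
  if (length(targets) != nrow(X))
    stop("one target per feature row is required", call. = FALSE)
  classLevels <- sort(unique(targets))
  if (length(classLevels) < 2L)
    stop("targets contain a single class; both classes must be present",
         call. = FALSE)
  # rescale each column to [0, 1]; constant columns map to 0
  center <- apply(X, 2L, min)
  scl <- apply(X, 2L, max) - center
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scl, "/")
  n <- nrow(Xs)
  withSeed(config@seed, {
    members <- vector("list", config@nMembers)
    for (m in seq_len(config@nMembers)) {
      if (config@subsample >= 1) {
        rows <- seq_len(n)
        if (n > config@maxTrainPixels)
          rows <- sort(sample(rows, config@maxTrainPixels))
      } else {
        size <- min(ceiling(config@subsample * n), config@maxTrainPixels)
        repeat {
          rows <- sample(n, size, replace = TRUE)
          if (length(unique(targets[rows])) >= 2L) break
        }
      }
      members[[m]] <- fitMember(Xs[rows, , drop = FALSE], targets[rows],
                                config, classLevels)
    }
    new("SVMEnsembleModel", members = members, config = config,
        center = center, scale = scl,
        featureNames = colnames(X) %||% paste0("f", seq_len(ncol(X))),
        classLevels = as.integer(classLevels))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Predict class values for raw (unstandardized) feature rows.
ensemblePredictRows <- function(model, X) {
  if (ncol(X) != length(model@featureNames))
    stop(sprintf("feature dimension mismatch: expected %d, got %d",
                 length(model@featureNames), ncol(X)), call. = FALSE)
  Xs <- sweep(sweep(X, 2L, model@center, "-"), 2L, model@scale, "/")
  if (length(model@classLevels) == 2L) {
    dvm <- vapply(model@members, function(mb) memberDecision(mb, Xs),
                  numeric(nrow(Xs)))
    dv <- rowMeans(matrix(dvm, nrow = nrow(Xs)))
    # exact zero counts as tumor (the higher class)
    ifelse(dv >= 0, model@classLevels[2L], model@classLevels[1L])
  } else {
    votes <- vapply(model@members, function(mb)
      as.integer(as.character(stats::predict(mb$fit, Xs))),
      integer(nrow(Xs)))
    votes <- matrix(votes, nrow = nrow(Xs))
    apply(votes, 1L, function(v) {
      tab <- table(v)
      as.integer(names(tab)[which.max(tab)])  # ties -> lowest class value
    })
  }
}

#' Predict a label map with the SVM ensemble
#'
#' Binary predictions aggregate members by the sign of the mean decision
#' value (an exact zero counts as tumor); with more than two classes each
#' member votes and ties break toward the lowest class value. Pixels not
#' covered by the table are 0 in the returned map.
#'
#' @param model an [SVMEnsembleModel-class].
#' @param table a [PixelFeatureTable-class] whose feature columns match the
#'   training layout (including the presegmentation \code{label} column).
#' @return A [LabelMap-class] on the table's source grid.
#' @export
predictEnsemble <- function(model, table) {
  stopifnot(is(model, "SVMEnsembleModel"), is(table, "PixelFeatureTable"))
  pred <- ensemblePredictRows(model, table@features)
  out <- array(0L, dim = table@gridDim)
  out[coordsToLinear(table@coords, table@gridDim)] <- as.integer(pred)
  scheme <- if (all(model@classLevels %in% c(0L, 1L))) "BINARY" else "BRATS"
  LabelMap(out, scheme = scheme)
}
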