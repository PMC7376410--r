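#' @include AllGenerics.R
NULL

MODALITIES <- c("T1", "T1CE", "T2", "FLAIR", "UNKNOWN")
LABEL_SCHEMES <- c("BRATS", "BINARY")
BRATS_CODES <- c(0L, 1L, 2L, 4L)
PHANTOM_REGIONS <- c("NCR", "ET", "NET", "ED")

## ---------------------------------------------------------------------------
## Core image containers
## ---------------------------------------------------------------------------

#' ImageVolume: a scalar intensity grid with modality and spacing
#'
#' A 2-D (\code{H x W}) or 3-D (\code{H x W x D}) array of finite intensities
#' in arbitrary units, tagged with the MRI modality it was acquired with and
#' the physical voxel spacing. Axis order is (row, column[, slice]) and
#' indexing is 1-based throughout the package.
#'
#' @slot data numeric array, all values finite.
#' @slot modality one of \code{"T1"}, \code{"T1CE"}, \code{"T2"},
#'   \code{"FLAIR"}, \code{"UNKNOWN"}.
#' @slot spacing numeric vector of voxel sizes in mm, one per axis.
#' @export
setClass("ImageVolume",
  representation(data = "array", modality = "character", spacing = "numeric"))

setValidity("ImageVolume", function(object) {
  d <- object@data
  if (!(length(dim(d)) %in% c(2L, 3L))) return("data must be a 2-D or 3-D array")
  if (any(dim(d) < 1L)) return("all axes must have length >= 1")
  if (!all(is.finite(d))) return("all intensities must be finite")
  if (length(object@modality) != 1L || !object@modality %in% MODALITIES)
    return(sprintf("modality must be one of %s", paste(MODALITIES, collapse = ", ")))
  if (length(object@spacing) != length(dim(d)) || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be positive and match the number of axes")
  TRUE
})

#' Construct an ImageVolume
#'
#' @param data numeric matrix or 2-D/3-D array of finite intensities.
#' @param modality modality tag; defaults to \code{"UNKNOWN"}.
#' @param spacing voxel spacing in mm per axis; defaults to 1 on each axis.
#' @return An [ImageVolume-class].
#' @examples
#' vol <- ImageVolume(matrix(rnorm(16), 4, 4), modality = "FLAIR")
#' dim(imageData(vol))
#' @export
ImageVolume <- function(data, modality = "UNKNOWN", spacing = NULL) {
  data <- as.array(data)
  if (is.null(spacing)) spacing <- rep(1, length(dim(data)))
  new("ImageVolume", data = data, modality = toupper(modality), spacing = spacing)
}

#' LabelMap: an integer label grid
#'
#' Integer labels aligned voxel-for-voxel with an [ImageVolume-class].
#' The \code{"BRATS"} scheme uses the challenge codes 0 (background),
#' 1 (necrotic / non-enhancing tumor core), 2 (peritumoral edema) and
#' 4 (enhancing tumor core); the \code{"BINARY"} scheme uses 0/1
#' (background / whole tumor).
#'
#' @slot data integer-valued array.
#' @slot scheme \code{"BRATS"} or \code{"BINARY"}.
#' @export
setClass("LabelMap", representation(data = "array", scheme = "character"))

setValidity("LabelMap", function(object) {
  d <- object@data
  if (!(length(dim(d)) %in% c(2L, 3L))) return("data must be a 2-D or 3-D array")
  if (!isWholeNumber(d)) return("labels must be integer-valued and finite")
  if (length(object@scheme) != 1L || !object@scheme %in% LABEL_SCHEMES)
    return("scheme must be 'BRATS' or 'BINARY'")
  vals <- unique(as.integer(round(d)))
  allowed <- if (object@scheme == "BRATS") BRATS_CODES else c(0L, 1L)
  bad <- setdiff(vals, allowed)
  if (length(bad))
    return(sprintf("scheme %s does not allow label code(s): %s",
                   object@scheme, paste(sort(bad), collapse = ", ")))
  TRUE
})

#' Construct a LabelMap
#'
#' @param data integer-valued matrix or array.
#' @param scheme \code{"BRATS"} (codes 0/1/2/4) or \code{"BINARY"} (0/1).
#' @return A [LabelMap-class].
#' @examples
#' lm <- LabelMap(matrix(c(0, 1, 2, 4), 2, 2), scheme = "BRATS")
#' labelScheme(lm)
#' @export
LabelMap <- function(data, scheme = c("BINARY", "BRATS")) {
  scheme <- match.arg(toupper(scheme[1L]), LABEL_SCHEMES)
  data <- as.array(data)
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, scheme = scheme)
}

#' CaseRecord: one subject's volumes plus optional ground truth
#'
#' @slot caseId character identifier.
#' @slot volumes named list of [ImageVolume-class], keyed by modality.
#' @slot truth a [LabelMap-class] aligned with the volumes, or \code{NULL}.
#' @export
setClass("CaseRecord",
  representation(caseId = "character", volumes = "list", truth = "ANY"))

setValidity("CaseRecord", function(object) {
  if (length(object@caseId) != 1L || !nzchar(object@caseId))
    return("caseId must be a non-empty string")
  if (length(object@volumes) < 1L) return("at least one volume is required")
  if (!all(vapply(object@volumes, is, logical(1L), "ImageVolume")))
    return("volumes must all be ImageVolume objects")
  dims <- lapply(object@volumes, function(v) dim(v@data))
  if (length(unique(dims)) != 1L) return("all volumes must share one shape")
  if (is.null(names(object@volumes)) ||
      !identical(unname(names(object@volumes)),
                 unname(vapply(object@volumes, function(v) v@modality, character(1L)))))
    return("volumes must be named by their modality tags")
  if (!is.null(object@truth)) {
    if (!is(object@truth, "LabelMap")) return("truth must be a LabelMap or NULL")
    if (!identical(dim(object@truth@data), dims[[1L]]))
      return("truth shape must match the volumes")
  }
  TRUE
})

#' Construct a CaseRecord
#'
#' @param caseId character identifier.
#' @param volumes list of [ImageVolume-class]; names are taken from each
#'   volume's modality tag.
#' @param truth optional [LabelMap-class] with the same shape.
#' @return A [CaseRecord-class].
#' @export
CaseRecord <- function(caseId, volumes, truth = NULL) {
  names(volumes) <- vapply(volumes, function(v) v@modality, character(1L))
  volumes <- volumes[orderModalities(names(volumes))]
  new("CaseRecord", caseId = as.character(caseId), volumes = volumes, truth = truth)
}

## ---------------------------------------------------------------------------
## Feature table
## ---------------------------------------------------------------------------

#' PixelFeatureTable: per-pixel feature rows
#'
#' One row per pixel of a source grid, in row-major scan order (columns vary
#' fastest within a row; for 3-D sources, slices vary slowest). The feature
#' columns are, per modality, the pixel's grayscale value, the mean of its
#' square window neighborhood, and the window median; [augmentWithLabels()]
#' appends presegmentation label columns.
#'
#' @slot coords integer matrix with columns \code{row}, \code{col}
#'   (and \code{slice} for 3-D sources).
#' @slot features numeric matrix, one row per coordinate, finite values.
#' @slot gridDim integer dimensions of the source grid.
#' @export
setClass("PixelFeatureTable",
  representation(coords = "matrix", features = "matrix", gridDim = "integer"))

setValidity("PixelFeatureTable", function(object) {
  if (nrow(object@coords) != nrow(object@features))
    return("one feature row per coordinate is required")
  if (ncol(object@coords) != length(object@gridDim))
    return("coordinate columns must match the grid dimensionality")
  if (!all(is.finite(object@features))) return("all feature values must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' PhantomConfig: parameters of the synthetic glioma phantom
#'
#' Describes a concentric-ellipsoid glioma embedded in a smooth brain
#' ellipse: necrotic core (NCR) inside enhancing core (ET) inside
#' non-enhancing core (NET) inside peritumoral edema (ED), imaged in four
#' modalities with modality-dependent tissue contrast, additive Gaussian
#' noise, and a smooth multiplicative intensity offset (bias) field.
#'
#' @slot shape integer grid dimensions (2-D or 3-D).
#' @slot center tumor center coordinates (may be fractional).
#' @slot radii numeric matrix of ellipsoid semi-axes, rows
#'   \code{NCR, ET, NET, ED} (strictly nested), one column per axis.
#' @slot brainAxes semi-axes of the brain ellipse; voxels outside are 0.
#' @slot tissueMeans numeric matrix of mean intensities, rows = modalities
#'   (\code{T1, T1CE, T2, FLAIR}), columns = regions
#'   (\code{BG, ED, NET, ET, NCR}).
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @slot biasAmplitude peak relative deviation of the multiplicative bias
#'   field (0 disables it; must be < 1).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomConfig",
  representation(shape = "integer", center = "numeric", radii = "matrix",
                 brainAxes = "numeric", tissueMeans = "matrix",
                 noiseSd = "numeric", biasAmplitude = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  nd <- length(object@shape)
  if (!(nd %in% c(2L, 3L)) || any(object@shape < 8L))
    return("shape must be 2-D or 3-D with all axes >= 8")
  if (length(object@center) != nd) return("center must match the grid dimensionality")
  if (!identical(rownames(object@radii), PHANTOM_REGIONS) || ncol(object@radii) != nd)
    return("radii must have rows NCR, ET, NET, ED and one column per axis")
  if (any(object@radii <= 0)) return("all semi-axes must be positive")
  for (ax in seq_len(nd))
    if (any(diff(object@radii[, ax]) <= 0))
      return("semi-axes must be strictly nested: NCR < ET < NET < ED on every axis")
  if (length(object@brainAxes) != nd || any(object@brainAxes <= 0))
    return("brainAxes must be positive and match the grid dimensionality")
  if (!identical(rownames(object@tissueMeans), c("T1", "T1CE", "T2", "FLAIR")) ||
      !identical(colnames(object@tissueMeans), c("BG", "ED", "NET", "ET", "NCR")))
    return("tissueMeans must have rows T1,T1CE,T2,FLAIR and columns BG,ED,NET,ET,NCR")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 1)
    return("biasAmplitude must be in [0, 1)")
  TRUE
})

#' Default phantom tissue mean intensities
#'
#' Mean intensities per (modality, region) on a unit background scale,
#' chosen to mirror clinical contrast: edema is bright on FLAIR and T2,
#' the enhancing core is bright on post-contrast T1 (T1CE), and the
#' necrotic core is dark on T1/T1CE.
#'
#' @return Numeric matrix, rows \code{T1, T1CE, T2, FLAIR}, columns
#'   \code{BG, ED, NET, ET, NCR}.
#' @export
defaultTissueMeans <- function() {
  m <- rbind(
    T1    = c(BG = 1.0, ED = 0.9, NET = 0.8, ET = 1.1, NCR = 0.6),
    T1CE  = c(BG = 1.0, ED = 0.9, NET = 1.0, ET = 1.8, NCR = 0.5),
    T2    = c(BG = 1.0, ED = 1.6, NET = 1.3, ET = 1.2, NCR = 1.5),
    FLAIR = c(BG = 1.0, ED = 1.8, NET = 1.4, ET = 1.3, NCR = 1.1))
  m
}

#' Construct a PhantomConfig
#'
#' @param shape grid dimensions; default \code{c(64, 64)} (desk-scale 2-D).
#' @param center tumor center; default is the grid center.
#' @param radii matrix of semi-axes (rows \code{NCR, ET, NET, ED}); default
#'   nests (3, 2.5) in (5, 4) in (7, 6) in (10, 8) for 2-D grids.
#' @param brainAxes brain-ellipse semi-axes; default 90\% of the half-shape.
#' @param tissueMeans per-(modality, region) mean intensities; see
#'   [defaultTissueMeans()].
#' @param noiseSd additive Gaussian noise standard deviation (intensity
#'   units); default 0.
#' @param biasAmplitude peak relative deviation of the smooth multiplicative
#'   bias field; default 0.
#' @param seed integer RNG seed.
#' @return A [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(noiseSd = 0.2, seed = 7)
#' case <- generateCase(cfg)
#' @export
phantomConfig <- function(shape = c(64L, 64L), center = NULL, radii = NULL,
                          brainAxes = NULL, tissueMeans = defaultTissueMeans(),
                          noiseSd = 0, biasAmplitude = 0, seed = 1L) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (is.null(center)) center <- (shape + 1) / 2
  if (is.null(radii)) {
    base <- rbind(NCR = c(3, 2.5), ET = c(5, 4), NET = c(7, 6), ED = c(10, 8))
    radii <- if (nd == 2L) base else cbind(base, base[, 2L] * 0.9)
  }
  radii <- as.matrix(radii)
  rownames(radii) <- PHANTOM_REGIONS
  if (is.null(brainAxes)) brainAxes <- shape / 2 * 0.9
  new("PhantomConfig", shape = shape, center = as.numeric(center), radii = radii,
      brainAxes = as.numeric(brainAxes), tissueMeans = tissueMeans,
      noiseSd = as.numeric(noiseSd), biasAmplitude = as.numeric(biasAmplitude),
      seed = as.integer(seed))
}

#' FeatureConfig: per-pixel feature extraction parameters
#'
#' @slot window odd window side length (pixels) for the local mean and
#'   median; default 5.
#' @slot normalize whether to z-score intensities over nonzero (brain)
#'   pixels before extracting features.
#' @export
setClass("FeatureConfig",
  representation(window = "integer", normalize = "logical"))

setValidity("FeatureConfig", function(object) {
  w <- object@window
  if (length(w) != 1L || w < 1L || w %% 2L == 0L)
    return("window must be an odd positive integer")
  TRUE
})

#' Construct a FeatureConfig
#'
#' @param window odd window side length; default 5.
#' @param normalize z-score intensities over nonzero pixels first;
#'   default TRUE.
#' @return A [FeatureConfig-class].
#' @export
featureConfig <- function(window = 5L, normalize = TRUE) {
  new("FeatureConfig", window = as.integer(window), normalize = isTRUE(normalize))
}

#' CNNConfig: architecture and training parameters of the convolutional
#' pixel classifier
#'
#' The classifier is a small LeNet-style network applied to square intensity
#' patches centered on each pixel: alternating valid convolutions and 2x2
#' downsampling, one fully connected layer, and a softmax output.
#'
#' @slot patchSize odd patch side length in pixels.
#' @slot convChannels output channels of each convolution layer; every
#'   convolution is followed by 2x2 pooling.
#' @slot kernelSize square convolution kernel side length.
#' @slot pool \code{"max"} or \code{"mean"} downsampling.
#' @slot activation \code{"relu"} (\eqn{max(0, x)}) or \code{"softplus"}
#'   (\eqn{log(1 + e^x)}).
#' @slot fcUnits width of the fully connected layer.
#' @slot nClasses number of output classes (>= 2); 2 = tumor vs background.
#' @slot epochs training epochs (0 returns an untrained model).
#' @slot batchSize minibatch size.
#' @slot learningRate SGD learning rate (momentum 0.9 is used internally).
#' @slot pixelsPerClass cap on training pixels sampled per class per case;
#'   background is subsampled to match the tumor count (class balancing).
#' @slot seed integer RNG seed.
#' @export
setClass("CNNConfig",
  representation(patchSize = "integer", convChannels = "integer",
                 kernelSize = "integer", pool = "character",
                 activation = "character", fcUnits = "integer",
                 nClasses = "integer", epochs = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 pixelsPerClass = "integer", seed = "integer"))

setValidity("CNNConfig", function(object) {
  if (object@patchSize < 3L || object@patchSize %% 2L == 0L)
    return("patchSize must be an odd integer >= 3")
  if (length(object@convChannels) < 1L || any(object@convChannels < 1L))
    return("convChannels must be positive")
  if (!object@pool %in% c("max", "mean")) return("pool must be 'max' or 'mean'")
  if (!object@activation %in% c("relu", "softplus"))
    return("activation must be 'relu' or 'softplus'")
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@batchSize < 1L || object@fcUnits < 1L || object@learningRate <= 0)
    return("batchSize, fcUnits and learningRate must be positive")
  # the spatial extent must survive the conv/pool stack
  s <- object@patchSize
  for (i in seq_along(object@convChannels)) {
    s <- s - object@kernelSize + 1L
    if (s < 2L) return("patchSize too small for the conv/pool stack")
    s <- s %/% 2L
  }
  if (s < 1L) return("patchSize too small for the conv/pool stack")
  TRUE
})

#' Construct a CNNConfig
#'
#' @param patchSize odd patch side length; default 17.
#' @param convChannels channels per convolution layer; default \code{c(8, 16)}.
#' @param kernelSize kernel side length; default 3.
#' @param pool \code{"max"} (default) or \code{"mean"}.
#' @param activation \code{"relu"} (default) or \code{"softplus"}.
#' @param fcUnits fully connected width; default 64.
#' @param nClasses output classes; default 2 (tumor vs background).
#' @param epochs training epochs; default 6.
#' @param batchSize minibatch size; default 128.
#' @param learningRate SGD learning rate; default 0.01.
#' @param pixelsPerClass training pixels sampled per class per case;
#'   default 800.
#' @param seed RNG seed; default 1.
#' @return A [CNNConfig-class].
#' @export
cnnConfig <- function(patchSize = 17L, convChannels = c(8L, 16L),
                      kernelSize = 3L, pool = "max", activation = "relu",
                      fcUnits = 64L, nClasses = 2L, epochs = 6L,
                      batchSize = 128L, learningRate = 0.01,
                      pixelsPerClass = 800L, seed = 1L) {
  new("CNNConfig", patchSize = as.integer(patchSize),
      convChannels = as.integer(convChannels), kernelSize = as.integer(kernelSize),
      pool = pool, activation = activation, fcUnits = as.integer(fcUnits),
      nClasses = as.integer(nClasses), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = as.numeric(learningRate),
      pixelsPerClass = as.integer(pixelsPerClass), seed = as.integer(seed))
}

#' SVMEnsembleConfig: parameters of the bagged RBF-SVM refinement stage
#'
#' Each ensemble member is a kernel SVM with radial basis function
#' \eqn{k(u, v) = exp(-||u - v||^2 / (2 \sigma^2))} and penalty \eqn{C},
#' trained on an independent seeded subsample of the pixel rows; binary
#' predictions aggregate by the sign of the mean member decision value.
#'
#' @slot sigma RBF kernel width \eqn{\sigma}; default 0.1.
#' @slot C soft-margin penalty; default 1000.
#' @slot nMembers ensemble size; default 5.
#' @slot subsample fraction of training rows per member in (0, 1]; a value
#'   of 1 uses every row exactly once, values below 1 draw a bootstrap
#'   sample (with replacement) of that fraction.
#' @slot maxTrainPixels cap on training rows per member; default 5000.
#' @slot seed integer RNG seed.
#' @export
setClass("SVMEnsembleConfig",
  representation(sigma = "numeric", C = "numeric", nMembers = "integer",
                 subsample = "numeric", maxTrainPixels = "integer",
                 seed = "integer"),
  prototype(sigma = 0.1, C = 1000, nMembers = 5L, subsample = 0.5,
            maxTrainPixels = 5000L, seed = 1L))

setValidity("SVMEnsembleConfig", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@C <= 0) return("C must be > 0")
  if (object@nMembers < 1L) return("nMembers must be >= 1")
  if (object@subsample <= 0 || object@subsample > 1)
    return("subsample must be in (0, 1]")
  if (object@maxTrainPixels < 1L) return("maxTrainPixels must be >= 1")
  TRUE
})

#' Construct an SVMEnsembleConfig
#'
#' @param sigma RBF kernel width; default 0.1.
#' @param C penalty parameter; default 1000.
#' @param nMembers ensemble size; default 5.
#' @param subsample per-member subsample fraction; default 0.5.
#' @param maxTrainPixels per-member training-row cap; default 5000.
#' @param seed RNG seed; default 1.
#' @return An [SVMEnsembleConfig-class].
#' @export
svmEnsembleConfig <- function(sigma = 0.1, C = 1000, nMembers = 5L,
                              subsample = 0.5, maxTrainPixels = 5000L,
                              seed = 1L) {
  # slots assigned individually: an argument named C would partially match
  # new()'s `Class` formal
  cfg <- new("SVMEnsembleConfig")
  cfg@sigma <- as.numeric(sigma)
  cfg@C <- as.numeric(C)
  cfg@nMembers <- as.integer(nMembers)
  cfg@subsample <- as.numeric(subsample)
  cfg@maxTrainPixels <- as.integer(maxTrainPixels)
  cfg@seed <- as.integer(seed)
  validObject(cfg)
  cfg
}

#' CascadeConfig: all tunables of the three-stage pipeline
#'
#' @slot feature a [FeatureConfig-class].
#' @slot cnn a [CNNConfig-class].
#' @slot svm an [SVMEnsembleConfig-class].
#' @slot roiDilation radius (pixels) of the Euclidean-disc dilation that
#'   turns the current segmentation into the refinement ROI; default 3.
#' @slot maxIterations refinement iteration cap; default 2.
#' @slot convergenceTol stop when the fraction of pixels changing between
#'   iterations falls below this; default 0.001.
#' @slot cnnVetoThreshold within the ROI the network's argmax overrides the
#'   SVM label where its maximum class probability reaches this confidence;
#'   default 0.9.
#' @slot seed integer RNG seed for pipeline-level sampling.
#' @export
setClass("CascadeConfig",
  representation(feature = "FeatureConfig", cnn = "CNNConfig",
                 svm = "SVMEnsembleConfig", roiDilation = "integer",
                 maxIterations = "integer", convergenceTol = "numeric",
                 cnnVetoThreshold = "numeric", seed = "integer"))

setValidity("CascadeConfig", function(object) {
  if (object@roiDilation < 0L) return("roiDilation must be >= 0")
  if (object@maxIterations < 0L) return("maxIterations must be >= 0")
  if (object@convergenceTol < 0 || object@convergenceTol > 1)
    return("convergenceTol must be in [0, 1]")
  if (object@cnnVetoThreshold < 0 || object@cnnVetoThreshold > 1)
    return("cnnVetoThreshold must be in [0, 1]")
  TRUE
})

#' Construct a CascadeConfig
#'
#' @param feature a [FeatureConfig-class]; default \code{featureConfig()}.
#' @param cnn a [CNNConfig-class]; default \code{cnnConfig()}.
#' @param svm an [SVMEnsembleConfig-class]; default \code{svmEnsembleConfig()}.
#' @param roiDilation ROI dilation radius in pixels; default 3.
#' @param maxIterations refinement iteration cap; default 2.
#' @param convergenceTol pixel-change fraction below which refinement stops;
#'   default 0.001.
#' @param cnnVetoThreshold CNN confidence needed to override the SVM inside
#'   the ROI; default 0.9.
#' @param seed RNG seed; default 1.
#' @return A [CascadeConfig-class].
#' @export
cascadeConfig <- function(feature = featureConfig(), cnn = cnnConfig(),
                          svm = svmEnsembleConfig(), roiDilation = 3L,
                          maxIterations = 2L, convergenceTol = 0.001,
                          cnnVetoThreshold = 0.9, seed = 1L) {
  new("CascadeConfig", feature = feature, cnn = cnn, svm = svm,
      roiDilation = as.integer(roiDilation),
      maxIterations = as.integer(maxIterations),
      convergenceTol = as.numeric(convergenceTol),
      cnnVetoThreshold = as.numeric(cnnVetoThreshold), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Model and result objects
## ---------------------------------------------------------------------------

#' CNNModel: a trained (or untrained) convolutional pixel classifier
#'
#' @slot config the [CNNConfig-class] used for training.
#' @slot params list of weight/bias arrays (opaque).
#' @slot trained logical; prediction requires \code{TRUE}.
#' @slot channels number of input channels (modalities) the model expects.
#' @slot modalities modality names of the channels, in training order.
#' @slot lossHistory mean cross-entropy per epoch.
#' @export
setClass("CNNModel",
  representation(config = "CNNConfig", params = "list", trained = "logical",
                 channels = "integer", modalities = "character",
                 lossHistory = "numeric"))

#' SVMEnsembleModel: a trained bagged RBF-SVM ensemble
#'
#' @slot members list of fitted member SVMs (with decision-value orientation).
#' @slot config the [SVMEnsembleConfig-class] used for training.
#' @slot center,scale feature standardization replayed at predict time.
#' @slot featureNames training feature column names.
#' @slot classLevels sorted class values seen in training.
#' @export
setClass("SVMEnsembleModel",
  representation(members = "list", config = "SVMEnsembleConfig",
                 center = "numeric", scale = "numeric",
                 featureNames = "character", classLevels = "integer"))

setValidity("SVMEnsembleModel", function(object) {
  if (length(object@members) != object@config@nMembers)
    return("number of members must equal config nMembers")
  TRUE
})

#' CascadeResult: the output of one cascade run
#'
#' @slot presegmentation the CNN-only initial [LabelMap-class].
#' @slot refined list of [LabelMap-class], one per completed refinement
#'   iteration.
#' @slot final the last map (the presegmentation when no iteration ran).
#' @slot iterationsRun number of completed refinement iterations.
#' @slot perIterationChange fraction of pixels whose label changed at each
#'   iteration, measured on the whole image.
#' @export
setClass("CascadeResult",
  representation(presegmentation = "LabelMap", refined = "list",
                 final = "LabelMap", iterationsRun = "integer",
                 perIterationChange = "numeric"))

setValidity("CascadeResult", function(object) {
  if (length(object@refined) != object@iterationsRun)
    return("refined must hold one map per completed iteration")
  if (length(object@perIterationChange) != object@iterationsRun)
    return("perIterationChange must hold one fraction per iteration")
  last <- if (object@iterationsRun > 0L)
    object@refined[[object@iterationsRun]] else object@presegmentation
  if (!identical(last@data, object@final@data))
    return("final must equal the last refined map (or the presegmentation)")
  TRUE
})

#' ConfusionCounts: pixel-level TP/FP/TN/FN tallies
#'
#' @slot tp,fp,tn,fn nonnegative pixel counts; they sum to the number of
#'   evaluated pixels.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0) || !isWholeNumber(v))
    return("tp, fp, tn, fn must be nonnegative integers")
  TRUE
})

#' Construct ConfusionCounts from explicit tallies
#'
#' @param tp,fp,tn,fn nonnegative pixel counts.
#' @return A [ConfusionCounts-class].
#' @export
ConfusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      tn = as.numeric(tn), fn = as.numeric(fn))
}

#' MetricReport: per-case and cohort segmentation quality
#'
#' @slot dsc,sensitivity,specificity cohort-level values in [0, 1]
#'   (unweighted means over cases; \code{NA} when undefined).
#' @slot nCases number of cases summarized.
#' @slot perCase data.frame with columns \code{case_id}, \code{dsc},
#'   \code{sensitivity}, \code{specificity} (may have zero rows).
#' @export
setClass("MetricReport",
  representation(dsc = "numeric", sensitivity = "numeric",
                 specificity = "numeric", nCases = "integer",
                 perCase = "data.frame"))

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname imageData
#' @export
setMethod("imageData", "ImageVolume", function(x) x@data)

#' @rdname imageData
#' @export
setMethod("imageData", "LabelMap", function(x) x@data)

#' @rdname modality
#' @export
setMethod("modality", "ImageVolume", function(x) x@modality)

#' @rdname spacing
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)

#' @rdname labelScheme
#' @export
setMethod("labelScheme", "LabelMap", function(x) x@scheme)

#' @rdname caseId
#' @export
setMethod("caseId", "CaseRecord", function(x) x@caseId)

#' @rdname volumes
#' @export
setMethod("volumes", "CaseRecord", function(x) x@volumes)

#' @rdname truth
#' @export
setMethod("truth", "CaseRecord", function(x) x@truth)

#' @rdname isTrained
#' @export
setMethod("isTrained", "CNNModel", function(x) isTRUE(x@trained))

#' @rdname isTrained
#' @export
setMethod("isTrained", "SVMEnsembleModel", function(x) length(x@members) > 0L)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "PixelFeatureTable", function(x) x@features)

#' @rdname pixelCoords
#' @export
setMethod("pixelCoords", "PixelFeatureTable", function(x) x@coords)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  cat(sprintf("ImageVolume [%s] %s, spacing %s mm, range [%.4g, %.4g]\n",
              object@modality, paste(dim(object@data), collapse = "x"),
              paste(format(object@spacing, digits = 3), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap [%s] %s, codes {%s}, foreground %d px\n",
              object@scheme, paste(dim(object@data), collapse = "x"),
              paste(sort(unique(as.vector(object@data))), collapse = ","),
              sum(object@data != 0L)))
})

setMethod("show", "CaseRecord", function(object) {
  cat(sprintf("CaseRecord '%s': %s, modalities %s, truth %s\n",
              object@caseId, paste(dim(object@volumes[[1L]]@data), collapse = "x"),
              paste(names(object@volumes), collapse = "/"),
              if (is.null(object@truth)) "absent" else "present"))
})

setMethod("show", "PixelFeatureTable", function(object) {
  cat(sprintf("PixelFeatureTable: %d pixels x %d features (%s) on a %s grid\n",
              nrow(object@features), ncol(object@features),
              paste(colnames(object@features), collapse = ", "),
              paste(object@gridDim, collapse = "x")))
})

setMethod("show", "CNNModel", function(object) {
  cat(sprintf(paste0("CNNModel: patch %dx%dx%d, conv (%s) + %s pool, fc %d, ",
                     "%d classes, %s\n"),
              object@config@patchSize, object@config@patchSize, object@channels,
              paste(object@config@convChannels, collapse = ","),
              object@config@pool, object@config@fcUnits, object@config@nClasses,
              if (object@trained) sprintf("trained (%d epochs, final loss %.4f)",
                                          length(object@lossHistory),
                                          utils::tail(object@lossHistory, 1L))
              else "untrained"))
})

setMethod("show", "SVMEnsembleModel", function(object) {
  cat(sprintf("SVMEnsembleModel: %d RBF members (sigma %.3g, C %.3g), %d features\n",
              length(object@members), object@config@sigma, object@config@C,
              length(object@featureNames)))
})

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf("CascadeResult: %d refinement iteration(s), change %s, final foreground %d px\n",
              object@iterationsRun,
              if (object@iterationsRun) paste(format(object@perIterationChange,
                                                     digits = 3), collapse = ", ")
              else "-", sum(object@final@data != 0L)))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %d, FP %d, TN %d, FN %d (total %d px)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport over %d case(s): DSC %.4f, sensitivity %.4f, specificity %.4f\n",
              object@nCases, object@dsc, object@sensitivity, object@specificity))
})
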