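#' @import methods
NULL

#' Extract the intensity or label grid from an image object
#'
#' @param x an [ImageVolume-class] or [LabelMap-class] object.
#' @return The underlying array (2-D \code{H x W} or 3-D \code{H x W x D}).
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' Modality tag of an image volume
#'
#' @param x an [ImageVolume-class].
#' @return One of \code{"T1"}, \code{"T1CE"}, \code{"T2"}, \code{"FLAIR"},
#'   \code{"UNKNOWN"}.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Voxel spacing of an image volume
#'
#' @param x an [ImageVolume-class].
#' @return Numeric vector of physical voxel sizes (mm), one entry per axis.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Label scheme of a label map
#'
#' @param x a [LabelMap-class].
#' @return \code{"BRATS"} (codes 0/1/2/4) or \code{"BINARY"} (0/1).
#' @export
setGeneric("labelScheme", function(x) standardGeneric("labelScheme"))

#' Case identifier
#'
#' @param x a [CaseRecord-class].
#' @return Character scalar.
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' Modality volumes of a case
#'
#' @param x a [CaseRecord-class].
#' @return Named list of [ImageVolume-class] objects, one per modality.
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' Ground-truth label map of a case
#'
#' @param x a [CaseRecord-class].
#' @return A [LabelMap-class], or \code{NULL} when the case has no truth.
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' Is a model trained and ready to predict?
#'
#' @param x a [CNNModel-class] or [SVMEnsembleModel-class].
#' @return Logical scalar.
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))

#' Per-pixel feature matrix of a feature table
#'
#' @param x a [PixelFeatureTable-class].
#' @return Numeric matrix, one row per pixel.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Pixel coordinates of a feature table
#'
#' @param x a [PixelFeatureTable-class].
#' @return Integer matrix with columns \code{row}, \code{col}
#'   (and \code{slice} for 3-D sources), in row-major scan order.
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))
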