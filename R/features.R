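#' @include AllClasses.R
NULL

## Intensity standardization and the per-pixel (grayscale, windowed mean,
## windowed median) feature vector.

#' Standardize image intensities over nonzero pixels
#'
#' Z-scores the intensities of all nonzero pixels (mean 0, population
#' standard deviation 1, so a two-valued image maps to -1/+1); pixels that
#' are exactly zero — the background of skull-stripped MRI — are left at
#' zero. A constant nonzero image is shifted to zero mean with the
#' unit-scale step skipped (warned). The operation is idempotent to
#' floating-point precision.
#'
#' @param volume an [ImageVolume-class].
#' @return An [ImageVolume-class] with standardized intensities.
#' @examples
#' v <- ImageVolume(matrix(c(0, 1, 3, 0), 2, 2))
#' imageData(normalizeIntensity(v))  # nonzero pixels become -1, +1
#' @export
normalizeIntensity <- function(volume) {
  stopifnot(is(volume, "ImageVolume"))
  d <- volume@data
  nz <- d != 0
  if (!any(nz)) return(volume)
  m <- mean(d[nz])
  s <- sqrt(mean((d[nz] - m)^2))   # population sd: two values map to -1/+1
  if (!is.finite(s) || s == 0) {
    warning("constant nonzero intensities: centered only, unit-scale skipped")
    d[nz] <- d[nz] - m
  } else {
    d[nz] <- (d[nz] - m) / s
  }
  ImageVolume(d, modality = volume@modality, spacing = volume@spacing)
}

# Reflect-pad a 2-D matrix by `pad` samples on each side (edge duplicated).
reflectPad2d <- function(mat, pad) {
  nr <- nrow(mat); nc <- ncol(mat)
  mat[reflectIndex(seq.int(1L - pad, nr + pad), nr),
      reflectIndex(seq.int(1L - pad, nc + pad), nc), drop = FALSE]
}

# Gather the w x w neighborhood of every pixel of a 2-D matrix into an
# (nr*nc) x w^2 matrix (rows in column-major pixel order).
windowStack <- function(mat, window) {
  pad <- (window - 1L) %/% 2L
  padded <- reflectPad2d(mat, pad)
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr * nc, window * window)
  k <- 0L
  for (dj in seq_len(window)) {
    for (di in seq_len(window)) {
      k <- k + 1L
      out[, k] <- as.vector(padded[di:(di + nr - 1L), dj:(dj + nc - 1L)])
    }
  }
  out
}

featureSliceMatrix <- function(mat, window) {
  stack <- windowStack(mat, window)
  meds <- apply(stack, 1L, lowerMedian)
  cbind(gray = as.vector(mat), mean = rowMeans(stack), median = meds)
}

# Row-major coordinate grid for a 2-D or 3-D shape.
rowMajorCoords <- function(dm) {
  nr <- dm[1L]; nc <- dm[2L]
  slice2d <- cbind(row = rep(seq_len(nr), each = nc),
                   col = rep(seq_len(nc), times = nr))
  if (length(dm) == 2L) return(slice2d)
  ns <- dm[3L]
  cbind(row = rep(slice2d[, 1L], times = ns),
        col = rep(slice2d[, 2L], times = ns),
        slice = rep(seq_len(ns), each = nr * nc))
}

#' Per-pixel grayscale / windowed mean / windowed median features
#'
#' For every pixel the feature triplet is its (optionally standardized)
#' intensity, the mean of its \code{window x window} neighborhood, and the
#' median of that neighborhood. Borders use reflect padding (the edge
#' sample is duplicated). For 3-D volumes the window is applied within each
#' slice. Rows are emitted in row-major scan order (columns fastest,
#' slices slowest).
#'
#' @param image an [ImageVolume-class].
#' @param config a [FeatureConfig-class]; the window must be odd and no
#'   larger than the smallest in-slice image dimension.
#' @return A [PixelFeatureTable-class] with columns \code{gray},
#'   \code{mean}, \code{median}.
#' @examples
#' img <- ImageVolume(matrix(1:25, 5, 5, byrow = TRUE))
#' tab <- pixelFeatures(img, featureConfig(window = 5, normalize = FALSE))
#' featureMatrix(tab)[13, ]  # center pixel: gray 13, mean 13, median 13
#' @export
pixelFeatures <- function(image, config = featureConfig()) {
  stopifnot(is(image, "ImageVolume"), is(config, "FeatureConfig"))
  validObject(config)
  w <- config@window
  dm <- dim(image@data)
  if (w > min(dm[1:2]))
    stop(sprintf("window (%d) exceeds the smallest in-slice dimension (%d)",
                 w, min(dm[1:2])), call. = FALSE)
  vol <- if (config@normalize) normalizeIntensity(image) else image
  coords <- rowMajorCoords(dm)
  lin <- coordsToLinear(coords, dm)
  if (length(dm) == 2L) {
    featLin <- featureSliceMatrix(vol@data, w)
  } else {
    featLin <- do.call(rbind, lapply(seq_len(dm[3L]), function(s)
      featureSliceMatrix(vol@data[, , s], w)))
  }
  new("PixelFeatureTable", coords = coords, features = featLin[lin, , drop = FALSE],
      gridDim = as.integer(dm))
}

#' Append a presegmentation label column to a feature table
#'
#' Joins the label value at each pixel coordinate as an extra feature
#' column named \code{label}, as consumed by the SVM refinement stage.
#' Applying the operation twice appends two label columns (this is
#' intentional and not an error).
#'
#' @param table a [PixelFeatureTable-class].
#' @param labels a [LabelMap-class] aligned with the table's source grid.
#' @return The augmented [PixelFeatureTable-class].
#' @export
augmentWithLabels <- function(table, labels) {
  stopifnot(is(table, "PixelFeatureTable"), is(labels, "LabelMap"))
  if (!identical(as.integer(dim(labels@data)), table@gridDim))
    stop(sprintf("label shape (%s) does not match the table's source grid (%s)",
                 paste(dim(labels@data), collapse = "x"),
                 paste(table@gridDim, collapse = "x")), call. = FALSE)
  lin <- coordsToLinear(table@coords, table@gridDim)
  lab <- as.numeric(labels@data[lin])
  feats <- cbind(table@features, label = lab)
  new("PixelFeatureTable", coords = table@coords, features = feats,
      gridDim = table@gridDim)
}
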