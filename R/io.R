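#' @include AllClasses.R
NULL

## NIfTI-1 and PNG input/output plus BraTS label conventions.

niftiExt <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
pngExt <- function(path) grepl("\\.png$", path, ignore.case = TRUE)

readGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (niftiExt(path)) {
    img <- RNifti::readNifti(path)
    dm <- dim(img)
    # drop trailing singleton axes (2-D slices are often stored as HxWx1)
    while (length(dm) > 2L && dm[length(dm)] == 1L) dm <- dm[-length(dm)]
    sp <- RNifti::pixdim(img)[seq_along(dm)]
    arr <- array(as.numeric(img), dim = dm)
    list(data = arr, spacing = as.numeric(sp))
  } else if (pngExt(path)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L)
      stop(sprintf("expected a grayscale PNG but found %d channels", dim(img)[3L]),
           call. = FALSE)
    # png values are scaled to [0, 1]; map back to 8-bit units
    list(data = as.array(img * 255), spacing = c(1, 1))
  } else {
    stop("unsupported extension (expected .nii, .nii.gz or .png): ", path,
         call. = FALSE)
  }
}

#' Read an image volume from NIfTI or PNG
#'
#' NIfTI (\code{.nii}/\code{.nii.gz}) files yield 2-D or 3-D volumes with
#' their stored voxel spacing; grayscale PNG files yield a single 2-D slice
#' with intensities in [0, 255] and \code{UNKNOWN} modality (unless
#' overridden). RGB PNGs are rejected.
#'
#' @param path file path ending in \code{.nii}, \code{.nii.gz} or \code{.png}.
#' @param modality optional modality tag to attach; inferred as
#'   \code{UNKNOWN} otherwise.
#' @return An [ImageVolume-class].
#' @seealso [writeVolume()], [readLabelMap()]
#' @export
readVolume <- function(path, modality = "UNKNOWN") {
  g <- readGrid(path)
  ImageVolume(g$data, modality = modality, spacing = g$spacing)
}

#' Write an image volume to NIfTI or PNG
#'
#' NIfTI output stores intensities at double precision (lossless round
#' trip); PNG output writes a single 2-D slice as 16-bit grayscale with
#' intensities interpreted on the [0, 255] scale.
#'
#' @param volume an [ImageVolume-class].
#' @param path destination ending in \code{.nii}, \code{.nii.gz} or
#'   \code{.png}.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  if (niftiExt(path)) {
    img <- RNifti::asNifti(volume@data)
    RNifti::pixdim(img) <- volume@spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (pngExt(path)) {
    if (length(dim(volume@data)) != 2L)
      stop("PNG output supports only 2-D slices", call. = FALSE)
    png::writePNG(pmin(pmax(volume@data / 255, 0), 1), path)
  } else {
    stop("unsupported extension (expected .nii, .nii.gz or .png): ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Read a label map from NIfTI or PNG
#'
#' Values are rounded to integers; PNG label files are assumed to store the
#' raw codes on the 8-bit scale written by [writeLabelmap()].
#'
#' @param path file path ending in \code{.nii}, \code{.nii.gz} or \code{.png}.
#' @param scheme \code{"BRATS"} or \code{"BINARY"}.
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path, scheme = c("BRATS", "BINARY")) {
  scheme <- match.arg(scheme)
  g <- readGrid(path)
  LabelMap(round(g$data), scheme = scheme)
}

#' Write a label map
#'
#' NIfTI output uses 16-bit integers; PNG output stores the raw integer
#' codes in 8-bit gray levels. Both round-trip exactly through
#' [readLabelMap()].
#'
#' @param map a [LabelMap-class].
#' @param path destination ending in \code{.nii}, \code{.nii.gz} or
#'   \code{.png}.
#' @return Invisibly, \code{path}.
#' @export
writeLabelmap <- function(map, path) {
  stopifnot(is(map, "LabelMap"))
  if (niftiExt(path)) {
    RNifti::writeNifti(RNifti::asNifti(map@data), path, datatype = "int16")
  } else if (pngExt(path)) {
    if (length(dim(map@data)) != 2L)
      stop("PNG output supports only 2-D slices", call. = FALSE)
    png::writePNG(map@data / 255, path)
  } else {
    stop("unsupported extension (expected .nii, .nii.gz or .png): ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Collapse BraTS subregion labels to a whole-tumor binary mask
#'
#' The whole tumor is the union of all nonzero BraTS codes: edema (2),
#' necrotic / non-enhancing core (1) and enhancing core (4). Binary maps
#' pass through unchanged (the operation is idempotent).
#'
#' @param map a [LabelMap-class] with scheme \code{"BRATS"} (or already
#'   \code{"BINARY"}).
#' @return A \code{"BINARY"} [LabelMap-class] with 1 wherever the input was
#'   1, 2 or 4.
#' @examples
#' m <- LabelMap(matrix(c(0, 1, 2, 4), 2, 2), "BRATS")
#' imageData(binarizeWholeTumor(m))
#' @export
binarizeWholeTumor <- function(map) {
  stopifnot(is(map, "LabelMap"))
  if (map@scheme == "BINARY") return(map)
  codes <- unique(as.vector(map@data))
  bad <- setdiff(codes, BRATS_CODES)
  if (length(bad))
    stop("unexpected BraTS label code(s): ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  bin <- array(as.integer(map@data %in% c(1L, 2L, 4L)), dim = dim(map@data))
  LabelMap(bin, scheme = "BINARY")
}

## BraTS-style case directories -----------------------------------------------

caseSuffixes <- c(T1 = "_t1", T1CE = "_t1ce", T2 = "_t2", FLAIR = "_flair")

findCaseFile <- function(dir, suffix) {
  files <- list.files(dir, full.names = TRUE)
  stems <- sub("\\.nii(\\.gz)?$|\\.png$", "", tolower(basename(files)))
  hit <- files[endsWith(stems, suffix)]
  if (length(hit) == 0L) return(NULL)
  if (length(hit) > 1L)
    stop(sprintf("multiple files match '*%s' in %s", suffix, dir), call. = FALSE)
  hit
}

#' Read a BraTS-style case directory
#'
#' Discovers the modality volumes by the public-dataset filename convention
#' (case-insensitive suffixes \code{_t1}, \code{_t1ce}, \code{_t2},
#' \code{_flair}, and \code{_seg} for the label volume, before the
#' extension).
#'
#' @param dir directory holding one case.
#' @param caseId identifier to record; default is the directory name.
#' @return A [CaseRecord-class]; \code{truth} is \code{NULL} when no
#'   \code{*_seg} file is present.
#' @export
readCase <- function(dir, caseId = basename(normalizePath(dir))) {
  if (!dir.exists(dir)) stop("case directory not found: ", dir, call. = FALSE)
  vols <- list()
  for (mod in names(caseSuffixes)) {
    f <- findCaseFile(dir, caseSuffixes[[mod]])
    if (!is.null(f)) vols[[mod]] <- readVolume(f, modality = mod)
  }
  if (length(vols) == 0L)
    stop("no modality volumes (*_t1, *_t1ce, *_t2, *_flair) found in ", dir,
         call. = FALSE)
  segFile <- findCaseFile(dir, "_seg")
  tr <- if (is.null(segFile)) NULL else readLabelMap(segFile, scheme = "BRATS")
  CaseRecord(caseId, vols, truth = tr)
}

#' Write a case as a BraTS-style directory
#'
#' @param case a [CaseRecord-class].
#' @param dir destination directory (created if needed); files are named
#'   \code{<caseId>_<modality>.nii.gz} and \code{<caseId>_seg.nii.gz}.
#' @return Invisibly, \code{dir}.
#' @export
writeCase <- function(case, dir) {
  stopifnot(is(case, "CaseRecord"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mod in names(case@volumes)) {
    writeVolume(case@volumes[[mod]],
                file.path(dir, sprintf("%s%s.nii.gz", case@caseId,
                                       caseSuffixes[[mod]])))
  }
  if (!is.null(case@truth))
    writeLabelmap(case@truth, file.path(dir, sprintf("%s_seg.nii.gz", case@caseId)))
  invisible(dir)
}

#' Write a per-case metric report to CSV
#'
#' One row per case with columns \code{case_id}, \code{dsc},
#' \code{sensitivity}, \code{specificity}, matching the cohort evaluation
#' tables produced by [cohortReport()].
#'
#' @param report a [MetricReport-class].
#' @param path destination CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeMetricsCSV <- function(report, path) {
  stopifnot(is(report, "MetricReport"))
  utils::write.csv(report@perCase, path, row.names = FALSE)
  invisible(path)
}
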