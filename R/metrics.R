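#' @include AllClasses.R
NULL

## Pixel-level evaluation: confusion tallies, DSC / sensitivity /
## specificity, cohort summaries and relative improvements.

asBinaryArray <- function(x, what) {
  if (is(x, "LabelMap")) {
    if (x@scheme != "BINARY")
      stop(what, " must use the BINARY scheme", call. = FALSE)
    return(x@data)
  }
  arr <- as.array(x)
  if (!all(arr %in% c(0, 1)))
    stop(what, " must be binary (0/1)", call. = FALSE)
  arr
}

#' Pixel confusion counts between a prediction and the truth
#'
#' TP: predicted tumor, truly tumor. FP: predicted tumor, truly
#' background. TN: predicted background, truly background. FN: predicted
#' background, truly tumor. The four counts sum to the number of pixels.
#'
#' @param pred predicted \code{BINARY} [LabelMap-class] (or 0/1 array).
#' @param truth reference \code{BINARY} [LabelMap-class] (or 0/1 array)
#'   of the same shape.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth) {
  p <- asBinaryArray(pred, "pred")
  t <- asBinaryArray(truth, "truth")
  if (!identical(dim(p), dim(t)))
    stop(sprintf("shape mismatch: pred %s vs truth %s",
                 paste(dim(p), collapse = "x"), paste(dim(t), collapse = "x")),
         call. = FALSE)
  ConfusionCounts(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
                  tn = sum(p == 0 & t == 0), fn = sum(p == 0 & t == 1))
}

#' Dice similarity coefficient
#'
#' \eqn{DSC = 2 TP / (FP + 2 TP + FN)}, the overlap between prediction and
#' truth (1 = perfect). When both are empty (zero denominator) the overlap
#' is defined as 1.
#'
#' @param counts a [ConfusionCounts-class].
#' @return DSC in [0, 1].
#' @examples
#' dsc(ConfusionCounts(tp = 3, fp = 1, tn = 10, fn = 2))  # 6/9
#' @export
dsc <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  den <- counts@fp + 2 * counts@tp + counts@fn
  if (den == 0) {
    message("empty truth and empty prediction: DSC defined as 1")
    return(1)
  }
  2 * counts@tp / den
}

#' Sensitivity (true positive rate)
#'
#' \eqn{Sens = TP / (TP + FN)}. Undefined (returned as \code{NA}) when the
#' truth has no tumor pixels.
#'
#' @param counts a [ConfusionCounts-class].
#' @return Sensitivity in [0, 1], or \code{NA}.
#' @export
sensitivity <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  den <- counts@tp + counts@fn
  if (den == 0) {
    message("no positive pixels in truth: sensitivity undefined (NA)")
    return(NA_real_)
  }
  counts@tp / den
}

#' Specificity (true negative rate)
#'
#' \eqn{Spec = TN / (TN + FP)}. Undefined (returned as \code{NA}) when the
#' truth has no background pixels.
#'
#' @param counts a [ConfusionCounts-class].
#' @return Specificity in [0, 1], or \code{NA}.
#' @export
specificity <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  den <- counts@tn + counts@fp
  if (den == 0) {
    message("no negative pixels in truth: specificity undefined (NA)")
    return(NA_real_)
  }
  counts@tn / den
}

#' Evaluate one case against its ground truth
#'
#' Convenience wrapper producing one per-case metric row.
#'
#' @param pred predicted \code{BINARY} [LabelMap-class].
#' @param truth reference label map; BRATS maps are collapsed to the whole
#'   tumor first.
#' @param caseId identifier for the row.
#' @return data.frame with columns \code{case_id}, \code{dsc},
#'   \code{sensitivity}, \code{specificity}.
#' @export
evaluateCase <- function(pred, truth, caseId = "case") {
  if (is(truth, "LabelMap") && truth@scheme == "BRATS")
    truth <- binarizeWholeTumor(truth)
  counts <- confusionCounts(pred, truth)
  data.frame(case_id = caseId, dsc = dsc(counts),
             sensitivity = sensitivity(counts),
             specificity = specificity(counts))
}

#' Summarize per-case metrics into a cohort report
#'
#' Cohort values are unweighted means of the per-case values; undefined
#' (\code{NA}) entries are excluded from the mean and their count is
#' logged. The per-case rows are retained in the report.
#'
#' @param perCase data.frame with columns \code{case_id}, \code{dsc},
#'   \code{sensitivity}, \code{specificity} (one row per case).
#' @return A [MetricReport-class].
#' @export
cohortReport <- function(perCase) {
  if (!is.data.frame(perCase) || nrow(perCase) < 1L)
    stop("at least one per-case row is required", call. = FALSE)
  needed <- c("case_id", "dsc", "sensitivity", "specificity")
  if (!all(needed %in% names(perCase)))
    stop("per-case rows need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  meanDefined <- function(v, nm) {
    nNA <- sum(is.na(v))
    if (nNA > 0L)
      message(sprintf("%d undefined %s value(s) excluded from the cohort mean",
                      nNA, nm))
    if (nNA == length(v)) return(NA_real_)
    mean(v, na.rm = TRUE)
  }
  new("MetricReport",
      dsc = meanDefined(perCase$dsc, "dsc"),
      sensitivity = meanDefined(perCase$sensitivity, "sensitivity"),
      specificity = meanDefined(perCase$specificity, "specificity"),
      nCases = nrow(perCase),
      perCase = perCase[, needed])
}

#' Relative improvement of one score over a baseline, in percent
#'
#' \eqn{100 (new - baseline) / baseline}, rounded to the reporting
#' precision (one decimal place by default). This is the relative percent
#' change used when comparing segmentation methods on the same cohort.
#'
#' @param new the improved method's score.
#' @param baseline the reference method's score; must be positive.
#' @param digits decimal places to round to; default 1.
#' @return Percent improvement (negative when \code{new} is worse).
#' @examples
#' relativeImprovement(0.8958, 0.8268)  # 8.3
#' @export
relativeImprovement <- function(new, baseline, digits = 1L) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline must be positive", call. = FALSE)
  round(100 * (new - baseline) / baseline, digits)
}
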