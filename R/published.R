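#' @include metrics.R
NULL

#' Published cohort-level evaluation indices of the three methods
#'
#' The DSC, sensitivity and specificity reported for the stand-alone SVM,
#' the stand-alone CNN, and the CNN-SVM cascade (method
#' \code{"DCNN-F-SVM"}) on the BraTS18 three-fold cross-validation test
#' set (\code{dataset = "brats18"}) and on a 26-patient clinical cohort
#' (\code{dataset = "clinical"}). Shipped as a plain-text table in
#' \code{inst/extdata/published_indices.csv}.
#'
#' @return data.frame with columns \code{dataset}, \code{method},
#'   \code{dsc}, \code{sensitivity}, \code{specificity}.
#' @examples
#' publishedIndices()
#' @export
publishedIndices <- function() {
  path <- system.file("extdata", "published_indices.csv", package = "cascadeSeg",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Relative improvements of the cascade over each baseline
#'
#' Recomputes, with [relativeImprovement()], the percent improvement of
#' the cascade's DSC, sensitivity and specificity over the stand-alone
#' SVM and CNN baselines on both published cohorts — twelve values in
#' total, reported to one decimal place.
#'
#' @return data.frame with columns \code{dataset}, \code{baseline},
#'   \code{metric}, \code{improvement_pct}.
#' @examples
#' publishedImprovements()
#' @export
publishedImprovements <- function() {
  idx <- publishedIndices()
  out <- list()
  for (ds in unique(idx$dataset)) {
    sub <- idx[idx$dataset == ds, ]
    prop <- sub[sub$method == "DCNN-F-SVM", ]
    for (bl in c("SVM", "CNN")) {
      base <- sub[sub$method == bl, ]
      for (metric in c("dsc", "sensitivity", "specificity")) {
        out[[length(out) + 1L]] <- data.frame(
          dataset = ds, baseline = bl, metric = metric,
          improvement_pct = relativeImprovement(prop[[metric]], base[[metric]]))
      }
    }
  }
  do.call(rbind, out)
}
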