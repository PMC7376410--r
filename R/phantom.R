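#' @include AllClasses.R
NULL

## Synthetic multimodal glioma phantoms with ground truth.

# Squared normalized ellipsoid distance of every voxel to `center` with
# semi-axes `axes`; <= 1 means inside.
ellipsoidDistance <- function(shape, center, axes) {
  grids <- lapply(seq_along(shape), function(ax)
    ((seq_len(shape[ax]) - center[ax]) / axes[ax])^2)
  d <- array(0, dim = shape)
  for (ax in seq_along(shape)) {
    d <- d + array(rep(grids[[ax]], each = prod(shape[seq_len(ax - 1L)])),
                   dim = shape)
  }
  d
}

# Region code array: 0 outside brain, 1 brain background, then tumor
# subregions by innermost containing ellipsoid.
phantomRegions <- function(config) {
  shape <- config@shape
  region <- array("OUT", dim = shape)
  brainCenter <- (shape + 1) / 2
  region[ellipsoidDistance(shape, brainCenter, config@brainAxes) <= 1] <- "BG"
  # assign from outermost inwards so inner regions overwrite
  for (rg in c("ED", "NET", "ET", "NCR")) {
    inside <- ellipsoidDistance(shape, config@center, config@radii[rg, ]) <= 1
    region[inside] <- rg
  }
  region
}

phantomLabels <- function(region) {
  code <- array(0L, dim = dim(region))
  code[region == "ED"] <- 2L
  code[region == "NET"] <- 1L
  code[region == "NCR"] <- 1L
  code[region == "ET"] <- 4L
  code
}

# Smooth multiplicative bias field: 1 + amplitude * Gaussian bump with a
# seeded center and a width of ~40% of the grid, peak deviation = amplitude.
biasField <- function(shape, amplitude) {
  if (amplitude == 0) return(array(1, dim = shape))
  bump <- runif(length(shape), 0.25, 0.75) * shape
  width <- 0.4 * shape
  d <- ellipsoidDistance(shape, bump, width)
  1 + amplitude * exp(-d / 2)
}

#' Generate one synthetic multimodal glioma case
#'
#' Builds a concentric-ellipsoid glioma (necrotic core inside enhancing core
#' inside non-enhancing core inside edema) within a smooth brain ellipse,
#' rendered in the four standard modalities (T1, T1CE, T2, FLAIR) with
#' modality-dependent contrast, an optional smooth multiplicative bias
#' field, and optional additive Gaussian noise. Voxels outside the brain
#' ellipse are exactly zero (as in skull-stripped MRI). The BraTS ground
#' truth labels edema 2, necrotic/non-enhancing core 1 and enhancing
#' core 4. Identical configurations (including the seed) generate
#' bit-identical cases.
#'
#' @param config a [PhantomConfig-class].
#' @param caseId identifier to record; defaults to one derived from the seed.
#' @return A [CaseRecord-class] with four volumes and a BRATS truth map.
#' @examples
#' case <- generateCase(phantomConfig(seed = 3))
#' truth(case)
#' @export
generateCase <- function(config, caseId = sprintf("phantom_%06d", config@seed)) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  region <- phantomRegions(config)
  labels <- phantomLabels(region)
  shape <- config@shape
  mods <- rownames(config@tissueMeans)
  withSeed(config@seed, {
    bias <- biasField(shape, config@biasAmplitude)
    vols <- lapply(mods, function(mod) {
      img <- array(0, dim = shape)
      for (rg in colnames(config@tissueMeans)) {
        sel <- region == rg
        img[sel] <- config@tissueMeans[mod, rg]
      }
      img <- img * bias
      if (config@noiseSd > 0) {
        inBrain <- region != "OUT"
        img[inBrain] <- img[inBrain] + rnorm(sum(inBrain), 0, config@noiseSd)
      }
      ImageVolume(img, modality = mod)
    })
    names(vols) <- mods
    CaseRecord(caseId, vols, truth = LabelMap(labels, scheme = "BRATS"))
  })
}

jitterConfig <- function(base, center, scales) {
  radii <- base@radii * scales
  phantomConfig(shape = base@shape, center = center, radii = radii,
                brainAxes = base@brainAxes, tissueMeans = base@tissueMeans,
                noiseSd = base@noiseSd, biasAmplitude = base@biasAmplitude,
                seed = base@seed)
}

#' Generate a cohort of jittered phantom cases
#'
#' Draws \code{nCases} cases from a seeded stream, jittering the tumor
#' center (uniformly within ±10\% of the grid) and each subregion's
#' semi-axes (uniform scale in [0.85, 1.2]) around \code{baseConfig}.
#' Jitter draws that would break the strict subregion nesting are resampled
#' internally, so every emitted configuration is valid. The cohort is
#' reproducible per (\code{baseConfig}, \code{seed}).
#'
#' @param nCases number of cases (>= 1).
#' @param baseConfig a [PhantomConfig-class] providing the nominal geometry,
#'   contrast, noise and bias settings.
#' @param seed integer seed for the cohort stream.
#' @return List of [CaseRecord-class] objects with ids
#'   \code{phantom_001, ...}.
#' @examples
#' cohort <- generateCohort(3, phantomConfig(noiseSd = 0.1), seed = 11)
#' vapply(cohort, caseId, character(1))
#' @export
generateCohort <- function(nCases, baseConfig = phantomConfig(), seed = 1L) {
  stopifnot(nCases >= 1L)
  validObject(baseConfig)
  withSeed(seed, {
    caseSeeds <- sample.int(.Machine$integer.max, nCases)
    configs <- vector("list", nCases)
    for (i in seq_len(nCases)) {
      repeat {
        center <- baseConfig@center + runif(length(baseConfig@shape),
                                            -0.1, 0.1) * baseConfig@shape
        scales <- matrix(runif(length(baseConfig@radii), 0.85, 1.2),
                         nrow = nrow(baseConfig@radii))
        radii <- baseConfig@radii * scales
        nested <- all(apply(radii, 2L, function(r) all(diff(r) > 0)))
        if (nested) break
      }
      cfg <- phantomConfig(shape = baseConfig@shape, center = center,
                           radii = radii, brainAxes = baseConfig@brainAxes,
                           tissueMeans = baseConfig@tissueMeans,
                           noiseSd = baseConfig@noiseSd,
                           biasAmplitude = baseConfig@biasAmplitude,
                           seed = caseSeeds[i])
      configs[[i]] <- cfg
    }
    lapply(seq_len(nCases), function(i)
      generateCase(configs[[i]], caseId = sprintf("phantom_%03d", i)))
  })
}
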