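# Shared fixtures: desk-scale phantom cohorts and down-sized model configs
# so training-based tests run in seconds.

tinyPhantomConfig <- function(noiseSd = 0, biasAmplitude = 0, seed = 1L) {
  phantomConfig(shape = c(32L, 32L),
                radii = rbind(NCR = c(1.6, 1.3), ET = c(2.6, 2.1),
                              NET = c(3.6, 3.1), ED = c(5.0, 4.2)),
                noiseSd = noiseSd, biasAmplitude = biasAmplitude, seed = seed)
}

tinyCnnConfig <- function(epochs = 12L, seed = 1L, ...) {
  # small cohorts yield few minibatches, so the desk-scale fixture trains
  # longer with a larger step and smaller batches
  cnnConfig(patchSize = 11L, convChannels = c(4L, 8L), fcUnits = 16L,
            epochs = epochs, batchSize = 64L, learningRate = 0.05,
            pixelsPerClass = 250L, seed = seed, ...)
}

tinyCascadeConfig <- function(seed = 1L, ...) {
  cascadeConfig(cnn = tinyCnnConfig(seed = seed),
                svm = svmEnsembleConfig(nMembers = 3L, maxTrainPixels = 2000L,
                                        seed = seed),
                roiDilation = 2L, seed = seed, ...)
}

# Independent double-loop oracle for the windowed pixel features, with its
# own reflect-index rule (edge duplicated).
oraclePixelFeatures <- function(mat, window) {
  reflect <- function(i, n) {
    if (i < 1) return(1 - i)
    if (i > n) return(2 * n + 1 - i)
    i
  }
  pad <- (window - 1) / 2
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr * nc, 3)
  k <- 0
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      vals <- numeric(0)
      for (dr in -pad:pad) {
        for (dc in -pad:pad) {
          vals <- c(vals, mat[reflect(r + dr, nr), reflect(cl + dc, nc)])
        }
      }
      k <- k + 1
      s <- sort(vals)
      out[k, ] <- c(mat[r, cl], mean(vals), s[ceiling(length(s) / 2)])
    }
  }
  out  # rows in row-major scan order
}

# Brute-force per-pixel confusion tally.
oracleConfusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}
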