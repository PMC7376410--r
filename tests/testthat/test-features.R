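test_that("intensity standardization z-scores nonzero pixels only", {
  v <- ImageVolume(matrix(c(0, 1, 3, 0), 2, 2))
  out <- imageData(normalizeIntensity(v))
  expect_equal(sort(out[out != 0]), c(-1, 1))
  expect_true(all(out[imageData(v) == 0] == 0))
  # idempotence
  once <- normalizeIntensity(ImageVolume(matrix(rnorm(64, 5, 2) + 10, 8, 8)))
  twice <- normalizeIntensity(once)
  expect_lt(max(abs(imageData(twice) - imageData(once))), 1e-9)
  # moments recomputed directly on a phantom volume
  vol <- volumes(generateCase(tinyPhantomConfig(noiseSd = 0.3, seed = 2)))$T2
  nd <- imageData(normalizeIntensity(vol))
  nz <- nd[imageData(vol) != 0]
  expect_lt(abs(mean(nz)), 1e-9)
  expect_lt(abs(sqrt(mean((nz - mean(nz))^2)) - 1), 1e-9)
  # constant nonzero image: centered only, with a warning
  expect_warning(cn <- normalizeIntensity(ImageVolume(matrix(7, 3, 3))),
                 "constant")
  expect_true(all(imageData(cn) == 0))
})

test_that("window features reproduce hand-computable cases", {
  cfgNoNorm <- function(w) featureConfig(window = w, normalize = FALSE)
  # constant image: every row is (c, c, c)
  tab <- pixelFeatures(ImageVolume(matrix(4.5, 6, 6)), cfgNoNorm(3))
  expect_true(all(featureMatrix(tab) == 4.5))
  # 5x5 row-major 1..25, center pixel, window 5: mean 13, median 13
  img <- ImageVolume(matrix(1:25, 5, 5, byrow = TRUE))
  f <- featureMatrix(pixelFeatures(img, cfgNoNorm(5)))
  expect_equal(unname(f[13, ]), c(13, 13, 13))
  # window 1 degenerates to the grayscale value
  f1 <- featureMatrix(pixelFeatures(img, cfgNoNorm(1)))
  expect_equal(f1[, "mean"], f1[, "gray"])
  expect_equal(f1[, "median"], f1[, "gray"])
  # invalid windows
  expect_error(featureConfig(window = 4), "odd")
  expect_error(pixelFeatures(img, cfgNoNorm(7)), "exceeds")
})

test_that("window features match the double-loop oracle exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    mat <- matrix(rnorm(81), 9, 9)
    for (w in c(3, 5)) {
      got <- featureMatrix(pixelFeatures(ImageVolume(mat),
                                         featureConfig(w, normalize = FALSE)))
      want <- oraclePixelFeatures(mat, w)
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("windowed features are translation-equivariant and order-bounded", {
  set.seed(8)
  inner <- matrix(rnorm(25), 5, 5)
  pad0 <- matrix(0, 11, 11)
  a <- b <- pad0
  a[2:6, 2:6] <- inner
  b[4:8, 4:8] <- inner  # shifted by (2, 2)
  cfg <- featureConfig(3, normalize = FALSE)
  fa <- featureMatrix(pixelFeatures(ImageVolume(a), cfg))
  fb <- featureMatrix(pixelFeatures(ImageVolume(b), cfg))
  idxA <- function(r, cl) (r - 1) * 11 + cl   # row-major row index
  for (r in 3:5) for (cl in 3:5)
    expect_equal(fa[idxA(r, cl), ], fb[idxA(r + 2, cl + 2), ])
  # median bounded by the window extremes
  set.seed(9)
  m <- matrix(rnorm(49), 7, 7)
  stack <- cascadeSeg:::windowStack(m, 3)
  med <- featureMatrix(pixelFeatures(ImageVolume(m), cfg))[, "median"]
  lin <- cascadeSeg:::coordsToLinear(
    pixelCoords(pixelFeatures(ImageVolume(m), cfg)), c(7L, 7L))
  expect_true(all(med >= apply(stack, 1, min)[lin]))
  expect_true(all(med <= apply(stack, 1, max)[lin]))
})

test_that("label augmentation joins per-coordinate values", {
  img <- ImageVolume(matrix(rnorm(36), 6, 6))
  tab <- pixelFeatures(img, featureConfig(3, normalize = FALSE))
  zero <- augmentWithLabels(tab, LabelMap(matrix(0L, 6, 6)))
  expect_true(all(featureMatrix(zero)[, "label"] == 0))
  set.seed(4)
  lab <- matrix(sample(0:1, 36, replace = TRUE), 6, 6)
  aug <- augmentWithLabels(tab, LabelMap(lab))
  co <- pixelCoords(aug)
  expect_equal(featureMatrix(aug)[, "label"], lab[cbind(co[, 1], co[, 2])])
  # applying twice yields two label columns
  aug2 <- augmentWithLabels(aug, LabelMap(lab))
  expect_identical(sum(colnames(featureMatrix(aug2)) == "label"), 2L)
  expect_error(augmentWithLabels(tab, LabelMap(matrix(0L, 5, 5))), "match")
})
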