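test_that("noiseless phantoms place exact tissue means and honor contrast", {
  cfg <- phantomConfig(noiseSd = 0, biasAmplitude = 0, seed = 2)
  case <- generateCase(cfg)
  tr <- imageData(truth(case))
  means <- defaultTissueMeans()
  for (mod in c("T1", "T1CE", "T2", "FLAIR")) {
    img <- imageData(volumes(case)[[mod]])
    # edema voxels hold exactly the configured mean in the noiseless limit
    expect_true(all(img[tr == 2L] == means[mod, "ED"]))
    expect_true(all(img[tr == 4L] == means[mod, "ET"]))
  }
  fl <- imageData(volumes(case)$FLAIR)
  t1c <- imageData(volumes(case)$T1CE)
  # FLAIR-bright edema, T1CE-bright enhancing core
  expect_gt(mean(fl[tr == 2L]), mean(fl[tr == 0L & fl != 0]))
  expect_gt(mean(t1c[tr == 4L]), mean(t1c[tr == 1L]))
})

test_that("generation is deterministic per (config, seed)", {
  cfg <- phantomConfig(noiseSd = 0.4, biasAmplitude = 0.2, seed = 11)
  a <- generateCase(cfg); b <- generateCase(cfg)
  for (mod in names(volumes(a)))
    expect_identical(imageData(volumes(a)[[mod]]), imageData(volumes(b)[[mod]]))
  expect_identical(imageData(truth(a)), imageData(truth(b)))
})

test_that("whole-tumor extent matches the configured edema ellipse", {
  case <- generateCase(phantomConfig(seed = 4))  # 64x64, ED semi-axes (10, 8)
  count <- sum(imageData(binarizeWholeTumor(truth(case))))
  expect_lt(abs(count - pi * 10 * 8) / (pi * 10 * 8), 0.05)
})

test_that("subregion nesting holds on every generated case", {
  cohort <- generateCohort(5, tinyPhantomConfig(noiseSd = 0.3), seed = 21)
  for (case in cohort) {
    tr <- imageData(truth(case))
    core <- tr == 1L | tr == 4L
    whole <- tr != 0L
    expect_true(all(whole[core]))          # core within whole tumor
    expect_true(all(dim(tr) == dim(imageData(volumes(case)$T1))))
  }
})

test_that("cohorts are reproducible, sized, and jittered", {
  base <- tinyPhantomConfig()
  expect_length(generateCohort(1, base, seed = 5), 1L)
  a <- generateCohort(4, base, seed = 6)
  b <- generateCohort(4, base, seed = 6)
  for (i in seq_along(a))
    expect_identical(imageData(volumes(a[[i]])$T2), imageData(volumes(b[[i]])$T2))
  # distinct tumor centers: truth centroids differ pairwise
  cents <- vapply(generateCohort(10, base, seed = 7), function(cs) {
    w <- which(imageData(truth(cs)) != 0L, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2))
  expect_identical(nrow(unique(t(cents))), 10L)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantomConfig(radii = rbind(NCR = c(5, 4), ET = c(4, 3),
                                           NET = c(7, 6), ED = c(10, 8))),
               "nested")
  expect_error(phantomConfig(biasAmplitude = 1.2), "biasAmplitude")
})
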