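test_that("confusion counts match hand tallies and the brute-force oracle", {
  allT <- LabelMap(matrix(1L, 2, 2))
  c1 <- confusionCounts(allT, allT)
  expect_identical(c(c1@tp, c1@fp, c1@tn, c1@fn), c(4, 0, 0, 0))
  comp <- LabelMap(matrix(0L, 2, 2))
  c2 <- confusionCounts(comp, allT)
  expect_identical(c(c2@tp, c2@tn), c(0, 0))
  for (seed in 1:5) {
    set.seed(seed)
    p <- matrix(sample(0:1, 16, TRUE), 4, 4)
    t <- matrix(sample(0:1, 16, TRUE), 4, 4)
    got <- confusionCounts(LabelMap(p), LabelMap(t))
    want <- oracleConfusion(as.vector(p), as.vector(t))
    expect_identical(c(got@tp, got@fp, got@tn, got@fn), unname(want))
    expect_identical(got@tp + got@fp + got@tn + got@fn, 16)
  }
  expect_error(confusionCounts(LabelMap(matrix(0L, 2, 2)),
                               LabelMap(matrix(0L, 3, 3))), "mismatch")
  expect_error(confusionCounts(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("the three indices follow their confusion-count formulas", {
  expect_identical(dsc(ConfusionCounts(1, 0, 0, 0)), 1)
  expect_equal(dsc(ConfusionCounts(3, 1, 10, 2)), 6 / 9)
  expect_identical(dsc(ConfusionCounts(0, 5, 10, 0)), 0)
  expect_message(d0 <- dsc(ConfusionCounts(0, 0, 10, 0)), "defined as 1")
  expect_identical(d0, 1)
  expect_equal(sensitivity(ConfusionCounts(4, 0, 0, 1)), 0.8)
  expect_identical(sensitivity(ConfusionCounts(3, 2, 1, 0)), 1)
  expect_identical(sensitivity(ConfusionCounts(0, 1, 1, 2)), 0)
  expect_message(sNA <- sensitivity(ConfusionCounts(0, 1, 5, 0)), "undefined")
  expect_true(is.na(sNA))
  expect_equal(specificity(ConfusionCounts(1, 1, 9, 1)), 0.9)
  expect_identical(specificity(ConfusionCounts(2, 0, 7, 1)), 1)
  expect_identical(specificity(ConfusionCounts(2, 3, 0, 1)), 0)
  expect_message(pNA <- specificity(ConfusionCounts(5, 0, 0, 5)), "undefined")
  expect_true(is.na(pNA))
})

test_that("DSC equals the set-overlap identity and swap symmetries hold", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(sample(0:1, 64, TRUE, prob = c(0.7, 0.3)), 8, 8)
    t <- matrix(sample(0:1, 64, TRUE, prob = c(0.7, 0.3)), 8, 8)
    cnt <- confusionCounts(LabelMap(p), LabelMap(t))
    inter <- sum(p == 1 & t == 1)
    if (sum(p) + sum(t) > 0)
      expect_equal(dsc(cnt), 2 * inter / (sum(p) + sum(t)))
    swapped <- confusionCounts(LabelMap(t), LabelMap(p))
    expect_equal(dsc(swapped), dsc(cnt))
    # swapping pred and truth transposes fp and fn
    expect_identical(c(swapped@tp, swapped@fp, swapped@fn),
                     c(cnt@tp, cnt@fn, cnt@fp))
  }
})

test_that("cohort reports average per-case rows and keep them", {
  rows <- data.frame(case_id = c("a", "b"), dsc = c(0.5, 1.0),
                     sensitivity = c(0.8, 0.9), specificity = c(1, 1))
  rep <- cohortReport(rows)
  expect_equal(rep@dsc, 0.75)
  expect_identical(rep@nCases, 2L)
  single <- cohortReport(rows[1, ])
  expect_equal(single@dsc, rows$dsc[1])
  # permutation invariance and a second summation order on 26 seeded rows
  set.seed(26)
  big <- data.frame(case_id = sprintf("p%02d", 1:26), dsc = runif(26, 0.7, 0.95),
                    sensitivity = runif(26, 0.7, 0.95),
                    specificity = runif(26, 0.9, 1))
  r1 <- cohortReport(big)
  r2 <- cohortReport(big[sample(26), ])
  expect_equal(r1@dsc, r2@dsc)
  expect_equal(r1@dsc, sum(rev(sort(big$dsc))) / 26)
  # undefined entries are excluded with a message
  rows$sensitivity[2] <- NA
  expect_message(r3 <- cohortReport(rows), "excluded")
  expect_equal(r3@sensitivity, 0.8)
  expect_error(cohortReport(rows[0, ]), "at least one")
})

test_that("relative improvement is percent change at one decimal", {
  expect_equal(relativeImprovement(0.8958, 0.8268), 8.3)
  expect_equal(relativeImprovement(0.9110, 0.8306), 9.7)
  expect_equal(relativeImprovement(0.42, 0.42), 0)
  expect_equal(relativeImprovement(0.7, 0.8), -12.5)
  expect_error(relativeImprovement(0.9, 0), "positive")
})
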