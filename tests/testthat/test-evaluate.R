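mkTruth <- function(B = c(0, 0, 0), eL = c(-14, 40, -23),
                    eR = c(14, 40, -23))
  list(B = B, eyeLeft = eL, eyeRight = eR)

test_that("the success criterion applies the 1.2 x OD radius per labelled eye", {
  tr <- mkTruth()
  det <- c(tr, labeled = TRUE)
  expect_true(successCriterion(det, tr, od = 14))
  off <- det
  off$eyeLeft <- det$eyeLeft + c(1.3 * 14, 0, 0)
  expect_false(successCriterion(off, tr, od = 14))
  near <- det
  near$eyeLeft <- det$eyeLeft + c(1.1 * 14, 0, 0)
  expect_true(successCriterion(near, tr, od = 14))
})

test_that("swapped labels fail strictly but pass label-agnostic", {
  tr <- mkTruth()
  swapped <- list(B = tr$B, eyeLeft = tr$eyeRight, eyeRight = tr$eyeLeft,
                  labeled = TRUE)
  expect_false(successCriterion(swapped, tr, od = 14))
  expect_true(successCriterion(swapped, tr, od = 14, agnostic = TRUE))
})

test_that("rotation error recovers exact constructed rotations", {
  tr <- mkTruth()
  expect_equal(rotationError(c(tr, labeled = TRUE), tr)$dR, 0,
               tolerance = 1e-9)

  Rz <- FetalScout:::eulerXYZToRotation(c(0, 0, pi / 2))
  rot <- list(B = as.numeric(Rz %*% tr$B),
              eyeLeft = as.numeric(Rz %*% tr$eyeLeft),
              eyeRight = as.numeric(Rz %*% tr$eyeRight), labeled = TRUE)
  re <- rotationError(rot, tr)
  expect_equal(re$dR, 90, tolerance = 1e-6)
  expect_equal(unname(re$perAxis["z"]), 90, tolerance = 1e-6)
  expect_lt(re$perAxis[["x"]] + re$perAxis[["y"]], 1e-6)
})

test_that("rotation error equals the applied angle for random rotations", {
  set.seed(66)
  tr <- mkTruth()
  for (i in 1:100) {
    R <- FetalScout:::randomRotation()
    rot <- list(B = as.numeric(R %*% tr$B),
                eyeLeft = as.numeric(R %*% tr$eyeLeft),
                eyeRight = as.numeric(R %*% tr$eyeRight), labeled = TRUE)
    want <- rotationAngleDeg(R)
    expect_equal(rotationError(rot, tr)$dR, want, tolerance = 1e-6)
  }
})

test_that("rotation error is bi-invariant under a common pre-rotation", {
  set.seed(3)
  tr <- mkTruth()
  R <- FetalScout:::randomRotation()
  det <- list(B = tr$B + c(2, 1, -1), eyeLeft = tr$eyeLeft + c(-1, 2, 0),
              eyeRight = tr$eyeRight + c(0, -2, 1), labeled = TRUE)
  base <- rotationError(det, tr)$dR
  pre <- function(lm) list(B = as.numeric(R %*% lm$B),
                           eyeLeft = as.numeric(R %*% lm$eyeLeft),
                           eyeRight = as.numeric(R %*% lm$eyeRight),
                           labeled = TRUE)
  expect_equal(rotationError(pre(det), pre(tr))$dR, base, tolerance = 1e-9)
})

test_that("degenerate triangles are rejected", {
  bad <- list(B = c(0, 0, 0), eyeLeft = c(1, 0, 0), eyeRight = c(2, 0, 0),
              labeled = TRUE)
  expect_error(rotationError(bad, bad), "degenerate")
})

test_that("translation error is Euclidean with a consistent axis split", {
  tr <- mkTruth()
  det <- c(tr, labeled = TRUE)
  expect_equal(unname(translationError(det, tr)$dT), rep(0, 3))
  det$B <- tr$B + c(3, 4, 0)
  te <- translationError(det, tr)
  expect_equal(unname(te$dT["B"]), 5)
  expect_equal(sum(te$perAxisB^2), unname(te$dT["B"])^2, tolerance = 1e-12)
})

test_that("cohort reports summarize successes with the standard rows", {
  tr <- mkTruth()
  perfect <- evaluateDetection(c(tr, labeled = TRUE), tr, od = 14)
  rep1 <- cohortReport(list(perfect))
  expect_equal(rep1$successRate, 1)
  expect_equal(rep1$stats[rep1$stats$Statistic == "Mean", "dR"], 0)
  expect_identical(rep1$stats$Statistic,
                   c("Minimum", "Maximum", "Mean", "SD"))

  det2 <- c(tr, labeled = TRUE)
  det2$B <- tr$B + c(4, 0, 0)
  two <- cohortReport(list(perfect, evaluateDetection(det2, tr, od = 14)))
  expect_equal(two$stats[two$stats$Statistic == "Mean", "dT_B"], 2)
  f <- tempfile(fileext = ".tsv")
  cohortReport(list(perfect), path = f)
  expect_true(file.exists(f))
  expect_identical(read.delim(f)$Statistic,
                   c("Minimum", "Maximum", "Mean", "SD"))
})
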