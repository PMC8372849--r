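mkCand <- function(centroid, support = 4L)
  list(centroid = centroid, sliceSupport = as.integer(support))

test_that("pair error reproduces the closed-form worked examples", {
  ofd <- 96; od <- 14; B <- c(0, 0, 0); dIo <- 2 * od
  # both eyes at OFD/2 from B, separated by dIo, full slice support
  c1 <- mkCand(c(-od, sqrt((ofd / 2)^2 - od^2), 0))
  c2 <- mkCand(c(od, sqrt((ofd / 2)^2 - od^2), 0))
  e0 <- pairError(c1, c2, B, ofd, od, lambda = 4, dIo = dIo, sMax = 4L)
  expect_equal(as.numeric(e0), 0, tolerance = 1e-12)

  # distances 0.6 x OFD and 0.4 x OFD, all other terms still zero
  u1 <- 0.6 * ofd; u2 <- 0.4 * ofd
  a1 <- c(0, u1, 0)
  yy <- (u1^2 + u2^2 - 2 * u1 * (u1 - (u1^2 - u2^2 + dIo^2) / (2 * u1))) # scratch
  y2 <- (u2^2 - dIo^2 + u1^2) / (2 * u1)
  x2 <- sqrt(u2^2 - y2^2)
  a2 <- c(x2, y2, 0)
  expect_equal(sqrt(sum(a2^2)), u2, tolerance = 1e-9)
  expect_equal(sqrt(sum((a2 - a1)^2)), dIo, tolerance = 1e-9)
  e1 <- pairError(mkCand(a1), mkCand(a2), B, ofd, od, lambda = 4, dIo = dIo,
                  sMax = 4L)
  expect_equal(as.numeric(e1), 2 * 4 * 0.2, tolerance = 1e-9)

  # only the slice-support term: s_j = s_k = s_max / 2
  e2 <- pairError(mkCand(c1$centroid, 2L), mkCand(c2$centroid, 2L), B, ofd,
                  od, lambda = 4, dIo = dIo, sMax = 4L)
  expect_equal(as.numeric(e2), 0.5, tolerance = 1e-12)
})

test_that("pair error is symmetric and rigid-motion invariant", {
  set.seed(14)
  B <- c(10, -4, 7)
  c1 <- mkCand(B + rnorm(3, sd = 30), 3L)
  c2 <- mkCand(B + rnorm(3, sd = 30), 5L)
  e12 <- pairError(c1, c2, B, 96, 14, sMax = 6L)
  e21 <- pairError(c2, c1, B, 96, 14, sMax = 6L)
  expect_equal(as.numeric(e12), as.numeric(e21), tolerance = 1e-12)

  R <- FetalScout:::randomRotation()
  t <- c(100, -50, 20)
  mv <- function(p) as.numeric(R %*% p + t)
  eR <- pairError(mkCand(mv(c1$centroid), 3L), mkCand(mv(c2$centroid), 5L),
                  mv(B), 96, 14, sMax = 6L)
  expect_equal(as.numeric(e12), as.numeric(eR), tolerance = 1e-9)

  same <- pairError(c1, mkCand(c1$centroid), B, 96, 14, sMax = 6L)
  expect_identical(as.numeric(same), Inf)
})

test_that("selectEyes scans all pairs and returns the minimum", {
  ofd <- 96; od <- 14; B <- c(0, 0, 0)
  good1 <- mkCand(c(-od, sqrt(48^2 - od^2), 0), 4L)
  good2 <- mkCand(c(od, sqrt(48^2 - od^2), 0), 4L)
  decoy1 <- mkCand(c(0, -60, 0), 1L)
  decoy2 <- mkCand(c(50, 0, 30), 2L)
  pair <- selectEyes(list(decoy1, good1, decoy2, good2), B,
                     c(ofd = ofd, bpd = 79, od = od))
  got <- rbind(pair@E1, pair@E2)
  expect_true(any(apply(got, 1, function(p)
    sqrt(sum((p - good1$centroid)^2)) < 1e-9)))
  expect_true(any(apply(got, 1, function(p)
    sqrt(sum((p - good2$centroid)^2)) < 1e-9)))

  two <- selectEyes(list(decoy1, decoy2), B, c(ofd = ofd, bpd = 79, od = od))
  expect_equal(two@E1, decoy1$centroid)
  expect_error(selectEyes(list(good1), B, c(ofd = ofd, bpd = 79, od = od)),
               "fewer than 2")
})

test_that("eye clustering follows the 0.75 x OD radius rule", {
  ph <- cleanPhantom()
  biom <- biomAt(31)
  res <- detectEyeCandidates(ph$volume, ph$truth@bTrue, biom)
  expect_gte(length(res$candidates), 2L)
  # two candidates centred within 0.5 x OD of the true eyes
  dL <- vapply(res$candidates, function(cl)
    sqrt(sum((clusterCentroid(cl) - ph$truth@eLeftTrue)^2)), numeric(1))
  dR <- vapply(res$candidates, function(cl)
    sqrt(sum((clusterCentroid(cl) - ph$truth@eRightTrue)^2)), numeric(1))
  expect_lt(min(dL), 0.5 * biom[["od"]])
  expect_lt(min(dR), 0.5 * biom[["od"]])
  # no candidate mixes the two eyes (they are 2 x OD apart)
  for (cl in res$candidates) {
    bary <- do.call(rbind, lapply(cl@members, `[[`, "barycenterWorld"))
    spread <- max(dist(bary))
    expect_lt(spread, 1.5 * biom[["od"]])
  }
})

test_that("the true eye pair beats decoy pairs on a decoy phantom", {
  ph <- generatePhantom(phantomSpec(ga = 31, noiseSigma = 0, decoys = 3L,
                                    seed = 17))
  res <- detectHeadPose(ph$volume, 31)
  expect_true(res@success)
  biom <- biomAt(31)
  expect_true(successCriterion(res, ph$truth, biom[["od"]], agnostic = TRUE))
})
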