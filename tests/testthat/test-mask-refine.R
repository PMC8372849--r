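test_that("the local search box has side sqrt(2) x OFD", {
  vol <- volumeGrid(array(0, c(80, 80, 60)), c(3, 3, 3))
  ofd <- 96
  rng <- FetalScout:::worldBoxToVoxelRanges(vol, c(120, 120, 90),
                                            sqrt(2) * ofd)
  for (ax in 1:2) {
    span <- (length(rng[[ax]]) - 1) * 3
    expect_lt(abs(span - sqrt(2) * ofd), 2 * 3)   # within a voxel each side
  }
})

test_that("brain-mask stage excludes regions beyond 1.1 x OFD/2", {
  biom <- c(ofd = 96, bpd = 79, od = 14)
  near <- fakeRegion(a = 60, b = 50, bary = c(0.5 * 96 / 2, 0, 0))
  far <- fakeRegion(a = 60, b = 50, bary = c(0.6 * 96, 0, 0))  # dNorm 1.2
  kept <- applyFilters(list(near, far), filterStage("brain_mask"), biom,
                       brainCenter = c(0, 0, 0))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$barycenterWorld[1], 24)
})

test_that("a local search with no detectable regions is a pure union", {
  vol <- volumeGrid(array(0, c(40, 40, 30)), c(3, 3, 3))
  biom <- c(ofd = 96, bpd = 79, od = 14)
  M <- array(FALSE, c(40, 40, 30)); M[18:22, 18:22, 14:16] <- TRUE
  out <- localBrainSearch(vol, c(60, 60, 45), biom, pipelineConfig(), M)
  expect_identical(out, M)
})

## Centred 3-row rectangle stacks: a 3 x n rectangle's fitted major axis is
## exactly (4 / sqrt(12)) * n * spacing, so integer length profiles give
## slice axes that sit *exactly* on a chosen curve (no rasterization noise).
rectMask <- function(lengths, dims = c(60, 120, length(lengths)), sp = 3) {
  m <- array(FALSE, dims)
  for (k in seq_along(lengths)) {
    n <- lengths[k]
    if (n <= 0) next
    cols <- (dims[2] / 2 - n / 2 + 1):(dims[2] / 2 + n / 2)
    m[29:31, cols, k] <- TRUE
  }
  m
}

test_that("axes exactly on a concave parabola are left untouched", {
  k <- 1:12
  len <- 40 + 13 * k - k^2          # even integers, exactly concave in k
  m <- rectMask(len)
  out <- parabolaPrune(m, c(3, 3, 3), zPoly = 1.5, axis = 3L)
  expect_identical(out, m)
})

test_that("an oversized marginal slice is pruned; convex fits never prune", {
  k <- 1:12
  len <- 40 + 13 * k - k^2
  len[seq(2, 12, 2)] <- len[seq(2, 12, 2)] + 2   # jitter so the SD is > 0
  len[1] <- len[1] + 20                           # far off the fit
  m <- rectMask(len)
  out <- parabolaPrune(m, c(3, 3, 3), zPoly = 1.5, axis = 3L)
  expect_false(any(out[, , 1]))
  expect_true(any(out[, , 6]))

  convex <- rectMask(90 - 13 * k + k^2)
  expect_identical(parabolaPrune(convex, c(3, 3, 3), 1.5, 3L), convex)
})

test_that("pruning needs at least 4 slices, keeps the largest-axis slice, and is idempotent", {
  thin <- rectMask(c(40, 60, 40))
  expect_identical(parabolaPrune(thin, c(3, 3, 3), 1.5, 3L), thin)

  k <- 1:12
  len <- 40 + 13 * k - k^2
  len[seq(2, 12, 2)] <- len[seq(2, 12, 2)] + 2
  peak <- which.max(len)
  len[peak] <- len[peak] + 30        # oversized *peak* slice
  m <- rectMask(len)
  once <- parabolaPrune(m, c(3, 3, 3), 1.5, 3L)
  expect_true(any(once[, , peak]))   # guard: never drop the largest axis
  expect_identical(parabolaPrune(once, c(3, 3, 3), 1.5, 3L), once)
})

test_that("the 3D ellipsoid fit recovers constructed shapes", {
  vol <- volumeGrid(array(0, c(60, 60, 60)), c(2, 2, 2))
  vox <- as.matrix(expand.grid(1:60, 1:60, 1:60))
  w <- FetalScout:::voxelToWorld(vol, vox)
  ctr <- c(59, 59, 59)
  semi <- c(45, 35, 35)
  cw <- sweep(w, 2, ctr)
  mask <- array(rowSums(sweep(cw, 2, semi, `/`)^2) <= 1, c(60, 60, 60))
  ell <- fitEllipsoid(mask, vol)
  expect_lt(max(abs(ell@axes - c(90, 70, 70)) / c(90, 70, 70)), 0.05)
  angle <- acos(min(1, abs(ell@axisDirs[1, 1]))) * 180 / pi
  expect_lt(angle, 5)
  expect_equal(ell@center, maskBarycenter(mask, vol), tolerance = 1e-9)

  ball <- array(rowSums(cw^2) <= 40^2, c(60, 60, 60))
  eb <- fitEllipsoid(ball, vol)
  expect_lt(diff(range(eb@axes)) / mean(eb@axes), 0.02)

  R <- FetalScout:::rotationAboutAxis(c(0, 0, 1), 35 * pi / 180)
  cwr <- cw %*% R                       # rotate the sampling frame
  rot <- array(rowSums(sweep(cwr, 2, semi, `/`)^2) <= 1, c(60, 60, 60))
  er <- fitEllipsoid(rot, vol)
  want <- as.numeric(R[, 1])
  got <- er@axisDirs[, 1]
  ang <- acos(min(1, abs(sum(want * got)))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("coplanar masks cannot be fitted", {
  vol <- volumeGrid(array(0, c(20, 20, 20)), c(2, 2, 2))
  slab <- array(FALSE, c(20, 20, 20)); slab[5:15, 5:15, 10] <- TRUE
  expect_error(fitEllipsoid(slab, vol), "degenerate")
})
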