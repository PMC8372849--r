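test_that("mean shift finds the expected modes", {
  p1 <- matrix(c(10, 20, 30), 1)
  m <- meanShiftModes(p1, kernelFwhm = 40, gridSpacing = 20, tol = 1)
  expect_equal(nrow(m), 1L)
  expect_lt(sqrt(sum((m[1, ] - p1)^2)), 1)

  set.seed(4)
  g1 <- matrix(rnorm(15, sd = 0.5), 5, 3)
  g2 <- sweep(matrix(rnorm(15, sd = 0.5), 5, 3), 2, c(160, 0, 0), `+`)
  m2 <- meanShiftModes(rbind(g1, g2), kernelFwhm = 40, gridSpacing = 20,
                       tol = 1)
  expect_equal(nrow(m2), 2L)
  expect_lt(sqrt(sum((m2[1, ] - colMeans(g1))^2)), 1)
  expect_lt(sqrt(sum((m2[2, ] - colMeans(g2))^2)), 1)

  seg <- cbind(seq(-2, 2, length.out = 9), 0, 0)   # 0.1 x FWHM segment
  m3 <- meanShiftModes(seg, kernelFwhm = 40, gridSpacing = 20, tol = 1)
  expect_equal(nrow(m3), 1L)
  expect_lt(sqrt(sum((m3[1, ] - c(0, 0, 0))^2)), 1)
})

test_that("mean-shift modes are translation invariant", {
  set.seed(12)
  pts <- matrix(rnorm(30, sd = 10), 10, 3)
  shift <- c(55, -30, 12)
  m1 <- meanShiftModes(pts, 48, 24, tol = 0.5)
  m2 <- meanShiftModes(sweep(pts, 2, shift, `+`), 48, 24, tol = 0.5)
  expect_equal(nrow(m1), nrow(m2))
  expect_lt(max(abs(sweep(m2, 2, shift) - m1)), 0.5)
})

test_that("membership follows the strict 0.5 x OFD radius rule", {
  ofd <- 96
  mkReg <- function(bary) {
    r <- fakeRegion(a = 50, b = 40, bary = bary)
    r$voxels <- cbind(1L, 1L, 1L)
    r
  }
  modes <- matrix(c(0, 0, 0), 1)
  inReg <- mkReg(c(0.49 * ofd, 0, 0))
  onReg <- mkReg(c(0.50 * ofd, 0, 0))
  cl <- assignMembers(list(inReg, onReg), modes, ofd, c(4, 4, 4))
  expect_length(cl, 1L)
  expect_length(cl[[1]]@members, 1L)

  modes2 <- rbind(c(0, 0, 0), c(30, 0, 0))
  both <- mkReg(c(15, 0, 0))
  cl2 <- assignMembers(list(both), modes2, ofd, c(4, 4, 4))
  expect_length(cl2, 2L)   # a region may join multiple clusters
})

test_that("fill factor rewards ellipsoidal masks and penalises half masks", {
  vol <- volumeGrid(array(0, c(40, 40, 40)), c(2, 2, 2))
  vox <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  w <- FetalScout:::voxelToWorld(vol, vox)
  ctr <- c(39, 39, 39)
  m2 <- rowSums(sweep(w, 2, ctr)^2 / rep(c(30, 20, 20)^2, each = nrow(w)))
  full <- array(m2 <= 1, c(40, 40, 40))
  Ffull <- fillFactor(full, vol)
  expect_gte(Ffull, 0.9 * sum(full))

  half <- full & array(w[, 1] <= ctr[1], c(40, 40, 40))
  Fhalf <- fillFactor(half, vol)
  expect_lt(Fhalf / sum(half), 0.8)     # refit ellipsoid leaks past the cut
  expect_lt(Fhalf, Ffull)
})

test_that("degenerate masks get the -Inf sentinel", {
  vol <- volumeGrid(array(0, c(10, 10, 10)), c(1, 1, 1))
  tiny <- array(FALSE, c(10, 10, 10)); tiny[cbind(1:3, 1, 1)] <- TRUE
  expect_identical(fillFactor(tiny, vol), -Inf)
  slab <- array(FALSE, c(10, 10, 10)); slab[, , 5] <- TRUE
  expect_identical(fillFactor(slab, vol), -Inf)
})

test_that("brain selection prefers the ellipsoidal cluster and fails cleanly", {
  vol <- volumeGrid(array(0, c(40, 40, 40)), c(2, 2, 2))
  vox <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  w <- FetalScout:::voxelToWorld(vol, vox)
  ball <- array(rowSums(sweep(w, 2, c(30, 30, 30))^2) <= 18^2, c(40, 40, 40))
  flat <- array(FALSE, c(40, 40, 40)); flat[30:39, 30:39, 20:21] <- TRUE
  mkCl <- function(mask, ctr) new("RegionCluster",
                                  members = list(fakeRegion(10, 8)),
                                  centroid = ctr, mask = mask,
                                  sliceSupport = 3L)
  got <- selectBrain(list(mkCl(flat, c(60, 60, 40)), mkCl(ball, c(30, 30, 30))),
                     vol)
  expect_equal(clusterCentroid(got), c(30, 30, 30))
  single <- list(mkCl(ball, c(30, 30, 30)))
  expect_identical(selectBrain(single, vol), single[[1]])
  expect_error(selectBrain(list(), vol), "brain not found")
})

test_that("slice regularization fills holes, bridges gaps, trims protrusions", {
  m <- array(FALSE, c(9, 9, 5))
  disk <- diskPixels(c(5, 5), 3, c(9, 9))
  for (k in c(1, 2, 4, 5)) m[cbind(disk, k)] <- TRUE
  m[5, 5, 2] <- FALSE                      # interior hole
  m[1, 1, 4] <- TRUE                       # protrusion off the disk
  out <- regularizeSlices(m, axis = 3L)
  expect_true(out[5, 5, 2])                # hole filled
  expect_true(all(out[cbind(disk, 3)]))    # empty slice 3 = disk & disk
  expect_false(out[1, 1, 4])               # protrusion removed
})

test_that("regularization is idempotent on stacked-ellipse masks", {
  set.seed(77)
  for (trial in 1:10) {
    m <- array(FALSE, c(24, 24, 10))
    for (k in sample(1:10, 7)) {
      n <- sample(1:3, 1)
      for (j in seq_len(n)) {
        ctr <- runif(2, 6, 18); semi <- runif(2, 2, 6)
        m[cbind(ellipsePixels(ctr, semi, c(24, 24)), k)] <- TRUE
      }
    }
    once <- regularizeSlices(m, 3L)
    twice <- regularizeSlices(once, 3L)
    expect_identical(once, twice)
  }
})

test_that("mask barycentre is the world-mm centroid", {
  vol <- volumeGrid(array(0, c(21, 21, 21)), c(2, 2, 2))
  vox <- as.matrix(expand.grid(1:21, 1:21, 1:21))
  w <- FetalScout:::voxelToWorld(vol, vox)
  ball <- array(rowSums(sweep(w, 2, c(20, 20, 20))^2) <= 10^2, c(21, 21, 21))
  expect_lt(max(abs(maskBarycenter(ball, vol) - c(20, 20, 20))), 1)
  two <- array(FALSE, c(21, 21, 21)); two[1, 1, 1] <- TRUE; two[3, 1, 1] <- TRUE
  expect_equal(maskBarycenter(two, vol), c(2, 0, 0))
  expect_error(maskBarycenter(array(FALSE, c(3, 3, 3)), vol), "empty")
})
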