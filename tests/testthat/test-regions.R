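test_that("moment ellipse recovers a disk and an elongated ellipse", {
  dims <- c(40, 40)
  disk <- list(pixels = diskPixels(c(20, 20), 10, dims))   # radius 10 mm
  f <- fitEllipse(disk, c(1, 1), dims)
  expect_lt(abs(f$a - 20) / 20, 0.03)
  expect_lt(abs(f$b - 20) / 20, 0.03)
  expect_gte(f$D, 0.98)
  expect_equal(f$A, pi * (f$a / 2) * (f$b / 2), tolerance = 1e-9)

  ell <- list(pixels = ellipsePixels(c(20, 20), c(16, 8), dims))
  f2 <- fitEllipse(ell, c(1, 1), dims)
  expect_lt(abs(f2$a / f2$b - 2), 0.1)
})

test_that("a region equal to its own fitted ellipse raster has Dice 1", {
  dims <- c(40, 40)
  reg <- list(pixels = diskPixels(c(20, 20), 9, dims))
  for (i in 1:10) {                 # iterate region -> raster fixpoint
    f <- fitEllipse(reg, c(1, 1), dims)
    Sinv <- solve(f$Sigma)
    g <- as.matrix(expand.grid(r = 1:dims[1], c = 1:dims[2]))
    gm <- sweep(g - 1, 2, f$center)
    nxt <- g[rowSums((gm %*% Sinv) * gm) <= 4, , drop = FALSE]
    if (identical(regionKey(list(pixels = nxt)), regionKey(reg))) break
    reg <- list(pixels = nxt)
  }
  f <- fitEllipse(reg, c(1, 1), dims)
  expect_equal(f$D, 1)
})

test_that("ellipse axes scale linearly with voxel spacing", {
  dims <- c(40, 40)
  reg <- list(pixels = ellipsePixels(c(20, 20), c(12, 6), dims))
  f1 <- fitEllipse(reg, c(1, 1), dims)
  f2 <- fitEllipse(reg, c(2, 2), dims)
  expect_equal(f2$a / f1$a, 2, tolerance = 1e-6)
  expect_equal(f2$b / f1$b, 2, tolerance = 1e-6)
})

test_that("degenerate collinear regions are floored and flagged", {
  reg <- list(pixels = cbind(10, 5:25))
  f <- fitEllipse(reg, c(1, 1), c(40, 40))
  expect_true(f$degenerate)
  expect_gte(f$b, 0.5)
})

test_that("local contrast matches constructed medians", {
  dims <- c(41, 41)
  disk <- list(pixels = diskPixels(c(21, 21), 6, dims))
  uni <- matrix(100, dims[1], dims[2])
  expect_equal(localContrast(disk, uni, c(1, 1)), 1)
  img <- matrix(100, dims[1], dims[2])
  img[disk$pixels] <- 300
  expect_equal(localContrast(disk, img, c(1, 1)), 3)
})

test_that("a ribbon entirely outside the slice rejects the region", {
  slice <- matrix(1, 3, 10)
  reg <- list(pixels = as.matrix(expand.grid(r = 1:3, c = 1:10)))
  expect_true(is.na(localContrast(reg, slice, c(1, 1))))
})

test_that("the printed filter-bank examples behave as specified", {
  biom <- c(ofd = 96, bpd = 79, od = 14)
  stA <- filterStage("brain_localize")
  stB <- filterStage("brain_mask")
  stC <- filterStage("eye")

  ideal <- fakeRegion(a = 96, b = 79, D = 1)   # every ratio exactly 1
  expect_length(applyFilters(list(ideal), stA, biom), 1L)

  tooLong <- fakeRegion(a = 1.15 * 96, b = 79, D = 1,
                        A = pi * 48 * 39.5)    # only the axis is off
  expect_length(applyFilters(list(tooLong), stA, biom), 0L)

  small <- fakeRegion(a = 60, b = 49, D = 1, A = 0.10 * pi * 48 * 39.5)
  expect_length(applyFilters(list(small), stA, biom), 0L)    # min 0.2
  expect_length(applyFilters(list(small), stB, biom,
                             brainCenter = c(0, 0, 0)), 1L)  # min 0.05

  dimEye <- fakeRegion(a = 14, b = 14, D = 1, contrast = 1.5,
                       bary = c(48, 0, 0))
  expect_length(applyFilters(list(dimEye), stC, biom,
                             brainCenter = c(0, 0, 0)), 0L)  # C min 2
  brightEye <- fakeRegion(a = 14, b = 14, D = 1, contrast = 2.5,
                          bary = c(48, 0, 0))
  expect_length(applyFilters(list(brightEye), stC, biom,
                             brainCenter = c(0, 0, 0)), 1L)
})

test_that("distance bounds require a brain centre; biometry is mandatory", {
  biom <- c(ofd = 96, bpd = 79, od = 14)
  reg <- fakeRegion(a = 14, b = 14, contrast = 3)
  expect_error(applyFilters(list(reg), filterStage("eye"), biom),
               "brainCenter")
  expect_error(applyFilters(list(reg), filterStage("eye"), c(foo = 1)),
               "biometry")
})

test_that("loosening any single bound never shrinks the kept set", {
  set.seed(31)
  biom <- c(ofd = 96, bpd = 79, od = 14)
  regs <- lapply(1:40, function(i) {
    a <- runif(1, 40, 130)
    fakeRegion(a = a, b = a / runif(1, 1, 2.2),
               A = runif(1, 0.02, 1.4) * pi * 48 * 39.5,
               D = runif(1, 0.5, 1),
               bary = c(runif(1, 0, 70), 0, 0), contrast = runif(1, 1, 4))
  })
  keptName <- function(kept) vapply(kept, function(r) r$fit$a, numeric(1))
  base <- filterStage("brain_mask")
  kept0 <- keptName(applyFilters(regs, base, biom, brainCenter = c(0, 0, 0)))
  looser <- list(filterStage("brain_mask", areaMin = 0.01),
                 filterStage("brain_mask", areaMax = 2),
                 filterStage("brain_mask", aspectMax = 3),
                 filterStage("brain_mask", majorMax = 2),
                 filterStage("brain_mask", diceMin = 0.2),
                 filterStage("brain_mask", dMax = 3))
  for (st in looser) {
    kept1 <- keptName(applyFilters(regs, st, biom, brainCenter = c(0, 0, 0)))
    expect_true(all(kept0 %in% kept1))
  }
})
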