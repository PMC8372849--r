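test_that("frame construction matches the axis-aligned example", {
  fr <- buildFrame(c(0, 0, 0), c(-10, 20, 0), c(10, 20, 0))
  expect_equal(fr@PA, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr@LR, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr@IS, c(0, 0, 1), tolerance = 1e-12)

  sw <- buildFrame(c(0, 0, 0), c(10, 20, 0), c(-10, 20, 0))
  expect_equal(sw@LR, -fr@LR, tolerance = 1e-12)
  expect_equal(sw@IS, -fr@IS, tolerance = 1e-12)
  expect_equal(sw@PA, fr@PA, tolerance = 1e-12)
})

test_that("non-perpendicular landmarks still give an exact orthonormal basis", {
  E1 <- c(-10, 18, 2); E2 <- c(10, 22, -2)   # LR0 not orthogonal to PA
  fr <- buildFrame(c(0, 0, 0), E1, E2)
  R <- cbind(fr@LR, fr@PA, fr@IS)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
  LR0 <- (E2 - E1) / sqrt(sum((E2 - E1)^2))
  expect_gt(acos(min(1, sum(fr@LR * LR0))), 0)
  expect_lt(abs(sum(fr@LR * fr@PA)), 1e-12)
})

test_that("collinear landmarks are rejected", {
  expect_error(buildFrame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("the tilt rotates PA by theta about an unchanged LR", {
  fr <- buildFrame(c(0, 0, 0), c(-10, 20, 0), c(10, 20, 0))
  expect_identical(applyTilt(fr, 0), fr)
  t30 <- applyTilt(fr, 30)
  expect_equal(t30@LR, fr@LR, tolerance = 1e-12)
  ang <- acos(min(1, sum(t30@PA * fr@PA))) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-9)
  expect_lte(sum(t30@IS * fr@PA), 0)       # IS moved away from the eyes

  t15x2 <- applyTilt(applyTilt(fr, 15), 15)
  expect_equal(t15x2@PA, t30@PA, tolerance = 1e-9)
  expect_equal(t15x2@IS, t30@IS, tolerance = 1e-9)
})

canonicalScene <- function(flipInput = FALSE) {
  B <- c(0, 0, 0)
  eL <- c(-14, 40, -23); eR <- c(14, 40, -23)
  ell <- new("BrainEllipsoid", center = B, axes = c(90, 73, 73),
             axisDirs = cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)))
  E1 <- if (flipInput) eR else eL
  E2 <- if (flipInput) eL else eR
  list(frame = buildFrame(B, E1, E2), ell = ell, E1 = E1, E2 = E2, B = B,
       eL = eL, eR = eR)
}

test_that("left-right resolution labels the +LR eye as the right eye", {
  for (flip in c(FALSE, TRUE)) {
    sc <- canonicalScene(flip)
    fr <- resolveLeftRight(sc$frame, sc$ell, sc$E1, sc$E2, sc$B)
    expect_identical(fr@labels, "resolved")
    expect_equal(fr@eyeLeft, sc$eL, tolerance = 1e-9)
    expect_equal(fr@eyeRight, sc$eR, tolerance = 1e-9)
    expect_gt(sum(fr@IS * c(0, 0, 1)), 0)  # IS away from the inferior eyes
    expect_equal(det(cbind(fr@LR, fr@PA, fr@IS)), 1, tolerance = 1e-9)
  }
})

test_that("a spherical brain ellipsoid yields the ambiguous path", {
  sc <- canonicalScene()
  ball <- new("BrainEllipsoid", center = sc$B, axes = c(80, 79, 78),
              axisDirs = diag(3))
  fr <- resolveLeftRight(sc$frame, ball, sc$E1, sc$E2, sc$B)
  expect_identical(fr@labels, "ambiguous")
  aligned <- new("BrainEllipsoid", center = sc$B, axes = c(90, 73, 73),
                 axisDirs = cbind(sc$frame@LR, c(0, 1, 0), c(0, 0, 1)))
  expect_identical(resolveLeftRight(sc$frame, aligned, sc$E1, sc$E2,
                                    sc$B)@labels, "ambiguous")
})

test_that("resolve-then-tilt equals tilt-then-resolve", {
  sc <- canonicalScene()
  a <- applyTilt(resolveLeftRight(sc$frame, sc$ell, sc$E1, sc$E2, sc$B), 30)
  b <- resolveLeftRight(applyTilt(sc$frame, 30), sc$ell, sc$E1, sc$E2, sc$B)
  expect_equal(a@LR, b@LR, tolerance = 1e-9)
  expect_equal(a@PA, b@PA, tolerance = 1e-9)
  expect_equal(a@IS, b@IS, tolerance = 1e-9)
  expect_identical(a@labels, b@labels)
})

test_that("the world-to-anatomical transform is rigid and eye-symmetric", {
  fr <- buildFrame(c(0, 0, 0), c(-10, 20, 0), c(10, 20, 0))
  tf <- frameToTransform(fr)
  expect_equal(tf$transform[1:3, 1:3], diag(3), tolerance = 1e-12)
  sc <- canonicalScene()
  fr2 <- sc$frame
  T <- frameToTransform(fr2)$transform
  a1 <- T %*% c(sc$E1, 1); a2 <- T %*% c(sc$E2, 1)
  expect_equal(a1[3], a2[3], tolerance = 1e-9)   # same anatomical z
  R <- T[1:3, 1:3]
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
})
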