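## Shared fixtures and small utilities for the suite. Heavy phantoms are
## generated once and memoised.

regionKey <- function(r)
  paste(sort(r$pixels[, 1] * 1e5 + r$pixels[, 2]), collapse = ",")

sameRegionSets <- function(a, b) {
  identical(sort(vapply(a, regionKey, character(1))),
            sort(vapply(b, regionKey, character(1))))
}

## filled disk as pixel set on a grid (1-based indices)
diskPixels <- function(centerPx, radiusPx, dims) {
  g <- as.matrix(expand.grid(r = seq_len(dims[1]), c = seq_len(dims[2])))
  d <- sqrt((g[, 1] - centerPx[1])^2 + (g[, 2] - centerPx[2])^2)
  g[d <= radiusPx, , drop = FALSE]
}

## filled ellipse pixel set (axis-aligned, semi-axes in px)
ellipsePixels <- function(centerPx, semiPx, dims) {
  g <- as.matrix(expand.grid(r = seq_len(dims[1]), c = seq_len(dims[2])))
  d <- ((g[, 1] - centerPx[1]) / semiPx[1])^2 +
       ((g[, 2] - centerPx[2]) / semiPx[2])^2
  g[d <= 1, , drop = FALSE]
}

## a fake filtered-region record with a hand-set ellipse fit
fakeRegion <- function(a, b, A = pi * (a / 2) * (b / 2), D = 0.95,
                       bary = c(0, 0, 0), contrast = NA_real_,
                       sliceIndex = 1L) {
  V <- diag(2)
  Sigma <- V %*% diag((c(a, b) / 4)^2) %*% t(V)
  list(pixels = cbind(1:3, 1:3), sliceIndex = sliceIndex,
       level = 100L, stability = 0.1, area = 9L, seed = 1L,
       barycenterWorld = bary, voxels = cbind(1:3, 1:3, sliceIndex),
       contrast = contrast,
       fit = list(center = c(0, 0), a = a, b = b, orientation = 0,
                  A = A, D = D, Sigma = Sigma, degenerate = FALSE))
}

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtureCache[[name]]))
    assign(name, expr, envir = .fixtureCache)
  .fixtureCache[[name]]
}

cleanPhantom <- function()
  fixture("cleanPhantom",
          generatePhantom(phantomSpec(ga = 31, noiseSigma = 0, seed = 3)))

cleanDetection <- function()
  fixture("cleanDetection", detectHeadPose(cleanPhantom()$volume, 31))

biomAt <- function(ga) lookupBiometry(biometryTable(), ga)

rotationAngleDeg <- function(R)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
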