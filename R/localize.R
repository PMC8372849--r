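## Global brain search: mean-shift clustering of MSER barycentres across
## slices, fill-factor ranking, slice-wise mask regularization, and the
## brain centre.

#' Mean-shift mode seeking
#'
#' Gaussian-kernel mean-shift over 3D points: a regular grid of starting
#' points is laid over the points' bounding box and every start is
#' iterated with the kernel-weighted mean update until its displacement
#' falls below `tol`; converged points closer than `10 * tol` are merged.
#' The kernel FWHM is `0.5 x OFD` in the pipeline, matching the spatial
#' scale of the fetal brain.
#'
#' @param points n x 3 matrix of world-mm points.
#' @param kernelFwhm Gaussian kernel FWHM in mm.
#' @param gridSpacing spacing of the start grid in mm.
#' @param tol convergence tolerance in mm.
#' @param maxIter iteration cap.
#' @return k x 3 matrix of modes (lexicographically sorted); zero rows when
#'   there are no points.
#' @export
meanShiftModes <- function(points, kernelFwhm, gridSpacing = kernelFwhm,
                           tol = 1, maxIter = 100L) {
  points <- matrix(points, ncol = 3L)
  if (nrow(points) == 0L) return(matrix(numeric(0), 0, 3))
  sigma <- fwhmToSigma(kernelFwhm)
  lo <- apply(points, 2, min); hi <- apply(points, 2, max)
  gr <- lapply(1:3, function(ax) {
    s <- seq(lo[ax], hi[ax], by = gridSpacing)
    if (s[length(s)] < hi[ax] - 1e-9) s <- c(s, hi[ax])
    s
  })
  P <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
  active <- rep(TRUE, nrow(P))
  for (it in seq_len(maxIter)) {
    if (!any(active)) break
    A <- P[active, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(points^2), `+`) -
      2 * A %*% t(points)
    d2 <- d2 - apply(d2, 1, min)            # rescale for stability
    w <- exp(-d2 / (2 * sigma^2))
    Pnew <- (w %*% points) / rowSums(w)
    moved <- sqrt(rowSums((Pnew - A)^2))
    P[active, ] <- Pnew
    active[active] <- moved >= tol * 1e-3   # keep iterating until near-fixed
    if (max(moved) < tol * 1e-3) break
  }
  # merge converged points closer than 10 * tol (single linkage)
  merged <- rep(NA_integer_, nrow(P))
  modes <- list()
  for (i in seq_len(nrow(P))) {
    hit <- NA_integer_
    for (j in seq_along(modes)) {
      if (sqrt(sum((P[i, ] - modes[[j]]$rep)^2)) < 10 * tol) { hit <- j; break }
    }
    if (is.na(hit)) {
      modes[[length(modes) + 1L]] <- list(rep = P[i, ], pts = list(P[i, ]))
    } else {
      modes[[hit]]$pts <- c(modes[[hit]]$pts, list(P[i, ]))
    }
  }
  M <- do.call(rbind, lapply(modes, function(m)
    colMeans(do.call(rbind, m$pts))))
  M[order(M[, 1], M[, 2], M[, 3]), , drop = FALSE]
}

#' Assign regions to cluster modes
#'
#' A region joins every cluster whose mode lies within `0.5 x OFD` of its
#' barycentre (strictly); clusters with no members are dropped. The
#' fill-factor ranking disambiguates multi-membership downstream.
#'
#' @param regions list of `ExtremalRegion` records with `barycenterWorld`
#'   and `voxels` (n x 3 voxel indices on the parent grid).
#' @param modes k x 3 matrix from [meanShiftModes()].
#' @param ofd occipitofrontal diameter in mm.
#' @param dims integer(3) parent grid dimensions (for the cluster masks).
#' @return List of \linkS4class{RegionCluster}.
#' @export
assignMembers <- function(regions, modes, ofd, dims) {
  if (length(regions) == 0L || nrow(modes) == 0L) return(list())
  bary <- do.call(rbind, lapply(regions, `[[`, "barycenterWorld"))
  out <- list()
  for (j in seq_len(nrow(modes))) {
    d <- sqrt(rowSums(sweep(bary, 2, modes[j, ])^2))
    sel <- which(d < 0.5 * ofd)
    if (!length(sel)) next
    members <- regions[sel]
    mask <- array(FALSE, dims)
    for (m in members) mask[m$voxels] <- TRUE
    support <- length(unique(vapply(members, `[[`, integer(1), "sliceIndex")))
    out[[length(out) + 1L]] <- new("RegionCluster", members = members,
                                   centroid = as.numeric(modes[j, ]),
                                   mask = mask,
                                   sliceSupport = as.integer(support))
  }
  out
}

## Moment fit of a 3D ellipsoid to mask voxels, in world mm. Returns NULL
## for degenerate masks (< minVox voxels or coplanar).
.momentEllipsoid <- function(mask, affine, minVox = 4L) {
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) < minVox) return(NULL)
  A3 <- affine[1:3, 1:3]
  w <- t(A3 %*% t(vox - 1)) + rep(affine[1:3, 4], each = nrow(vox))
  ctr <- colMeans(w)
  cw <- sweep(w, 2, ctr)
  rawCov <- crossprod(cw) / nrow(w)
  if (min(eigen(rawCov, symmetric = TRUE, only.values = TRUE)$values) < 1e-9)
    return(NULL)                            # coplanar voxel set
  Sigma <- rawCov + A3 %*% diag(1 / 12, 3) %*% t(A3)
  eg <- eigen(Sigma, symmetric = TRUE)
  semi <- sqrt(5 * pmax(eg$values, 1e-12))  # solid-ellipsoid moment match
  list(center = ctr, semi = semi, V = eg$vectors, Sigma = Sigma)
}

## Voxels of the parent grid inside the fitted ellipsoid (Mahalanobis^2 <= 5).
.ellipsoidVoxels <- function(fit, dims, affine) {
  Ainv <- solve(affine)
  cvox <- (Ainv[1:3, 1:3] %*% fit$center + Ainv[1:3, 4])[, 1] + 1
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  r <- ceiling(fit$semi[1] / sp) + 1
  rng <- lapply(1:3, function(ax)
    max(1, floor(cvox[ax] - r[ax])):min(dims[ax], ceiling(cvox[ax] + r[ax])))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  if (!nrow(g)) return(g)
  A3 <- affine[1:3, 1:3]
  w <- t(A3 %*% t(g - 1)) + rep(affine[1:3, 4], each = nrow(g))
  cw <- sweep(w, 2, fit$center)
  Sinv <- solve(fit$Sigma)
  m2 <- rowSums((cw %*% Sinv) * cw)
  g[m2 <= 5, , drop = FALSE]
}

#' Fill factor of a cluster mask
#'
#' `F = |M intersect E| - |E \\ M|`, where `E` is the set of grid voxels
#' inside the 3D ellipsoid moment-fitted to the binary mask `M`. Rewards
#' masks that fill their own fitted ellipsoid, i.e. near-ellipsoidal 3D
#' shapes such as the fetal brain. Degenerate masks (fewer than 4
#' non-coplanar voxels) return `-Inf` so they are never selected.
#'
#' @param cluster a \linkS4class{RegionCluster} or a 3D logical array.
#' @param vol the parent \linkS4class{VolumeGrid} (for voxel geometry).
#' @return Signed voxel count.
#' @export
fillFactor <- function(cluster, vol) {
  mask <- if (is(cluster, "RegionCluster")) clusterMask(cluster) else cluster
  fit <- .momentEllipsoid(mask, voxelAffine(vol))
  if (is.null(fit)) return(-Inf)
  E <- .ellipsoidVoxels(fit, dim(mask), voxelAffine(vol))
  if (!nrow(E)) return(-Inf)
  inMask <- mask[E]
  sum(inMask) - sum(!inMask)
}

#' Select the brain cluster
#'
#' The cluster with the largest fill factor; ties broken by larger mask,
#' then by smaller third world coordinate of the centroid.
#'
#' @param clusters list of \linkS4class{RegionCluster}.
#' @param vol the parent \linkS4class{VolumeGrid}.
#' @return The winning \linkS4class{RegionCluster}.
#' @export
selectBrain <- function(clusters, vol) {
  if (length(clusters) == 0L) detectionFailure("brain not found")
  F <- vapply(clusters, fillFactor, numeric(1), vol = vol)
  if (all(!is.finite(F))) detectionFailure("brain not found")
  sz <- vapply(clusters, function(cl) sum(clusterMask(cl)), numeric(1))
  cz <- vapply(clusters, function(cl) clusterCentroid(cl)[3], numeric(1))
  ord <- order(-F, -sz, cz)
  clusters[[ord[1]]]
}

.fillHoles2D <- function(m) {
  f <- EBImage::fillHull(matrix(as.numeric(m), nrow(m), ncol(m)))
  matrix(as.numeric(f) > 0, nrow(m), ncol(m))
}

#' Regularize a 3D mask slice by slice
#'
#' Three passes, in order, applied once: (1) morphological 2D hole filling
#' within each slice; (2) interior empty slices are filled with the
#' intersection of the nearest non-empty slice on each side; (3)
#' protrusion removal — a voxel is kept iff it is present on the nearest
#' non-empty slice on at least one side (computed simultaneously from the
#' pre-pass state).
#'
#' @param mask 3D logical array.
#' @param axis slice axis (default 3).
#' @return Regularized mask of the same shape.
#' @export
regularizeSlices <- function(mask, axis = 3L) {
  perm <- c(setdiff(1:3, axis), axis)
  m <- aperm(mask, perm)
  nz <- dim(m)[3]

  for (k in seq_len(nz))
    if (any(m[, , k])) m[, , k] <- .fillHoles2D(m[, , k])

  ne <- which(vapply(seq_len(nz), function(k) any(m[, , k]), logical(1)))
  if (length(ne) >= 2L) {
    gaps <- setdiff(seq(min(ne), max(ne)), ne)
    for (k in gaps) {
      below <- max(ne[ne < k]); above <- min(ne[ne > k])
      m[, , k] <- m[, , below] & m[, , above]
    }
  }

  m <- .removeProtrusions(m)
  aperm(m, order(perm))
}

#' Barycentre of a binary mask in world mm
#'
#' @param mask 3D logical array (nonempty).
#' @param vol the parent \linkS4class{VolumeGrid} (or a 4x4 affine).
#' @return numeric(3) world-mm point.
#' @export
maskBarycenter <- function(mask, vol) {
  affine <- if (is(vol, "VolumeGrid")) voxelAffine(vol) else vol
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0L) stop("mask is empty")
  w <- t(affine[1:3, 1:3] %*% t(vox - 1)) + rep(affine[1:3, 4],
                                                each = nrow(vox))
  colMeans(w)
}
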