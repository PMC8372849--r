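#' Construct a VolumeGrid
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric(3) voxel size in mm.
#' @param affine optional 4x4 voxel (0-based) -> world-mm matrix; defaults to
#'   `diag(spacing)` with the first voxel centre at the origin.
#' @param sliceAxis optional slice axis (1-3). By default the axis with the
#'   largest spacing; for an isotropic volume the third axis.
#' @return A \linkS4class{VolumeGrid}.
#' @export
volumeGrid <- function(intensities, spacing, affine = NULL, sliceAxis = NULL) {
  intensities <- array(as.double(intensities), dim(intensities))
  spacing <- as.numeric(spacing)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
  }
  if (is.null(sliceAxis)) {
    sliceAxis <- if (max(spacing) - min(spacing) < 1e-9) 3L
                 else which.max(spacing)
  }
  new("VolumeGrid", intensities = intensities, spacing = spacing,
      affine = affine, sliceAxis = as.integer(sliceAxis))
}

#' Read a NIfTI volume
#'
#' @param path path to a NIfTI-1/2 file.
#' @param sliceAxis optional override of the inferred slice axis.
#' @return A \linkS4class{VolumeGrid}.
#' @export
readVolume <- function(path, sliceAxis = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI file '%s': %s",
                                 path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s' is not a 3D volume (found %d dimensions)",
                 path, length(d)))
  spacing <- RNifti::pixdim(img)[1:3]
  aff <- structure(RNifti::xform(img), class = "matrix")
  volumeGrid(as.array(img), spacing, matrix(aff, 4, 4), sliceAxis)
}

#' Write a VolumeGrid as NIfTI
#'
#' @param vol a \linkS4class{VolumeGrid}.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(intensities(vol))
  RNifti::pixdim(img) <- voxelSpacing(vol)   # before the xforms: scale source
  RNifti::qform(img) <- structure(voxelAffine(vol), code = 2L)
  RNifti::sform(img) <- structure(voxelAffine(vol), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## Voxel (1-based index rows) -> world mm.
voxelToWorld <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3L)
  A <- voxelAffine(vol)
  t(A[1:3, 1:3] %*% t(idx - 1)) + rep(A[1:3, 4], each = nrow(idx))
}

## World mm -> continuous 0-based voxel coordinates.
worldToVoxel0 <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3L)
  A <- voxelAffine(vol)
  Ainv <- solve(A)
  t(Ainv[1:3, 1:3] %*% t(pts)) + rep(Ainv[1:3, 4], each = nrow(pts))
}

## Trilinear interpolation at continuous 0-based voxel coordinates.
interpTrilinear <- function(arr, vox, fill = 0) {
  d <- dim(arr)
  n <- nrow(vox)
  f0 <- floor(vox)
  fr <- vox - f0
  out <- numeric(n)
  wsum <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- f0[, 1] + dx; jj <- f0[, 2] + dy; kk <- f0[, 3] + dz
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    inb <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1 &
           kk >= 0 & kk <= d[3] - 1
    sel <- inb & w > 0
    if (any(sel)) {
      lin <- ii[sel] + d[1] * (jj[sel] + d[2] * kk[sel]) + 1
      out[sel] <- out[sel] + w[sel] * arr[lin]
      wsum[sel] <- wsum[sel] + w[sel]
    }
  }
  miss <- wsum < 1 - 1e-9
  out[miss] <- out[miss] + (1 - wsum[miss]) * fill
  out
}

#' Resample an axis-aligned cubic box from a volume
#'
#' Extracts a cube of side `side` mm centred on a world point, trilinearly
#' interpolated onto an isotropic grid. Samples outside the source
#' field of view take `fill`.
#'
#' @param vol a \linkS4class{VolumeGrid}.
#' @param center numeric(3) world-mm box centre.
#' @param side box side length in mm (> 0).
#' @param isoSpacing isotropic target spacing in mm (> 0).
#' @param fill out-of-field fill value.
#' @return A \linkS4class{VolumeGrid} holding the cube; its slice axis is the
#'   world axis corresponding to the source slice axis.
#' @export
resampleBox <- function(vol, center, side, isoSpacing, fill = 0) {
  stopifnot(side > 0, isoSpacing > 0)
  d <- dim(intensities(vol))
  corners <- voxelToWorld(vol, as.matrix(expand.grid(
    c(1, d[1]), c(1, d[2]), c(1, d[3]))))
  lo <- apply(corners, 2, min) - voxelSpacing(vol) / 2
  hi <- apply(corners, 2, max) + voxelSpacing(vol) / 2
  if (any(center < lo | center > hi))
    warning("box centre lies outside the volume; proceeding with fill value")
  n <- max(2L, as.integer(round(side / isoSpacing)) + 1L)
  off <- (seq_len(n) - (n + 1) / 2) * isoSpacing
  g <- as.matrix(expand.grid(x = off, y = off, z = off))
  pts <- g + rep(center, each = nrow(g))
  vox <- worldToVoxel0(vol, pts)
  vals <- interpTrilinear(intensities(vol), vox, fill = fill)
  arr <- array(vals, dim = c(n, n, n))
  aff <- diag(4)
  diag(aff)[1:3] <- isoSpacing
  aff[1:3, 4] <- center + off[1]
  worldAxis <- which.max(abs(voxelAffine(vol)[1:3, sliceAxis(vol)]))
  volumeGrid(arr, rep(isoSpacing, 3), aff, sliceAxis = worldAxis)
}

## Voxel-index ranges of an axis-aligned world box (clamped to the grid).
## Assumes an affine without in-plane/through-plane mixing beyond axis
## permutations and flips (true for scanner-aligned scouts and all grids the
## package creates).
worldBoxToVoxelRanges <- function(vol, center, side) {
  half <- side / 2
  corners <- as.matrix(expand.grid(center[1] + c(-half, half),
                                   center[2] + c(-half, half),
                                   center[3] + c(-half, half)))
  vox <- worldToVoxel0(vol, corners) + 1   # 1-based
  d <- dim(intensities(vol))
  lapply(1:3, function(ax) {
    lo <- max(1L, as.integer(ceiling(min(vox[, ax]) - 1e-6)))
    hi <- min(d[ax], as.integer(floor(max(vox[, ax]) + 1e-6)))
    if (lo > hi) integer(0) else lo:hi
  })
}

## Extract slice k along the volume's slice axis as a matrix, together with
## the in-plane axes and spacing.
getSlice <- function(vol, k, ranges = NULL) {
  ax <- sliceAxis(vol)
  inPlane <- setdiff(1:3, ax)
  idx <- if (is.null(ranges)) lapply(dim(intensities(vol)), seq_len)
         else ranges
  idx[[ax]] <- k
  m <- intensities(vol)[idx[[1]], idx[[2]], idx[[3]], drop = TRUE]
  m <- matrix(m, nrow = length(idx[[inPlane[1]]]),
              ncol = length(idx[[inPlane[2]]]))
  list(data = m, inPlaneAxes = inPlane,
       spacing = voxelSpacing(vol)[inPlane],
       offset = c(idx[[inPlane[1]]][1], idx[[inPlane[2]]][1]))
}

## Map in-slice pixel indices (rows: r, c; 1-based, relative to an optional
## offset) on slice k to world mm.
slicePixelsToWorld <- function(vol, pixels, k, inPlaneAxes, offset = c(1, 1)) {
  ax <- sliceAxis(vol)
  idx <- matrix(0, nrow(pixels), 3)
  idx[, inPlaneAxes[1]] <- pixels[, 1] + offset[1] - 1
  idx[, inPlaneAxes[2]] <- pixels[, 2] + offset[2] - 1
  idx[, ax] <- k
  voxelToWorld(vol, idx)
}
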