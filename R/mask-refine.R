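## Local exhaustive brain search around the global estimate, parabola-based
## pruning of marginal mask slices, and the 3D brain ellipsoid whose major
## axis later resolves the left-right ambiguity.

#' Local brain search
#'
#' Re-runs MSER detection on partial slices within an axis-aligned box of
#' side `sqrt(2) x OFD` centred on the brain, filters with the brain-mask
#' stage (including the distance-from-brain bound), and unions the
#' surviving regions' voxels with the global-stage mask.
#'
#' @param vol the scout \linkS4class{VolumeGrid}.
#' @param B world-mm brain centre from the global search.
#' @param biometry named vector from [lookupBiometry()].
#' @param config a \linkS4class{PipelineConfig}.
#' @param globalMask 3D logical array from the global stage (same grid).
#' @return The augmented 3D logical mask.
#' @export
localBrainSearch <- function(vol, B, biometry, config = pipelineConfig(),
                             globalMask = NULL) {
  if (is.null(globalMask)) globalMask <- array(FALSE, dim(intensities(vol)))
  side <- sqrt(2) * biometry[["ofd"]]
  ranges <- worldBoxToVoxelRanges(vol, B, side)
  det <- detectRegionsOnVolume(vol, config, ranges = ranges)
  kept <- applyFilters(det$regions, filterStage("brain_mask"), biometry,
                       brainCenter = B)
  mask <- globalMask
  for (reg in kept) mask[reg$voxels] <- TRUE
  mask
}

## 1D morphological hole filling along the third (canonical slice) axis.
.fillColumns1D <- function(m) {
  nz <- dim(m)[3]
  fwd <- m; bwd <- m
  for (k in 2:nz) fwd[, , k] <- fwd[, , k] | fwd[, , k - 1]
  for (k in (nz - 1):1) bwd[, , k] <- bwd[, , k] | bwd[, , k + 1]
  fwd & bwd
}

## Protrusion removal (canonical slice axis 3): voxel kept iff present on
## the nearest non-empty slice on at least one side; frozen input state.
.removeProtrusions <- function(m) {
  nz <- dim(m)[3]
  ne <- which(vapply(seq_len(nz), function(k) any(m[, , k]), logical(1)))
  if (length(ne) < 2L) return(m)
  frozen <- m
  for (k in ne) {
    lower <- ne[ne < k]; upper <- ne[ne > k]
    keep <- array(FALSE, dim(m)[1:2])
    if (length(lower)) keep <- keep | frozen[, , max(lower)]
    if (length(upper)) keep <- keep | frozen[, , min(upper)]
    m[, , k] <- frozen[, , k] & keep
  }
  m
}

#' Parabola-based pruning of marginal mask slices
#'
#' Fits a parabola to the per-slice major ellipse axes of the central 50\%
#' of non-empty slices, converts the signed deviation of every slice's
#' axis from the fit to z-scores (dispersion taken from the central-slice
#' residuals), and removes slices with `z > zPoly` — slices whose cross
#' section is too large for a profile that rises to a maximum and falls
#' again, e.g. amniotic-fluid regions beyond the skull. This is only done
#' when the parabola is concave, so a bad fit never removes slices; the
#' genuinely tapering marginal slices of the brain sit below the fit and
#' are kept. Gaps left by the pruning are closed by 1D hole filling along
#' the slice axis, followed by protrusion removal.
#'
#' @param mask 3D logical array spanning >= 4 non-empty slices (fewer:
#'   returned unchanged).
#' @param spacing numeric(3) voxel size in mm.
#' @param zPoly z-score threshold (default 1.5).
#' @param axis slice axis (default 3).
#' @return Pruned mask.
#' @export
parabolaPrune <- function(mask, spacing, zPoly = 1.5, axis = 3L) {
  perm <- c(setdiff(1:3, axis), axis)
  m <- aperm(mask, perm)
  spIn <- spacing[perm[1:2]]
  nz <- dim(m)[3]
  ne <- which(vapply(seq_len(nz), function(k) any(m[, , k]), logical(1)))
  if (length(ne) < 4L) return(mask)

  axes <- vapply(ne, function(k) {
    pix <- which(m[, , k], arr.ind = TRUE)
    if (nrow(pix) < 3L) return(max(spIn))
    fitEllipse(list(pixels = pix), spIn)$a
  }, numeric(1))

  k <- length(ne)
  ncent <- floor(k / 4)
  centralIdx <- seq.int(ncent + 1L, k - ncent)
  if (length(centralIdx) >= 3L) {
    z <- ne
    df <- data.frame(a = axes, z = z, z2 = z^2)
    fit <- lm(a ~ z + z2, data = df[centralIdx, ])
    concave <- coef(fit)[["z2"]] < 0
    if (concave) {
      res <- axes - predict(fit, newdata = df)
      sdc <- sd(res[centralIdx])
      zscore <- if (sdc > 1e-9) res / sdc
                else ifelse(res < 1e-9, 0, Inf)   # signed: only oversized

      drop <- setdiff(ne[zscore > zPoly], ne[which.max(axes)])
      for (kk in drop) m[, , kk] <- FALSE
      if (any(m)) {
        m <- .fillColumns1D(m)
        m <- .removeProtrusions(m)
      }
    }
  }
  aperm(m, order(perm))
}

#' Fit a 3D ellipsoid to the brain mask
#'
#' Moment-based fit: eigendecomposition of the second central moments of
#' the mask voxels in world mm (with the per-voxel uniform moment added),
#' axes scaled to match a solid ellipsoid. The centre is the updated brain
#' centre; the major axis direction feeds the left-right disambiguation.
#'
#' @param mask 3D logical array with >= 10 non-coplanar voxels.
#' @param vol the parent \linkS4class{VolumeGrid}.
#' @return A \linkS4class{BrainEllipsoid}.
#' @export
fitEllipsoid <- function(mask, vol) {
  fit <- .momentEllipsoid(mask, voxelAffine(vol), minVox = 10L)
  if (is.null(fit))
    detectionFailure("brain mask too degenerate for an ellipsoid fit")
  ord <- order(fit$semi, decreasing = TRUE)
  semi <- fit$semi[ord]
  V <- fit$V[, ord, drop = FALSE]
  for (j in 1:3) {                          # deterministic eigenvector signs
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  new("BrainEllipsoid", center = fit$center, axes = 2 * semi, axisDirs = V)
}
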