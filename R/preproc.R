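## Per-slice intensity flattening and dark-edge enhancement ahead of MSER
## detection. All kernels are parameterized by FWHM in mm and converted to
## per-axis pixel sigmas (sigma = FWHM / (2 sqrt(2 ln 2))), mirrored
## boundaries, kernel radius >= 3 sigma.

#' Flatten slice intensities
#'
#' Divides a slice by a heavily blurred version of itself, removing
#' low-frequency coil/bias shading so that level sets of the brain and eyes
#' survive across intensity thresholds. A small guard
#' `eps = 1e-6 * max(slice)` keeps the division finite; an all-zero slice
#' maps to all zeros.
#'
#' @param slice 2D numeric matrix.
#' @param spacing numeric(2) in-plane voxel size (mm).
#' @param fNU Gaussian FWHM of the blur in mm (default 20).
#' @return Matrix of the same size.
#' @export
flattenIntensity <- function(slice, spacing, fNU = 20) {
  stopifnot(fNU > 0)
  spacing <- rep_len(spacing, 2L)
  mx <- max(slice)
  eps <- 1e-6 * if (mx > 0) mx else 1
  bl <- gaussBlur2D(slice, fwhmToSigma(fNU) / spacing)
  slice / (bl + eps)
}

#' Difference-of-Gaussian edge weights
#'
#' Computes `d = blur(slice, f1) - blur(slice, f2)`, clips negatives to
#' zero, rescales to `[0, 1]` and inverts, so that dark rims around bright
#' structures (the fetal skull) are down-weighted the least and bright-blob
#' interiors keep weight near 1. A constant slice (degenerate rescale)
#' returns weights identically 1.
#'
#' @param slice 2D numeric matrix.
#' @param spacing numeric(2) in-plane voxel size (mm).
#' @param f1 outer Gaussian FWHM in mm (default 10).
#' @param f2 inner Gaussian FWHM in mm (default 5); must satisfy f1 > f2.
#' @return Matrix of weights in `[0, 1]`.
#' @export
dogEdgeWeights <- function(slice, spacing, f1 = 10, f2 = 5) {
  stopifnot(f1 > f2, f2 > 0)
  spacing <- rep_len(spacing, 2L)
  d <- gaussBlur2D(slice, fwhmToSigma(f1) / spacing) -
       gaussBlur2D(slice, fwhmToSigma(f2) / spacing)
  d[d < 0] <- 0
  rng <- range(d)
  if (rng[2] - rng[1] < 1e-12 * max(1, abs(rng[2])))
    return(array(1, dim(slice)))
  1 - (d - rng[1]) / (rng[2] - rng[1])
}

#' Prepare one slice for MSER detection
#'
#' Multiplies the flattened slice by the difference-of-Gaussian edge
#' weights (computed on a copy of the *original* slice). The product is the
#' image the MSER detector runs on; it is invariant under global intensity
#' scaling of the input.
#'
#' @param slice 2D numeric matrix.
#' @param spacing numeric(2) in-plane voxel size (mm).
#' @param config a \linkS4class{PipelineConfig}.
#' @return List with elements `flattened`, `weights`, `product`.
#' @export
prepareSlice <- function(slice, spacing, config = pipelineConfig()) {
  stopifnot(all(is.finite(slice)))
  fl <- flattenIntensity(slice, spacing, config@fNU)
  w <- dogEdgeWeights(slice, spacing, config@f1, config@f2)
  structure(list(flattened = fl, weights = w, product = fl * w),
            class = "PreparedSlice")
}
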