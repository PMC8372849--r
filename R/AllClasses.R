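## Central S4 containers. Lightweight per-region records (ExtremalRegion) are
## plain lists with class "ExtremalRegion"; see mser.R.

#' VolumeGrid: a 3D scalar volume with voxel geometry
#'
#' Holds the scout image (or a binary mask) as a 3D array together with the
#' per-axis voxel size in mm and the voxel-index -> world-mm affine. Voxel
#' indices are 1-based in R; a voxel's world position is the position of its
#' centre, `affine %*% c(i-1, j-1, k-1, 1)`.
#'
#' @slot intensities 3D numeric array.
#' @slot spacing numeric(3), voxel size per axis in mm (all > 0).
#' @slot affine 4x4 voxel->world matrix (invertible; world units mm).
#' @slot sliceAxis integer in 1..3, the acquisition-slice dimension.
#' @aliases intensities voxelSpacing voxelAffine sliceAxis
#' @export
setClass("VolumeGrid", representation(
  intensities = "array", spacing = "numeric", affine = "matrix",
  sliceAxis = "integer"
))

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)) ||
      abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(object@sliceAxis) != 1L || !(object@sliceAxis %in% 1:3))
    msg <- c(msg, "sliceAxis must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' @rdname VolumeGrid-class
#' @export
setMethod("intensities", "VolumeGrid", function(x) x@intensities)
#' @rdname VolumeGrid-class
#' @export
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname VolumeGrid-class
#' @export
setMethod("voxelAffine", "VolumeGrid", function(x) x@affine)
#' @rdname VolumeGrid-class
#' @export
setMethod("sliceAxis", "VolumeGrid", function(x) x@sliceAxis)

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VolumeGrid: %d x %d x %d voxels, spacing %s mm, slice axis %d\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              object@sliceAxis))
  invisible(object)
})

#' PipelineConfig: tunable parameters of the detection pipeline
#'
#' Defaults are the operating point of the method: Gaussian FWHMs
#' `fNU = 20`, `f1 = 10`, `f2 = 5` mm for intensity flattening and the
#' difference-of-Gaussian edge weights; `zPoly = 1.5` for parabola-based
#' slice pruning; `lambda = 4` weighting the eye-symmetry term of the pair
#' error; `thetaDeg = 30` for the eye-plane tilt; clustering radii
#' `fClustFactor = 0.5` (x OFD, mean-shift kernel) and `rhoClustFactor =
#' 0.75` (x OD, eye clustering); success radius `rhoSuccessFactor = 1.2`
#' (x OD). MSER parameters (`mserDelta`, `mserMinArea`, `mserMaxAreaFrac`,
#' `mserMaxVariation`, `mserMinDiversity`) are deliberately loose: the
#' anatomical filter banks do the real selection.
#'
#' @slot fNU,f1,f2 Gaussian FWHMs in mm.
#' @slot zPoly z-score threshold for slice pruning.
#' @slot lambda weight of the eye-symmetry term in the pair error.
#' @slot thetaDeg tilt of the \{B, E1, E2\} plane from the axial plane (deg).
#' @slot rhoClustFactor eye clustering radius as a fraction of OD.
#' @slot rhoSuccessFactor success radius as a fraction of OD.
#' @slot fClustFactor mean-shift kernel FWHM as a fraction of OFD.
#' @slot mserDelta stability delta on the quantized (<= 256 level) scale.
#' @slot mserMinArea minimum region area in pixels.
#' @slot mserMaxAreaFrac maximum region area as a fraction of the slice.
#' @slot mserMaxVariation maximum relative growth rate.
#' @slot mserMinDiversity nested-duplicate suppression threshold.
#' @slot msGridFactor mean-shift start-grid spacing as a fraction of OFD.
#' @slot msTolMm mean-shift convergence tolerance (mm).
#' @slot msMaxIter mean-shift iteration cap.
#' @slot dIoFactor expected eye-separation reference as a multiple of OD.
#' @slot eyeIsoFactor eye-box resampling, fraction of the in-plane voxel size.
#' @slot fillValue out-of-field fill value for resampling.
#' @slot tiltSign +1 or -1; flips the tilt convention.
#' @slot seed integer seed (reserved for stochastic extensions; the
#'   detection itself is deterministic).
#' @export
setClass("PipelineConfig", representation(
  fNU = "numeric", f1 = "numeric", f2 = "numeric",
  zPoly = "numeric", lambda = "numeric", thetaDeg = "numeric",
  rhoClustFactor = "numeric", rhoSuccessFactor = "numeric",
  fClustFactor = "numeric",
  mserDelta = "integer", mserMinArea = "integer",
  mserMaxAreaFrac = "numeric", mserMaxVariation = "numeric",
  mserMinDiversity = "numeric",
  msGridFactor = "numeric", msTolMm = "numeric", msMaxIter = "integer",
  dIoFactor = "numeric", eyeIsoFactor = "numeric", fillValue = "numeric",
  tiltSign = "numeric", seed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@fNU <= 0 || object@f1 <= 0 || object@f2 <= 0)
    msg <- c(msg, "FWHMs must be positive")
  if (object@f1 <= object@f2)
    msg <- c(msg, "f1 must exceed f2 (difference of Gaussians)")
  if (object@mserDelta < 1L) msg <- c(msg, "mserDelta must be >= 1")
  if (!object@tiltSign %in% c(-1, 1)) msg <- c(msg, "tiltSign must be +/-1")
  if (length(msg)) msg else TRUE
})

#' BiometryTable: gestational-age-indexed reference anatomy
#'
#' Rows of (gestational age in weeks, occipitofrontal diameter OFD,
#' biparietal diameter BPD, ocular diameter OD), all in mm, covering 14-40
#' weeks, with OFD > BPD > OD > 0 and all columns non-decreasing in age.
#' Every size threshold of the pipeline is driven by this table.
#'
#' @slot table data.frame with columns ga_weeks, ofd_mm, bpd_mm, od_mm.
#' @export
setClass("BiometryTable", representation(table = "data.frame"))

setValidity("BiometryTable", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("ga_weeks", "ofd_mm", "bpd_mm", "od_mm")
  if (!all(need %in% names(tb)))
    return(paste("columns required:", paste(need, collapse = ", ")))
  if (nrow(tb) < 2L) msg <- c(msg, "at least two rows required")
  if (is.unsorted(tb$ga_weeks, strictly = TRUE))
    msg <- c(msg, "ga_weeks must be strictly increasing")
  if (min(tb$ga_weeks) > 14 || max(tb$ga_weeks) < 40)
    msg <- c(msg, "table must cover gestational ages 14 to 40 weeks")
  if (!all(tb$ofd_mm > tb$bpd_mm & tb$bpd_mm > tb$od_mm & tb$od_mm > 0))
    msg <- c(msg, "every row must satisfy OFD > BPD > OD > 0")
  for (cn in c("ofd_mm", "bpd_mm", "od_mm"))
    if (is.unsorted(tb[[cn]])) msg <- c(msg, paste(cn, "must be non-decreasing"))
  if (length(msg)) msg else TRUE
})

setMethod("show", "BiometryTable", function(object) {
  tb <- object@table
  cat(sprintf("BiometryTable: %d rows, %g-%g weeks GA\n",
              nrow(tb), min(tb$ga_weeks), max(tb$ga_weeks)))
  invisible(object)
})

#' RegionCluster: a 3D group of MSERs
#'
#' A converged mean-shift mode together with the member regions assigned to
#' it, their aggregated binary 3D mask on the parent grid, and the number of
#' distinct slices that contribute members.
#'
#' @slot members list of ExtremalRegion records.
#' @slot centroid numeric(3) world-mm mode position.
#' @slot mask 3D logical array (union of member pixels).
#' @slot sliceSupport integer, number of distinct slices with members.
#' @aliases clusterMask clusterCentroid sliceSupport
#' @export
setClass("RegionCluster", representation(
  members = "list", centroid = "numeric", mask = "array",
  sliceSupport = "integer"
))

setValidity("RegionCluster", function(object) {
  msg <- character()
  if (length(object@centroid) != 3L) msg <- c(msg, "centroid must be length 3")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(object@members) > 0L && !any(object@mask))
    msg <- c(msg, "mask must be nonempty when members exist")
  if (length(msg)) msg else TRUE
})

#' @rdname RegionCluster-class
#' @export
setMethod("clusterMask", "RegionCluster", function(x) x@mask)
#' @rdname RegionCluster-class
#' @export
setMethod("clusterCentroid", "RegionCluster", function(x) x@centroid)
#' @rdname RegionCluster-class
#' @export
setMethod("sliceSupport", "RegionCluster", function(x) x@sliceSupport)

setMethod("show", "RegionCluster", function(object) {
  cat(sprintf(
    "RegionCluster: %d members on %d slices, %d mask voxels, centroid (%s) mm\n",
    length(object@members), object@sliceSupport, sum(object@mask),
    paste(format(object@centroid, digits = 4), collapse = ", ")))
  invisible(object)
})

#' BrainEllipsoid: moment-fitted 3D ellipsoid of the brain mask
#'
#' @slot center numeric(3) world-mm centre (the updated brain centre).
#' @slot axes numeric(3) full axis lengths in mm, sorted descending.
#' @slot axisDirs 3x3 matrix of unit axis directions (columns; column 1 is
#'   the major axis).
#' @export
setClass("BrainEllipsoid", representation(
  center = "numeric", axes = "numeric", axisDirs = "matrix"
))

setValidity("BrainEllipsoid", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@axes))) msg <- c(msg, "axes must be descending")
  if (any(object@axes <= 0)) msg <- c(msg, "axes must be positive")
  g <- crossprod(object@axisDirs)
  if (max(abs(g - diag(3))) > 1e-6)
    msg <- c(msg, "axis directions must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' EyePair: the selected pair of eye clusters
#'
#' @slot E1,E2 numeric(3) world-mm cluster barycentres.
#' @slot epsilon geometric pair error of the selected pair.
#' @slot terms numeric(4): distance-prior, symmetry, separation and
#'   slice-support components of epsilon.
#' @slot s1,s2 integer slice supports of the two clusters.
#' @export
setClass("EyePair", representation(
  E1 = "numeric", E2 = "numeric", epsilon = "numeric",
  terms = "numeric", s1 = "integer", s2 = "integer"
))

setValidity("EyePair", function(object) {
  msg <- character()
  if (identical(object@E1, object@E2)) msg <- c(msg, "E1 and E2 must differ")
  if (length(object@epsilon) == 1L && is.finite(object@epsilon) &&
      object@epsilon < 0)
    msg <- c(msg, "epsilon must be >= 0")
  if (length(msg)) msg else TRUE
})

#' AnatomicalFrame: the orthonormal LR/PA/IS anatomical basis
#'
#' Unit axes in world coordinates with `det[LR PA IS] = +1` (never a
#' reflection), origin at the brain centre, plus the left/right labelling of
#' the two eye landmarks (RAS convention: +LR points towards the subject's
#' right, so the eye on the +LR side is the right eye). `labels` is
#' `"ambiguous"` when the brain ellipsoid is too degenerate to resolve
#' laterality.
#'
#' @slot LR,PA,IS numeric(3) unit axes.
#' @slot origin numeric(3) world-mm brain centre.
#' @slot handedness +1.
#' @slot labels character: "resolved", "ambiguous" or "unlabeled".
#' @slot eyeLeft,eyeRight numeric(3) labelled eye positions (NA when
#'   unlabeled).
#' @aliases frameAxes frameOrigin eyeLabels
#' @export
setClass("AnatomicalFrame", representation(
  LR = "numeric", PA = "numeric", IS = "numeric", origin = "numeric",
  handedness = "numeric", labels = "character",
  eyeLeft = "numeric", eyeRight = "numeric"
))

setValidity("AnatomicalFrame", function(object) {
  R <- cbind(object@LR, object@PA, object@IS)
  msg <- character()
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    msg <- c(msg, "axes must be orthonormal")
  if (abs(det(R) - 1) > 1e-6) msg <- c(msg, "determinant must be +1")
  if (!object@labels %in% c("resolved", "ambiguous", "unlabeled"))
    msg <- c(msg, "labels must be resolved/ambiguous/unlabeled")
  if (length(msg)) msg else TRUE
})

#' @rdname AnatomicalFrame-class
#' @export
setMethod("frameAxes", "AnatomicalFrame", function(x)
  cbind(LR = x@LR, PA = x@PA, IS = x@IS))
#' @rdname AnatomicalFrame-class
#' @export
setMethod("frameOrigin", "AnatomicalFrame", function(x) x@origin)
#' @rdname AnatomicalFrame-class
#' @export
setMethod("eyeLabels", "AnatomicalFrame", function(x) x@labels)

setMethod("show", "AnatomicalFrame", function(object) {
  cat("AnatomicalFrame (", object@labels, ")\n", sep = "")
  m <- rbind(LR = object@LR, PA = object@PA, IS = object@IS,
             origin = object@origin)
  print(round(m, 4))
  invisible(object)
})

#' HeadPoseResult: full output of the detection pipeline
#'
#' @slot success logical; FALSE when a stage raised a detection failure.
#' @slot failureReason character ("" on success).
#' @slot brainCenter numeric(3) world mm.
#' @slot eyes \linkS4class{EyePair} (may be empty on failure).
#' @slot frame \linkS4class{AnatomicalFrame}.
#' @slot ellipsoid \linkS4class{BrainEllipsoid}.
#' @slot brainMask 3D logical array on the input grid.
#' @slot transform 4x4 world -> anatomical rigid transform.
#' @slot diagnostics list of per-stage counts and timings.
#' @export
setClass("HeadPoseResult", representation(
  success = "logical", failureReason = "character",
  brainCenter = "numeric", eyes = "ANY", frame = "ANY", ellipsoid = "ANY",
  brainMask = "array", transform = "matrix", diagnostics = "list"
))

setMethod("show", "HeadPoseResult", function(object) {
  if (object@success) {
    cat("HeadPoseResult: success\n")
    cat("  brain centre (mm):",
        paste(format(object@brainCenter, digits = 4), collapse = ", "), "\n")
    cat("  eye-pair epsilon:", format(object@eyes@epsilon, digits = 4),
        " labels:", object@frame@labels, "\n")
  } else {
    cat("HeadPoseResult: FAILURE (", object@failureReason, ")\n", sep = "")
  }
  invisible(object)
})

#' PhantomSpec: parameters of one synthetic scout volume
#'
#' @slot ga gestational age in weeks (14-40).
#' @slot rotation numeric(3) intrinsic x-y-z Euler angles in degrees.
#' @slot translation numeric(3) world-mm offset of the brain centre from the
#'   FOV centre.
#' @slot dims integer(3) matrix size.
#' @slot inPlaneMm,sliceMm voxel sizes in mm.
#' @slot noiseSigma additive Gaussian noise SD as a fraction of the brain
#'   intensity.
#' @slot oddEvenShiftMm in-plane displacement applied to odd slices
#'   (interleaved-acquisition motion).
#' @slot decoys number of spurious bright blobs near the head.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec", representation(
  ga = "numeric", rotation = "numeric", translation = "numeric",
  dims = "integer", inPlaneMm = "numeric", sliceMm = "numeric",
  noiseSigma = "numeric", oddEvenShiftMm = "numeric", decoys = "integer",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@ga < 14 || object@ga > 40)
    msg <- c(msg, "ga must be within [14, 40] weeks")
  if (object@inPlaneMm <= 0 || object@sliceMm <= 0)
    msg <- c(msg, "spacings must be positive")
  if (any(object@dims < 8L)) msg <- c(msg, "dims too small")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: landmarks, frame and brain mask of a phantom
#'
#' @slot bTrue,eLeftTrue,eRightTrue numeric(3) world mm.
#' @slot frameTrue \linkS4class{AnatomicalFrame}.
#' @slot brainMaskTrue 3D logical array.
#' @export
setClass("GroundTruth", representation(
  bTrue = "numeric", eLeftTrue = "numeric", eRightTrue = "numeric",
  frameTrue = "ANY", brainMaskTrue = "array"
))
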