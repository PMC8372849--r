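## Pipeline configuration and the end-to-end head-pose detection.

#' Construct a pipeline configuration
#'
#' All defaults are the method's operating point; see
#' \linkS4class{PipelineConfig} for the meaning of each parameter.
#'
#' @param fNU,f1,f2 Gaussian FWHMs in mm (20, 10, 5).
#' @param zPoly slice-pruning z-score threshold (1.5).
#' @param lambda eye-symmetry weight (4).
#' @param thetaDeg eye-plane tilt in degrees (30).
#' @param rhoClustFactor eye clustering radius / OD (0.75).
#' @param rhoSuccessFactor success radius / OD (1.2).
#' @param fClustFactor mean-shift kernel FWHM / OFD (0.5).
#' @param mserDelta,mserMinArea,mserMaxAreaFrac,mserMaxVariation,mserMinDiversity
#'   MSER detector parameters.
#' @param msGridFactor,msTolMm,msMaxIter mean-shift start-grid spacing /
#'   OFD, tolerance (mm) and iteration cap.
#' @param dIoFactor expected eye separation / OD (2).
#' @param eyeIsoFactor eye-box resampling / in-plane voxel size (0.5).
#' @param fillValue out-of-field fill value (0).
#' @param tiltSign +1 or -1, tilt convention.
#' @param seed reserved; the detection itself is deterministic.
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(fNU = 20, f1 = 10, f2 = 5, zPoly = 1.5,
                           lambda = 4, thetaDeg = 30, rhoClustFactor = 0.75,
                           rhoSuccessFactor = 1.2, fClustFactor = 0.5,
                           mserDelta = 5L, mserMinArea = 9L,
                           mserMaxAreaFrac = 0.4, mserMaxVariation = 0.5,
                           mserMinDiversity = 0.2, msGridFactor = 0.5,
                           msTolMm = 1, msMaxIter = 100L, dIoFactor = 2,
                           eyeIsoFactor = 0.5, fillValue = 0, tiltSign = 1,
                           seed = 1L) {
  new("PipelineConfig", fNU = fNU, f1 = f1, f2 = f2, zPoly = zPoly,
      lambda = lambda, thetaDeg = thetaDeg, rhoClustFactor = rhoClustFactor,
      rhoSuccessFactor = rhoSuccessFactor, fClustFactor = fClustFactor,
      mserDelta = as.integer(mserDelta),
      mserMinArea = as.integer(mserMinArea),
      mserMaxAreaFrac = mserMaxAreaFrac,
      mserMaxVariation = mserMaxVariation,
      mserMinDiversity = mserMinDiversity, msGridFactor = msGridFactor,
      msTolMm = msTolMm, msMaxIter = as.integer(msMaxIter),
      dIoFactor = dIoFactor, eyeIsoFactor = eyeIsoFactor,
      fillValue = fillValue, tiltSign = tiltSign, seed = as.integer(seed))
}

#' Read a configuration file
#'
#' YAML or JSON with entries named after [pipelineConfig()] arguments;
#' unspecified entries keep their defaults.
#'
#' @param path configuration file path.
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration entries: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

.mserParamsFromConfig <- function(config)
  mserParams(config@mserDelta, config@mserMinArea, config@mserMaxAreaFrac,
             config@mserMaxVariation, config@mserMinDiversity)

#' Detect and describe MSERs on every slice of a volume
#'
#' Runs slice preparation and MSER detection along the volume's slice
#' axis (optionally restricted to a voxel sub-box), fits ellipses, and
#' maps each region's pixels and barycentre onto the parent grid / world
#' coordinates.
#'
#' @param vol a \linkS4class{VolumeGrid}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param ranges optional per-axis voxel index ranges (from
#'   [worldBoxToVoxelRanges()]).
#' @param computeContrast also compute each region's local contrast on the
#'   raw slice (needed by the eye stage).
#' @return List with `regions` (ExtremalRegion records carrying `voxels`,
#'   `barycenterWorld`, `fit`, optionally `contrast`) and `nSlices`.
#' @export
detectRegionsOnVolume <- function(vol, config = pipelineConfig(),
                                  ranges = NULL, computeContrast = FALSE) {
  params <- .mserParamsFromConfig(config)
  ax <- sliceAxis(vol)
  sliceIdx <- if (is.null(ranges)) seq_len(dim(intensities(vol))[ax])
              else ranges[[ax]]
  regions <- list()
  for (k in sliceIdx) {
    sl <- getSlice(vol, k, ranges)
    if (min(dim(sl$data)) < 8L) next
    prep <- prepareSlice(sl$data, sl$spacing, config)
    regs <- detectMsers(prep$product, params)
    for (reg in regs) {
      if (nrow(reg$pixels) < 3L) next
      fit <- fitEllipse(reg, sl$spacing, dim(sl$data))
      w <- slicePixelsToWorld(vol, reg$pixels, k, sl$inPlaneAxes, sl$offset)
      vox <- matrix(0L, nrow(reg$pixels), 3)
      vox[, sl$inPlaneAxes[1]] <- reg$pixels[, 1] + sl$offset[1] - 1L
      vox[, sl$inPlaneAxes[2]] <- reg$pixels[, 2] + sl$offset[2] - 1L
      vox[, ax] <- k
      reg$sliceIndex <- k
      reg$fit <- fit
      reg$voxels <- vox
      reg$barycenterWorld <- colMeans(w)
      if (computeContrast)
        reg$contrast <- localContrast(reg, sl$data, sl$spacing, fit = fit)
      regions[[length(regions) + 1L]] <- reg
    }
  }
  list(regions = regions, nSlices = length(sliceIdx))
}

#' Detect the fetal head pose in a scout volume
#'
#' The full pipeline: (1) global brain search — per-slice MSER detection,
#' brain-localization filtering, mean-shift clustering across slices,
#' fill-factor ranking, mask regularization; (2) local brain masking in a
#' `sqrt(2) x OFD` box, parabola-based slice pruning and the 3D brain
#' ellipsoid; (3) eye detection at doubled resolution with contrast
#' filtering and geometric pair selection; (4) anatomical frame
#' construction with left-right resolution and the eye-plane tilt.
#'
#' Detection failures (brain or eyes not found) are reported in the
#' returned object, not thrown.
#'
#' @param vol a \linkS4class{VolumeGrid} (see [readVolume()]).
#' @param ga gestational age in weeks (14-40).
#' @param config a \linkS4class{PipelineConfig}.
#' @param biometry a \linkS4class{BiometryTable}.
#' @param verbose emit per-stage log messages with timings.
#' @return A \linkS4class{HeadPoseResult}.
#' @export
detectHeadPose <- function(vol, ga, config = pipelineConfig(),
                           biometry = biometryTable(), verbose = FALSE) {
  biom <- lookupBiometry(biometry, ga)
  ofd <- biom[["ofd"]]
  diag_ <- list()
  t0 <- proc.time()[["elapsed"]]
  logStage <- function(stage, ...) {
    if (verbose)
      message(sprintf("[%6.2fs] %s: %s", proc.time()[["elapsed"]] - t0,
                      stage, sprintf(...)))
  }

  failed <- function(reason) {
    new("HeadPoseResult", success = FALSE, failureReason = reason,
        brainCenter = rep(NA_real_, 3), eyes = NULL, frame = NULL,
        ellipsoid = NULL, brainMask = array(FALSE, dim(intensities(vol))),
        transform = diag(4), diagnostics = diag_)
  }

  tryCatch({
    ## stage 1: global brain search
    det <- detectRegionsOnVolume(vol, config)
    regsA <- applyFilters(det$regions, filterStage("brain_localize"), biom)
    diag_$nGlobalRegions <- length(det$regions)
    diag_$nGlobalKept <- length(regsA)
    logStage("global", "%d MSERs, %d pass brain-localization filters",
             length(det$regions), length(regsA))
    if (length(regsA) == 0L) detectionFailure("brain not found")
    bary <- do.call(rbind, lapply(regsA, `[[`, "barycenterWorld"))
    modes <- meanShiftModes(bary, kernelFwhm = config@fClustFactor * ofd,
                            gridSpacing = config@msGridFactor * ofd,
                            tol = config@msTolMm, maxIter = config@msMaxIter)
    clusters <- assignMembers(regsA, modes, ofd, dim(intensities(vol)))
    diag_$nClusters <- length(clusters)
    brainCl <- selectBrain(clusters, vol)
    M <- regularizeSlices(clusterMask(brainCl), sliceAxis(vol))
    B0 <- maskBarycenter(M, vol)
    logStage("localize", "%d clusters, brain mask %d voxels, B0 (%s)",
             length(clusters), sum(M),
             paste(round(B0, 1), collapse = ", "))

    ## stage 2: local search, pruning, ellipsoid
    M2 <- localBrainSearch(vol, B0, biom, config, M)
    M2 <- parabolaPrune(M2, voxelSpacing(vol), config@zPoly, sliceAxis(vol))
    ell <- fitEllipsoid(M2, vol)
    B <- ell@center
    diag_$nMaskVoxels <- sum(M2)
    logStage("mask", "refined mask %d voxels, B (%s)", sum(M2),
             paste(round(B, 1), collapse = ", "))

    ## stage 3: eyes
    eyeRes <- detectEyeCandidates(vol, B, biom, config)
    diag_$nEyeCandidates <- length(eyeRes$candidates)
    pair <- selectEyes(eyeRes$candidates, B, biom, config)
    logStage("eyes", "%d candidates, epsilon %.3f",
             length(eyeRes$candidates), pair@epsilon)

    ## stage 4: frame
    frame0 <- buildFrame(B, pair@E1, pair@E2)
    frameR <- resolveLeftRight(frame0, ell, pair@E1, pair@E2, B)
    frame <- applyTilt(frameR, config@tiltSign * config@thetaDeg)
    tf <- frameToTransform(frame)
    diag_$elapsedSec <- proc.time()[["elapsed"]] - t0
    logStage("pose", "labels %s", frame@labels)

    new("HeadPoseResult", success = TRUE, failureReason = "",
        brainCenter = as.numeric(B), eyes = pair, frame = frame,
        ellipsoid = ell, brainMask = M2, transform = tf$transform,
        diagnostics = diag_)
  }, fetalscoutDetectionError = function(e) {
    logStage("abort", "%s", conditionMessage(e))
    failed(conditionMessage(e))
  })
}

#' Write a detection result as JSON
#'
#' World-mm landmarks, the anatomical axes (RAS convention), the 4x4
#' world-to-anatomical transform, the pair-error terms and the per-stage
#' diagnostics.
#'
#' @param result a \linkS4class{HeadPoseResult}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportPoseJson <- function(result, path) {
  obj <- if (result@success) list(
    success = TRUE,
    B = result@brainCenter,
    E_left = result@frame@eyeLeft,
    E_right = result@frame@eyeRight,
    E1 = result@eyes@E1, E2 = result@eyes@E2,
    LR = result@frame@LR, PA = result@frame@PA, IS = result@frame@IS,
    transform = result@transform,
    ambiguous = result@frame@labels == "ambiguous",
    epsilon = result@eyes@epsilon,
    epsilon_terms = as.list(result@eyes@terms),
    diagnostics = result@diagnostics
  ) else list(success = FALSE, reason = result@failureReason,
              diagnostics = result@diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write phantom ground truth as JSON
#'
#' Mirrors the detection output schema ([exportPoseJson()]).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportTruthJson <- function(truth, path) {
  fr <- truth@frameTrue
  jsonlite::write_json(list(
    success = TRUE, B = truth@bTrue, E_left = truth@eLeftTrue,
    E_right = truth@eRightTrue, LR = fr@LR, PA = fr@PA, IS = fr@IS,
    transform = frameToTransform(fr)$transform, ambiguous = FALSE),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
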