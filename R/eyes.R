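## Eye detection: local MSER search at doubled resolution, contrast
## filtering, radius-based clustering, and the geometric pair error.

#' Detect eye candidate clusters near the brain
#'
#' The brain box (side `sqrt(2) x OFD`) is resampled isotropically at half
#' the in-plane voxel size to resolve the small ocular structures; MSERs
#' are detected per slice, filtered with the eye stage of the anatomical
#' filter bank (including the local-contrast and distance-from-brain
#' bounds), and clustered: every region, together with all other regions
#' within `0.75 x OD` of its barycentre, seeds one candidate; candidates
#' with identical member sets are merged.
#'
#' @param vol the scout \linkS4class{VolumeGrid}.
#' @param B world-mm brain centre.
#' @param biometry named vector from [lookupBiometry()].
#' @param config a \linkS4class{PipelineConfig}.
#' @return List with `candidates` (list of \linkS4class{RegionCluster} on
#'   the resampled grid) and `box` (the resampled
#'   \linkS4class{VolumeGrid}).
#' @export
detectEyeCandidates <- function(vol, B, biometry, config = pipelineConfig()) {
  ofd <- biometry[["ofd"]]; od <- biometry[["od"]]
  inPlane <- voxelSpacing(vol)[setdiff(1:3, sliceAxis(vol))]
  iso <- config@eyeIsoFactor * min(inPlane)
  box <- resampleBox(vol, B, sqrt(2) * ofd, iso, fill = config@fillValue)
  det <- detectRegionsOnVolume(box, config, computeContrast = TRUE)
  kept <- applyFilters(det$regions, filterStage("eye"), biometry,
                       brainCenter = B)
  if (length(kept) == 0L) detectionFailure("eyes not found")

  bary <- do.call(rbind, lapply(kept, `[[`, "barycenterWorld"))
  memberSets <- lapply(seq_along(kept), function(i) {
    d <- sqrt(rowSums(sweep(bary, 2, bary[i, ])^2))
    sort(which(d < config@rhoClustFactor * od))
  })
  memberSets <- memberSets[!duplicated(vapply(memberSets, paste,
                                              character(1),
                                              collapse = ","))]
  dims <- dim(intensities(box))
  candidates <- lapply(memberSets, function(sel) {
    members <- kept[sel]
    mask <- array(FALSE, dims)
    for (m in members) mask[m$voxels] <- TRUE
    ctr <- colMeans(bary[sel, , drop = FALSE])
    support <- length(unique(vapply(members, `[[`, integer(1), "sliceIndex")))
    new("RegionCluster", members = members, centroid = as.numeric(ctr),
        mask = mask, sliceSupport = as.integer(support))
  })
  ord <- order(vapply(candidates, function(cl) clusterCentroid(cl)[1],
                      numeric(1)),
               vapply(candidates, function(cl) clusterCentroid(cl)[2],
                      numeric(1)),
               vapply(candidates, function(cl) clusterCentroid(cl)[3],
                      numeric(1)))
  list(candidates = candidates[ord], box = box)
}

.clusterInfo <- function(x) {
  if (is(x, "RegionCluster"))
    list(centroid = clusterCentroid(x), support = sliceSupport(x))
  else
    list(centroid = as.numeric(x$centroid),
         support = as.integer(x$sliceSupport))
}

#' Geometric error of a candidate eye pair
#'
#' Deviation from the expected brain-eye geometry:
#' \deqn{\epsilon = |(u_j + u_k)/OFD - 1| + 2\lambda |u_j - u_k|/(u_j + u_k)
#'   + |w/d_{io} - 1| + |(s_j + s_k)/(2 s_{max}) - 1|}
#' with \eqn{u_j, u_k} the brain-to-cluster distances, \eqn{w} the
#' cluster separation, \eqn{d_{io}} the expected eye separation (default
#' `2 x OD`) and \eqn{s_j, s_k} the slice supports. The four terms are the
#' brain-eye distance prior, left/right symmetry, eye-separation prior and
#' multi-slice support. Coincident barycentres score `Inf`.
#'
#' @param j,k candidate clusters (\linkS4class{RegionCluster} or lists with
#'   `centroid` and `sliceSupport`).
#' @param B world-mm brain centre.
#' @param ofd,od reference diameters in mm.
#' @param lambda symmetry weight (default 4).
#' @param dIo expected eye separation in mm (default `2 * od`).
#' @param sMax maximum slice support over all candidates.
#' @return Scalar error (attribute `terms` carries the four components).
#' @export
pairError <- function(j, k, B, ofd, od, lambda = 4, dIo = 2 * od,
                      sMax = NULL) {
  ji <- .clusterInfo(j); ki <- .clusterInfo(k)
  if (is.null(sMax)) sMax <- max(ji$support, ki$support)
  uj <- sqrt(sum((ji$centroid - B)^2))
  uk <- sqrt(sum((ki$centroid - B)^2))
  w <- sqrt(sum((ji$centroid - ki$centroid)^2))
  if (w < 1e-9) return(structure(Inf, terms = rep(Inf, 4)))
  terms <- c(distance = abs((uj + uk) / ofd - 1),
             symmetry = 2 * lambda * abs(uj - uk) / (uj + uk),
             separation = abs(w / dIo - 1),
             support = abs((ji$support + ki$support) / (2 * sMax) - 1))
  structure(sum(terms), terms = terms)
}

#' Select the eye pair
#'
#' Exhaustive scan over all unordered candidate pairs; the pair with the
#' lowest geometric error wins (deterministic tie-break by candidate
#' order, which is lexicographic in the barycentres).
#'
#' @param candidates list of >= 2 candidate clusters.
#' @param B world-mm brain centre.
#' @param biometry named vector from [lookupBiometry()].
#' @param config a \linkS4class{PipelineConfig}.
#' @return An \linkS4class{EyePair}.
#' @export
selectEyes <- function(candidates, B, biometry, config = pipelineConfig()) {
  m <- length(candidates)
  if (m < 2L) detectionFailure("eyes not found (fewer than 2 candidates)")
  ofd <- biometry[["ofd"]]; od <- biometry[["od"]]
  sMax <- max(vapply(candidates, function(cl) .clusterInfo(cl)$support,
                     integer(1)))
  best <- NULL; bestEps <- Inf
  for (i in seq_len(m - 1L)) for (jj in seq.int(i + 1L, m)) {
    eps <- pairError(candidates[[i]], candidates[[jj]], B, ofd, od,
                     lambda = config@lambda, dIo = config@dIoFactor * od,
                     sMax = sMax)
    if (eps < bestEps) { bestEps <- eps; best <- c(i, jj) }
  }
  if (is.null(best) || !is.finite(bestEps))
    detectionFailure("eyes not found (no valid pair)")
  ci <- .clusterInfo(candidates[[best[1]]])
  cj <- .clusterInfo(candidates[[best[2]]])
  eps <- pairError(candidates[[best[1]]], candidates[[best[2]]], B, ofd, od,
                   lambda = config@lambda, dIo = config@dIoFactor * od,
                   sMax = sMax)
  new("EyePair", E1 = ci$centroid, E2 = cj$centroid,
      epsilon = as.numeric(eps), terms = attr(eps, "terms"),
      s1 = ci$support, s2 = cj$support)
}
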