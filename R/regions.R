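## Ellipse descriptors for MSERs, the three anatomical filter banks, and
## the local-contrast statistic used for eye detection.

#' Fit an equal-moment ellipse to a region
#'
#' The ellipse whose second central moments match those of the region's
#' pixel set (pixel centres in mm plus the per-pixel uniform-square
#' moment), with full axis lengths `a >= b` in mm, area
#' `A = pi (a/2)(b/2)` and the Dice overlap `D` between the region mask and
#' the rasterized ellipse. Degenerate (collinear) regions get their minor
#' axis floored at one pixel width and are flagged.
#'
#' @param region an `ExtremalRegion` record (or any list with a `pixels`
#'   n x 2 matrix of 1-based row/col indices), n >= 3.
#' @param spacing numeric(2) in-plane voxel size in mm.
#' @param sliceDim optional `c(nrow, ncol)` of the slice; when given, the
#'   ellipse raster used for the Dice overlap is clipped to the slice.
#' @return List with `center` (mm), `a`, `b`, `orientation` (radians), `A`
#'   (mm^2), `D`, `Sigma` (2x2 moment matrix) and `degenerate`.
#' @export
fitEllipse <- function(region, spacing, sliceDim = NULL) {
  pix <- region$pixels
  if (nrow(pix) < 3L) stop("ellipse fit requires at least 3 pixels")
  spacing <- rep_len(spacing, 2L)
  pts <- sweep(pix - 1, 2, spacing, `*`)
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  rawCov <- crossprod(cpts) / nrow(pts)
  Sigma <- rawCov + diag(spacing^2 / 12)
  eg <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  semi <- 2 * sqrt(lam)
  # collinear pixel set: the per-pixel moment floors b at one pixel width
  degenerate <- min(eigen(rawCov, symmetric = TRUE,
                          only.values = TRUE)$values) < 1e-9 * max(lam)
  semi[2] <- max(semi[2], min(spacing) / 2)
  a <- 2 * semi[1]; b <- 2 * semi[2]
  V <- eg$vectors
  Sigma <- V %*% diag((semi / 2)^2) %*% t(V)
  orientation <- atan2(V[2, 1], V[1, 1])

  # rasterize the ellipse (pixel centre in ellipse <=> Mahalanobis^2 <= 4)
  Sinv <- solve(Sigma)
  rr <- ceiling(semi[1] / spacing)
  c0 <- round(ctr / spacing) + 1
  ri <- (c0[1] - rr[1] - 1):(c0[1] + rr[1] + 1)
  ci <- (c0[2] - rr[2] - 1):(c0[2] + rr[2] + 1)
  if (!is.null(sliceDim)) {
    ri <- ri[ri >= 1 & ri <= sliceDim[1]]
    ci <- ci[ci >= 1 & ci <= sliceDim[2]]
  }
  g <- as.matrix(expand.grid(r = ri, c = ci))
  gm <- sweep(sweep(g - 1, 2, spacing, `*`), 2, ctr)
  m2 <- rowSums((gm %*% Sinv) * gm)
  epix <- g[m2 <= 4, , drop = FALSE]
  keyR <- pix[, 1] * 1e6 + pix[, 2]
  keyE <- epix[, 1] * 1e6 + epix[, 2]
  inter <- sum(keyE %in% keyR)
  D <- if (nrow(epix) + nrow(pix) > 0)
    2 * inter / (nrow(epix) + nrow(pix)) else 0

  list(center = ctr, a = a, b = b, orientation = orientation,
       A = pi * (a / 2) * (b / 2), D = D, Sigma = Sigma,
       degenerate = degenerate)
}

#' Local contrast of a region
#'
#' Ratio of the median intensity inside the region's fitted ellipse `E` to
#' the median in the surrounding ribbon `R = Etilde \\ E`, where `Etilde`
#' has 50\% longer axes. Discriminates the eyes, which are brighter than
#' every surrounding tissue. Returns `NA` when the ribbon is entirely
#' outside the slice (such regions are rejected downstream).
#'
#' @param region an `ExtremalRegion` record.
#' @param slice the 2D intensity slice the region was detected on.
#' @param spacing numeric(2) in-plane voxel size in mm.
#' @param fit optional precomputed [fitEllipse()] result.
#' @return Scalar contrast `C`, or `NA_real_`.
#' @export
localContrast <- function(region, slice, spacing, fit = NULL) {
  spacing <- rep_len(spacing, 2L)
  if (is.null(fit)) fit <- fitEllipse(region, spacing, dim(slice))
  Sinv <- solve(fit$Sigma)
  rr <- ceiling(1.5 * (fit$a / 2) / spacing)
  c0 <- round(fit$center / spacing) + 1
  ri <- max(1, c0[1] - rr[1] - 1):min(dim(slice)[1], c0[1] + rr[1] + 1)
  ci <- max(1, c0[2] - rr[2] - 1):min(dim(slice)[2], c0[2] + rr[2] + 1)
  g <- as.matrix(expand.grid(r = ri, c = ci))
  gm <- sweep(sweep(g - 1, 2, spacing, `*`), 2, fit$center)
  m2 <- rowSums((gm %*% Sinv) * gm)
  inE <- m2 <= 4
  inRibbon <- m2 > 4 & m2 <= 9
  if (!any(inRibbon) || !any(inE)) return(NA_real_)
  vals <- slice[cbind(g[, 1], g[, 2])]
  denom <- median(vals[inRibbon])
  if (denom <= 0) return(Inf)
  median(vals[inE]) / denom
}

#' Anatomical filter stage bounds
#'
#' The three filter banks applied to fitted MSER ellipses: (A) global brain
#' localization, (B) local brain masking, (C) eye detection. All bounds are
#' on dimensionless normalized quantities — ellipse area over the reference
#' ellipse area `pi (a_ref/2)(b_ref/2)`, aspect ratio over `a_ref/b_ref`,
#' major axis over `a_ref`, Dice overlap, distance from the brain centre
#' over `OFD/2`, and local contrast — with `a_ref = OFD, b_ref = BPD` for
#' the brain stages and `a_ref = b_ref = OD` for the eyes. Individual cells
#' can be overridden by name.
#'
#' @param stage one of `"brain_localize"`, `"brain_mask"`, `"eye"`.
#' @param ... named overrides of individual bounds (`areaMin`, `areaMax`,
#'   `aspectMax`, `majorMax`, `diceMin`, `dMin`, `dMax`, `contrastMin`).
#' @return A `FilterStage` list.
#' @export
filterStage <- function(stage = c("brain_localize", "brain_mask", "eye"),
                        ...) {
  stage <- match.arg(stage)
  bounds <- switch(stage,
    brain_localize = list(areaMin = 0.2, areaMax = 1.1, aspectMax = 1.5,
                          majorMax = 1.1, diceMin = 0.7,
                          dMin = NA_real_, dMax = NA_real_,
                          contrastMin = NA_real_),
    brain_mask = list(areaMin = 0.05, areaMax = 1.1, aspectMax = 1.5,
                      majorMax = 1.2, diceMin = 0.7,
                      dMin = NA_real_, dMax = 1.1,
                      contrastMin = NA_real_),
    eye = list(areaMin = 0.5, areaMax = 1.2, aspectMax = 1.5,
               majorMax = 1.3, diceMin = 0.9,
               dMin = 0.6, dMax = 1.3, contrastMin = 2))
  ov <- list(...)
  bad <- setdiff(names(ov), names(bounds))
  if (length(bad)) stop("unknown filter bounds: ", paste(bad, collapse = ", "))
  bounds[names(ov)] <- ov
  structure(c(list(stage = stage), bounds), class = "FilterStage")
}

## Normalized descriptors of one fitted region for a given stage.
regionMetrics <- function(fit, stage, biometry, baryWorld = NULL,
                          brainCenter = NULL, contrast = NA_real_) {
  if (stage$stage == "eye") {
    aRef <- biometry[["od"]]; bRef <- biometry[["od"]]
  } else {
    aRef <- biometry[["ofd"]]; bRef <- biometry[["bpd"]]
  }
  dNorm <- NA_real_
  if (!is.null(brainCenter) && !is.null(baryWorld))
    dNorm <- sqrt(sum((baryWorld - brainCenter)^2)) / (biometry[["ofd"]] / 2)
  list(areaNorm = fit$A / (pi * (aRef / 2) * (bRef / 2)),
       aspectNorm = (fit$a / fit$b) / (aRef / bRef),
       majorNorm = fit$a / aRef,
       dice = fit$D,
       dNorm = dNorm,
       contrast = contrast)
}

## Single-region decision against a stage's bounds. Bounds are inclusive; a
## metric the stage constrains but that is undefined (NA) rejects.
keepRegion <- function(metrics, stage) {
  chk <- function(val, lo = NA, hi = NA) {
    if (is.na(lo) && is.na(hi)) return(TRUE)
    if (is.na(val)) return(FALSE)
    (is.na(lo) || val >= lo) && (is.na(hi) || val <= hi)
  }
  chk(metrics$areaNorm, stage$areaMin, stage$areaMax) &&
    chk(metrics$aspectNorm, hi = stage$aspectMax) &&
    chk(metrics$majorNorm, hi = stage$majorMax) &&
    chk(metrics$dice, lo = stage$diceMin) &&
    chk(metrics$dNorm, lo = stage$dMin, hi = stage$dMax) &&
    chk(metrics$contrast, lo = stage$contrastMin)
}

#' Filter regions against a stage's anatomical bounds
#'
#' Keeps a region iff every bound of the stage holds for its normalized
#' descriptors. Regions must carry `barycenterWorld` for stages with
#' distance bounds, and slices must be supplied for the eye stage's
#' contrast.
#'
#' @param regions list of `ExtremalRegion` records (with `fit` attached, or
#'   `spacing` given so it can be computed).
#' @param stage a [filterStage()].
#' @param biometry named vector `c(ofd, bpd, od)` from [lookupBiometry()].
#' @param brainCenter world-mm brain centre; required for stages with
#'   distance bounds.
#' @param slices optional list of intensity slices indexed by each region's
#'   `sliceIndex`, used for the contrast bound.
#' @param spacing in-plane spacing, needed only when fits are missing.
#' @return The kept regions, each with `fit` and `metrics` attached.
#' @export
applyFilters <- function(regions, stage, biometry, brainCenter = NULL,
                         slices = NULL, spacing = NULL) {
  if (is.null(biometry) || !all(c("ofd", "bpd", "od") %in% names(biometry)))
    stop("biometry (ofd, bpd, od) is required")
  needD <- !is.na(stage$dMin) || !is.na(stage$dMax)
  if (needD && is.null(brainCenter))
    stop("brainCenter is required for stage '", stage$stage, "'")
  needC <- !is.na(stage$contrastMin)
  kept <- list()
  for (reg in regions) {
    fit <- reg$fit
    if (is.null(fit)) {
      if (is.null(spacing)) stop("spacing needed to fit missing ellipses")
      fit <- fitEllipse(reg, spacing)
    }
    contrast <- reg$contrast
    if (is.null(contrast)) contrast <- NA_real_
    if (needC && is.na(contrast) && !is.null(slices)) {
      sl <- slices[[reg$sliceIndex]]
      contrast <- localContrast(reg, sl,
                                if (is.null(spacing)) rep(1, 2) else spacing,
                                fit = fit)
    }
    m <- regionMetrics(fit, stage, biometry, baryWorld = reg$barycenterWorld,
                       brainCenter = brainCenter, contrast = contrast)
    if (keepRegion(m, stage)) {
      reg$fit <- fit
      reg$metrics <- m
      reg$contrast <- contrast
      kept[[length(kept) + 1L]] <- reg
    }
  }
  kept
}
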