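## Anatomical frame construction from {B, E1, E2}, the eye-plane tilt, and
## left-right disambiguation via the brain ellipsoid.

#' Build the anatomical frame from the three landmarks
#'
#' `LR0 = (E2 - E1)/||.||`, `PA` from the brain centre through the eye
#' midpoint, `IS = LR0 x PA`, and the basis is made exactly orthonormal by
#' replacing `LR` with `PA x IS`. The result is untilted and unlabeled;
#' `E1`/`E2` order is arbitrary at this point.
#'
#' @param B,E1,E2 numeric(3) world-mm points (non-collinear).
#' @return An \linkS4class{AnatomicalFrame} with labels `"unlabeled"`.
#' @export
buildFrame <- function(B, E1, E2) {
  v1 <- E1 - B; v2 <- E2 - B
  if (sqrt(sum(cross3(v1, v2)^2)) < 1e-9 * max(1, sqrt(sum(v1^2))))
    detectionFailure("landmarks are collinear; frame undefined")
  LR0 <- normalize(E2 - E1)
  PA <- normalize((E1 + E2) / 2 - B)
  IS <- normalize(cross3(LR0, PA))
  LR <- cross3(PA, IS)
  new("AnatomicalFrame", LR = LR, PA = PA, IS = IS, origin = as.numeric(B),
      handedness = 1, labels = "unlabeled",
      eyeLeft = rep(NA_real_, 3), eyeRight = rep(NA_real_, 3))
}

#' Tilt the frame about the left-right axis
#'
#' The plane through the brain centre and both eyes sits about 30 degrees
#' from the brain's axial plane, so `PA` and `IS` are rotated about `LR`
#' by `theta`. The rotation sense moves `IS` away from the eyes'
#' half-space (the eyes are inferior): after the tilt,
#' `dot(IS, PA_before) <= 0`.
#'
#' @param frame an \linkS4class{AnatomicalFrame}.
#' @param thetaDeg tilt angle in degrees (a negative value flips the
#'   convention).
#' @return The tilted frame.
#' @export
applyTilt <- function(frame, thetaDeg = 30) {
  if (abs(thetaDeg) < 1e-12) return(frame)
  th <- thetaDeg * pi / 180
  R <- rotationAboutAxis(frame@LR, th)
  PAn <- as.numeric(R %*% frame@PA)
  ISn <- as.numeric(R %*% frame@IS)
  if (sum(ISn * frame@PA) > 0) {            # wrong sense: rotate other way
    R <- rotationAboutAxis(frame@LR, -th)
    PAn <- as.numeric(R %*% frame@PA)
    ISn <- as.numeric(R %*% frame@IS)
  }
  frame@PA <- PAn
  frame@IS <- ISn
  frame
}

#' Resolve the left-right ambiguity and label the eyes
#'
#' The plane `H` through the brain-ellipsoid centre that contains the
#' ellipsoid's major axis and is parallel to `LR` divides the brain into
#' inferior and superior halves; the inferior half contains the eyes. If
#' `IS` points into the eyes' half-space, `LR` and `IS` are negated
#' (preserving handedness). The eye on the `+LR` side is then the
#' subject's right eye (RAS convention). When the ellipsoid is too
#' spherical, its major axis is nearly parallel to `LR`, or the eyes lie
#' in `H`, the frame is returned with labels `"ambiguous"`.
#'
#' @param frame an untilted \linkS4class{AnatomicalFrame} from
#'   [buildFrame()].
#' @param ellipsoid a \linkS4class{BrainEllipsoid}.
#' @param E1,E2 the eye landmarks the frame was built from.
#' @param B the brain centre.
#' @return The frame with labels `"resolved"` (and `eyeLeft`/`eyeRight`
#'   set) or `"ambiguous"`.
#' @export
resolveLeftRight <- function(frame, ellipsoid, E1, E2, B) {
  aDir <- ellipsoid@axisDirs[, 1]
  anis <- ellipsoid@axes[1] / ellipsoid@axes[2]
  angLR <- acos(min(1, abs(sum(normalize(aDir) * frame@LR)))) * 180 / pi
  mid <- (E1 + E2) / 2
  nH <- cross3(aDir, frame@LR)
  degenerate <- anis <= 1.05 || angLR <= 10 ||
    sqrt(sum(nH^2)) < 1e-9
  if (!degenerate) {
    nH <- normalize(nH)
    sEyes <- sum(nH * (mid - ellipsoid@center))
    sIS <- sum(nH * frame@IS)
    if (abs(sEyes) < 1e-6 * ellipsoid@axes[1]) degenerate <- TRUE
    if (!degenerate) {
      if (sign(sIS) == sign(sEyes)) {       # IS points at the eyes: flip
        frame@LR <- -frame@LR
        frame@IS <- -frame@IS
      }
      onPlus <- sum(frame@LR * (E1 - mid)) > 0
      frame@eyeRight <- if (onPlus) E1 else E2
      frame@eyeLeft <- if (onPlus) E2 else E1
      frame@labels <- "resolved"
      return(frame)
    }
  }
  frame@labels <- "ambiguous"
  frame
}

#' World-to-anatomical rigid transform and prescription record
#'
#' Rows of the rotation block are `LR`, `PA`, `IS`; the translation maps
#' the brain centre to the origin. The prescription record carries the
#' field-of-view centre and the three cardinal slice-stack normals a
#' prescription system would use (axial stacks normal to `IS`, coronal to
#' `PA`, sagittal to `LR`).
#'
#' @param frame an \linkS4class{AnatomicalFrame}.
#' @return List with `transform` (4x4) and `prescription`.
#' @export
frameToTransform <- function(frame) {
  R <- rbind(frame@LR, frame@PA, frame@IS)
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- -as.numeric(R %*% frame@origin)
  list(transform = T,
       prescription = list(
         fovCenterMm = frame@origin,
         sliceNormals = list(sagittal = frame@LR, coronal = frame@PA,
                             axial = frame@IS)))
}
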