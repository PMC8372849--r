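## Validation metrics: success criterion, translation error, rotation
## error from triangle registration, and the cohort summary table.

.detectedLandmarks <- function(detected) {
  if (is(detected, "HeadPoseResult")) {
    if (!detected@success) return(NULL)
    fr <- detected@frame
    if (is(fr, "AnatomicalFrame") && fr@labels == "resolved")
      return(list(B = detected@brainCenter, eyeLeft = fr@eyeLeft,
                  eyeRight = fr@eyeRight, labeled = TRUE))
    return(list(B = detected@brainCenter, eyeLeft = detected@eyes@E1,
                eyeRight = detected@eyes@E2, labeled = FALSE))
  }
  if (is(detected, "AnatomicalFrame"))
    return(list(B = detected@origin, eyeLeft = detected@eyeLeft,
                eyeRight = detected@eyeRight,
                labeled = detected@labels == "resolved"))
  detected$labeled <- isTRUE(detected$labeled) || !is.null(detected$eyeLeft)
  if (is.null(detected$eyeLeft)) {
    detected$eyeLeft <- detected$E1
    detected$eyeRight <- detected$E2
  }
  detected
}

.truthLandmarks <- function(truth) {
  if (is(truth, "GroundTruth"))
    list(B = truth@bTrue, eyeLeft = truth@eLeftTrue,
         eyeRight = truth@eRightTrue)
  else truth
}

#' Success criterion for a detection
#'
#' TRUE iff both detected eye barycentres lie within `rho x OD` (strictly)
#' of the corresponding ground-truth eyes. In strict mode (default) the
#' left/right labelling must be resolved and match; in label-agnostic mode
#' the better of the two assignments is used (and ambiguous labellings are
#' allowed).
#'
#' @param detected a \linkS4class{HeadPoseResult}, labelled
#'   \linkS4class{AnatomicalFrame}, or list with `eyeLeft`, `eyeRight`.
#' @param truth a \linkS4class{GroundTruth} or list with `eyeLeft`,
#'   `eyeRight` (and `B`).
#' @param od ocular diameter in mm.
#' @param rho success radius as a multiple of OD (default 1.2).
#' @param agnostic ignore left/right labels (default FALSE).
#' @return Logical.
#' @export
successCriterion <- function(detected, truth, od, rho = 1.2,
                             agnostic = FALSE) {
  det <- .detectedLandmarks(detected)
  if (is.null(det)) return(FALSE)
  tru <- .truthLandmarks(truth)
  dist <- function(a, b) sqrt(sum((a - b)^2))
  straight <- dist(det$eyeLeft, tru$eyeLeft) < rho * od &&
    dist(det$eyeRight, tru$eyeRight) < rho * od
  if (!agnostic) return(isTRUE(det$labeled) && straight)
  swapped <- dist(det$eyeLeft, tru$eyeRight) < rho * od &&
    dist(det$eyeRight, tru$eyeLeft) < rho * od
  straight || swapped
}

## Proper rotation mapping X onto Y (rows are corresponding points).
kabschRotation <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(t(Xc) %*% Yc)
  d <- det(s$v %*% t(s$u))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Rotation error between detected and true head pose
#'
#' Regards the two landmark sets \{B, E1, E2\} as triangles, registers
#' them with a proper least-squares rotation (Kabsch), and reports the
#' rotation magnitude plus its absolute per-axis decomposition (intrinsic
#' x-y-z Euler angles of the recovered rotation).
#'
#' @param detected,truth landmark sets (see [successCriterion()]).
#' @return List with `dR` (degrees) and `perAxis` (named absolute degrees).
#' @export
rotationError <- function(detected, truth) {
  det <- .detectedLandmarks(detected)
  if (is.null(det)) stop("detection failed; no landmarks to register")
  tru <- .truthLandmarks(truth)
  X <- rbind(det$B, det$eyeLeft, det$eyeRight)
  Y <- rbind(tru$B, tru$eyeLeft, tru$eyeRight)
  for (m in list(X, Y)) {
    v1 <- m[2, ] - m[1, ]; v2 <- m[3, ] - m[1, ]
    if (sqrt(sum(cross3(v1, v2)^2)) < 1e-9)
      stop("degenerate landmark triangle")
  }
  R <- kabschRotation(X, Y)
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  eul <- abs(rotationToEulerXYZ(R)) * 180 / pi
  list(dR = ang, perAxis = c(x = eul[1], y = eul[2], z = eul[3]))
}

#' Translation error between detected and true landmarks
#'
#' Euclidean distances per landmark plus the absolute per-axis components
#' for the brain centre.
#'
#' @param detected,truth landmark sets (see [successCriterion()]).
#' @return List with `dT` (named: `B`, `eyeLeft`, `eyeRight`, mm) and
#'   `perAxisB`.
#' @export
translationError <- function(detected, truth) {
  det <- .detectedLandmarks(detected)
  if (is.null(det)) stop("detection failed; no landmarks to compare")
  tru <- .truthLandmarks(truth)
  dv <- det$B - tru$B
  list(dT = c(B = sqrt(sum(dv^2)),
              eyeLeft = sqrt(sum((det$eyeLeft - tru$eyeLeft)^2)),
              eyeRight = sqrt(sum((det$eyeRight - tru$eyeRight)^2))),
       perAxisB = c(x = abs(dv[1]), y = abs(dv[2]), z = abs(dv[3])))
}

#' Evaluate one detection against ground truth
#'
#' @param result a \linkS4class{HeadPoseResult}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param od ocular diameter in mm.
#' @param rho success radius multiple (default 1.2).
#' @return An `EvalResult` list: `success`, `successAgnostic`, `dT_B`,
#'   `dT_Eleft`, `dT_Eright`, `dR`, per-axis errors (NA when the
#'   detection failed).
#' @export
evaluateDetection <- function(result, truth, od, rho = 1.2) {
  out <- list(success = successCriterion(result, truth, od, rho),
              successAgnostic = successCriterion(result, truth, od, rho,
                                                 agnostic = TRUE),
              dT_B = NA_real_, dT_Eleft = NA_real_, dT_Eright = NA_real_,
              dR = NA_real_,
              dr = c(x = NA_real_, y = NA_real_, z = NA_real_),
              dt = c(x = NA_real_, y = NA_real_, z = NA_real_))
  if (is(result, "HeadPoseResult") && !result@success)
    return(structure(out, class = "EvalResult"))
  te <- translationError(result, truth)
  re <- rotationError(result, truth)
  out$dT_B <- unname(te$dT["B"])
  out$dT_Eleft <- unname(te$dT["eyeLeft"])
  out$dT_Eright <- unname(te$dT["eyeRight"])
  out$dt <- te$perAxisB
  out$dR <- re$dR
  out$dr <- re$perAxis
  structure(out, class = "EvalResult")
}

#' Summarize a cohort of evaluations
#'
#' @param results list of `EvalResult` (from [evaluateDetection()]).
#' @param path optional TSV output path.
#' @return List with `successRate`, `successRateAgnostic`, `n`, and
#'   `stats`, a data.frame with rows Minimum / Maximum / Mean / SD over the
#'   successful cases for each error metric.
#' @export
cohortReport <- function(results, path = NULL) {
  stopifnot(length(results) >= 1)
  suc <- vapply(results, function(r) isTRUE(r$success), logical(1))
  sucA <- vapply(results, function(r) isTRUE(r$successAgnostic), logical(1))
  grab <- function(f) vapply(results[suc], f, numeric(1))
  cols <- list(
    dT_B = grab(function(r) r$dT_B),
    dT_Eleft = grab(function(r) r$dT_Eleft),
    dT_Eright = grab(function(r) r$dT_Eright),
    dt_x = grab(function(r) r$dt[["x"]]),
    dt_y = grab(function(r) r$dt[["y"]]),
    dt_z = grab(function(r) r$dt[["z"]]),
    dR = grab(function(r) r$dR),
    dr_x = grab(function(r) r$dr[["x"]]),
    dr_y = grab(function(r) r$dr[["y"]]),
    dr_z = grab(function(r) r$dr[["z"]]))
  stat <- function(v, f) if (length(v)) f(v) else NA_real_
  stats <- data.frame(
    Statistic = c("Minimum", "Maximum", "Mean", "SD"),
    lapply(cols, function(v)
      c(stat(v, min), stat(v, max), stat(v, mean),
        if (length(v) > 1) sd(v) else NA_real_)),
    check.names = FALSE)
  out <- list(successRate = mean(suc), successRateAgnostic = mean(sucA),
              n = length(results), stats = stats)
  if (!is.null(path)) {
    write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
    out$path <- path
  }
  out
}
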