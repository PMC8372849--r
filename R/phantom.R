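## Seeded synthetic scout generator. The phantom emulates the geometry the
## detector relies on — bright ellipsoidal brain (OFD x BPD x BPD), dark
## skull shell, two bright eye spheres of diameter OD placed
## anterior-inferior so the {B, E1, E2} plane is tilted 30 degrees from the
## brain's axial plane, textured maternal background, multiplicative
## low-frequency bias, additive noise, optional odd/even-slice displacement
## — not MR physics.

#' Specify a synthetic scout phantom
#'
#' @param ga gestational age in weeks (14-40).
#' @param rotation numeric(3) intrinsic x-y-z Euler angles (degrees) posing
#'   the head in the scanner.
#' @param translation numeric(3) world-mm offset of the brain centre from
#'   the FOV centre.
#' @param dims matrix size (default 68 x 68 x 48).
#' @param inPlaneMm in-plane voxel size (default 3 mm).
#' @param sliceMm slice thickness/spacing (default 3 mm).
#' @param noiseSigma additive Gaussian noise SD as a fraction of the brain
#'   intensity (default 0.05).
#' @param oddEvenShiftMm in-plane displacement of the head on odd-numbered
#'   slices, emulating interleaved-acquisition motion (default 0).
#' @param decoys number of spurious bright blobs placed near the head
#'   (default 0).
#' @param seed RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(ga = 31, rotation = c(0, 0, 0),
                        translation = c(0, 0, 0), dims = c(68L, 68L, 48L),
                        inPlaneMm = 3, sliceMm = 3, noiseSigma = 0.05,
                        oddEvenShiftMm = 0, decoys = 0L, seed = 1L) {
  new("PhantomSpec", ga = ga, rotation = as.numeric(rotation),
      translation = as.numeric(translation), dims = as.integer(dims),
      inPlaneMm = inPlaneMm, sliceMm = sliceMm, noiseSigma = noiseSigma,
      oddEvenShiftMm = oddEvenShiftMm, decoys = as.integer(decoys),
      seed = as.integer(seed))
}

## Intensity levels (arbitrary units): chosen so the anatomical filter
## banks pass at their default bounds on the noise-free phantom.
.PHANTOM_LEVELS <- c(brain = 1.0, eye = 1.2, background = 0.5, skull = 0.2,
                     orbit = 0.35)

#' Generate a synthetic scout volume with ground truth
#'
#' Deterministic given the seed. The skull is a dark ellipsoidal shell
#' whose outer surface has axes OFD x BPD x BPD (OFD along PA); the brain
#' is its bright interior (semi-axes minus the ~3 mm shell). The eyes are
#' bright spheres of diameter OD at distance `0.55 x OFD` from the brain
#' centre, separated by `2 x OD`, their plane tilted 30 degrees
#' inferior-anterior about LR, each inside a dark orbital pocket carved
#' outside the cranium. The maternal background is a smooth random
#' texture at about half the brain intensity, modulated by a low-frequency
#' multiplicative bias field; Gaussian noise is added last. When
#' `oddEvenShiftMm > 0` the fetal structures are displaced in-plane on
#' odd-numbered slices only.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param biometry a \linkS4class{BiometryTable}.
#' @return List with `volume` (\linkS4class{VolumeGrid}) and `truth`
#'   (\linkS4class{GroundTruth}).
#' @export
generatePhantom <- function(spec, biometry = biometryTable()) {
  biom <- lookupBiometry(biometry, spec@ga)
  ofd <- biom[["ofd"]]; bpd <- biom[["bpd"]]; od <- biom[["od"]]
  dims <- spec@dims
  spacing <- c(spec@inPlaneMm, spec@inPlaneMm, spec@sliceMm)
  affine <- diag(4)
  diag(affine)[1:3] <- spacing
  affine[1:3, 4] <- -(dims - 1) / 2 * spacing   # FOV centred on the origin
  vol0 <- volumeGrid(array(0, dims), spacing, affine, sliceAxis = 3L)

  R <- eulerXYZToRotation(spec@rotation * pi / 180)
  ctr <- spec@translation

  semiOuter <- c(bpd, ofd, bpd) / 2             # skull, canonical LR/PA/IS
  semiBrain <- semiOuter - 3                    # brain inside a 3 mm shell
  theta <- 30 * pi / 180
  eyeDist <- 0.55 * ofd                         # just outside the skull
  mAnt <- sqrt(eyeDist^2 - od^2)                # eye separation = 2 x OD
  eCanRight <- c(od, mAnt * cos(theta), -mAnt * sin(theta))
  eCanLeft <- c(-od, mAnt * cos(theta), -mAnt * sin(theta))
  eLeft <- as.numeric(R %*% eCanLeft + ctr)
  eRight <- as.numeric(R %*% eCanRight + ctr)

  vox <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  X <- voxelToWorld(vol0, vox)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  for (e in list(eLeft, eRight))
    if (any(e < lo | e > hi))
      stop("phantom eyes fall outside the field of view; ",
           "reduce rotation/translation or enlarge dims")

  withSeed(spec@seed, {
    shiftDir <- normalize(c(rnorm(2), 0))
    shift <- spec@oddEvenShiftMm * shiftDir

    Xeff <- X
    odd <- vox[, 3] %% 2L == 1L
    if (spec@oddEvenShiftMm > 0)
      Xeff[odd, ] <- sweep(Xeff[odd, , drop = FALSE], 2, shift)

    U <- t(t(R) %*% (t(Xeff) - ctr))            # canonical head coordinates
    inBrain <- rowSums(sweep(U, 2, semiBrain, `/`)^2) <= 1
    inOuter <- rowSums(sweep(U, 2, semiOuter, `/`)^2) <= 1
    dL <- sqrt(rowSums(sweep(U, 2, eCanLeft)^2))
    dR <- sqrt(rowSums(sweep(U, 2, eCanRight)^2))
    inEye <- dL <= od / 2 | dR <= od / 2

    texture <- gaussBlur3D(array(rnorm(prod(dims)), dims), 12 / spacing)
    texture <- texture / max(sd(texture), 1e-9)
    img <- .PHANTOM_LEVELS[["background"]] * (1 + 0.3 * as.vector(texture))
    img <- pmax(img, 0.05)
    img[inOuter] <- .PHANTOM_LEVELS[["skull"]]
    img[inBrain] <- .PHANTOM_LEVELS[["brain"]]
    img[dL <= od | dR <= od] <- .PHANTOM_LEVELS[["orbit"]]   # orbital pocket

    if (spec@decoys > 0L) {
      placed <- 0L
      tries <- 0L
      while (placed < spec@decoys && tries < 200L) {
        tries <- tries + 1L
        dir <- normalize(rnorm(3))
        dist <- runif(1, 0.8, 1.2) * ofd / 2
        p <- dir * dist
        if (sqrt(sum((p - eCanLeft)^2)) < 1.5 * od) next
        if (sqrt(sum((p - eCanRight)^2)) < 1.5 * od) next
        if (sum((p / (semiOuter + od / 2))^2) <= 1) next
        pw <- as.numeric(R %*% p + ctr)
        if (any(pw < lo + od | pw > hi - od)) next
        dd <- sqrt(rowSums(sweep(U, 2, p)^2))
        img[dd <= od] <- .PHANTOM_LEVELS[["orbit"]]
        img[dd <= od / 2] <- .PHANTOM_LEVELS[["eye"]]
        placed <- placed + 1L
      }
    }
    img[inEye] <- .PHANTOM_LEVELS[["eye"]]

    bias <- gaussBlur3D(array(rnorm(prod(dims)), dims), 40 / spacing)
    bias <- bias / max(sd(bias), 1e-9)
    img <- img * (1 + 0.15 * as.vector(bias))
    if (spec@noiseSigma > 0)
      img <- img + rnorm(length(img),
                         sd = spec@noiseSigma * .PHANTOM_LEVELS[["brain"]])

    Ut <- t(t(R) %*% (t(X) - ctr))              # unshifted truth geometry
    maskTrue <- array(rowSums(sweep(Ut, 2, semiBrain, `/`)^2) <= 1, dims)

    frameTrue <- new("AnatomicalFrame",
                     LR = as.numeric(R[, 1]), PA = as.numeric(R[, 2]),
                     IS = as.numeric(R[, 3]), origin = as.numeric(ctr),
                     handedness = 1, labels = "resolved",
                     eyeLeft = eLeft, eyeRight = eRight)
    vol <- volumeGrid(array(img, dims), spacing, affine, sliceAxis = 3L)
    truth <- new("GroundTruth", bTrue = as.numeric(ctr), eLeftTrue = eLeft,
                 eRightTrue = eRight, frameTrue = frameTrue,
                 brainMaskTrue = maskTrue)
    list(volume = vol, truth = truth)
  })
}

#' Generate a seeded phantom cohort
#'
#' `n` phantoms with poses drawn uniformly over rotations, translations
#' jittered within +/- 8 mm, and gestational ages uniform over `gaRange`.
#' Per-phantom seeds derive from the master seed, so the full cohort is
#' reproducible.
#'
#' @param n number of phantoms.
#' @param gaRange numeric(2) gestational-age range in weeks.
#' @param noiseSigma noise level (default 0.05).
#' @param oddEvenShiftMm odd/even slice displacement (default 1 mm).
#' @param decoys decoy count per phantom (default 0).
#' @param seed master seed.
#' @param biometry a \linkS4class{BiometryTable}.
#' @return List of `list(volume, truth, spec)`.
#' @export
phantomCohort <- function(n, gaRange = c(26, 37), noiseSigma = 0.05,
                          oddEvenShiftMm = 1, decoys = 0L, seed = 1L,
                          biometry = biometryTable()) {
  stopifnot(n >= 1)
  specs <- withSeed(seed, {
    subSeeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      rot <- rotationToEulerXYZ(randomRotation()) * 180 / pi
      phantomSpec(ga = runif(1, gaRange[1], gaRange[2]), rotation = rot,
                  translation = runif(3, -8, 8), noiseSigma = noiseSigma,
                  oddEvenShiftMm = oddEvenShiftMm, decoys = decoys,
                  seed = subSeeds[i])
    })
  })
  lapply(specs, function(sp) {
    out <- generatePhantom(sp, biometry)
    out$spec <- sp
    out
  })
}
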