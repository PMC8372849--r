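## Internal numerics shared across modules.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

fwhmToSigma <- function(fwhm) fwhm * FWHM_TO_SIGMA

## Mirrored-boundary index for positions 1..n shifted by off (vectorized over
## a scalar offset). Reflection about the voxel centres: 0 -> 1, n+1 -> n.
.mirrorIndex <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  p <- (idx - 1L) %% (2L * (n - 1L))
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

.gaussKernel <- function(sigmaPx) {
  if (sigmaPx <= 0) return(1)
  r <- max(1L, ceiling(3 * sigmaPx))
  k <- exp(-(seq(-r, r))^2 / (2 * sigmaPx^2))
  k / sum(k)
}

## Separable Gaussian blur of a matrix; sigma in pixels per axis, mirrored
## boundaries, kernel radius >= 3 sigma.
gaussBlur2D <- function(m, sigmaPx) {
  sigmaPx <- rep_len(sigmaPx, 2L)
  out <- m
  for (ax in 1:2) {
    s <- sigmaPx[ax]
    if (s <= 0) next
    k <- .gaussKernel(s)
    r <- (length(k) - 1L) %/% 2L
    n <- dim(out)[ax]
    acc <- array(0, dim(out))
    for (o in seq(-r, r)) {
      idx <- .mirrorIndex(seq_len(n) + o, n)
      shifted <- if (ax == 1L) out[idx, , drop = FALSE]
                 else out[, idx, drop = FALSE]
      acc <- acc + k[o + r + 1L] * shifted
    }
    out <- acc
  }
  out
}

## Separable Gaussian blur of a 3D array (used by the phantom texture).
gaussBlur3D <- function(a, sigmaPx) {
  sigmaPx <- rep_len(sigmaPx, 3L)
  out <- a
  for (ax in 1:3) {
    s <- sigmaPx[ax]
    if (s <= 0) next
    k <- .gaussKernel(s)
    r <- (length(k) - 1L) %/% 2L
    n <- dim(out)[ax]
    acc <- array(0, dim(out))
    for (o in seq(-r, r)) {
      idx <- .mirrorIndex(seq_len(n) + o, n)
      shifted <- switch(ax, out[idx, , , drop = FALSE],
                        out[, idx, , drop = FALSE],
                        out[, , idx, drop = FALSE])
      acc <- acc + k[o + r + 1L] * shifted
    }
    out <- acc
  }
  out
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Rodrigues rotation matrix about unit axis by angle (radians).
rotationAboutAxis <- function(axis, angle) {
  u <- normalize(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Intrinsic x-y-z Euler angles (radians): R = Rx(a) %*% Ry(b) %*% Rz(c).
rotationToEulerXYZ <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  if (abs(abs(R[1, 3]) - 1) < 1e-9) {          # gimbal lock
    a <- atan2(R[2, 1], R[2, 2])
    cc <- 0
  } else {
    a <- atan2(-R[2, 3], R[3, 3])
    cc <- atan2(-R[1, 2], R[1, 1])
  }
  c(a, b, cc)
}

eulerXYZToRotation <- function(abc) {
  ca <- cos(abc[1]); sa <- sin(abc[1])
  cb <- cos(abc[2]); sb <- sin(abc[2])
  cc <- cos(abc[3]); sc <- sin(abc[3])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

## Uniform random rotation (quaternion method); consumes 4 normal deviates.
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## Detection-failure condition used by every pipeline stage.
detectionFailure <- function(msg) {
  stop(structure(class = c("fetalscoutDetectionError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

isDetectionFailure <- function(e) inherits(e, "fetalscoutDetectionError")

## Run expr with a private RNG stream; restores the caller's .Random.seed.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
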