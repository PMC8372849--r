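## Slice-wise MSER detection. The production detector is a C++ max-tree
## (src/mser.cpp); mserOracle() is an exhaustive pure-R re-derivation of the
## same region semantics used as an independent cross-check in the tests.

#' MSER detector parameters
#'
#' Deliberately loose defaults: the gestational-age-specific anatomical
#' filter banks downstream do the real selection. `delta` is the stability
#' probe on the quantized (256-level) intensity scale; `maxVariation` caps
#' the relative growth rate; `minDiversity` suppresses nested duplicates,
#' keeping the most stable region of a branch.
#'
#' @param delta stability delta (quantized levels, >= 1).
#' @param minArea minimum region area in pixels.
#' @param maxAreaFrac maximum region area as a fraction of the slice.
#' @param maxVariation maximum relative growth rate.
#' @param minDiversity minimum relative area difference between retained
#'   nested regions.
#' @return A named list of parameters.
#' @export
mserParams <- function(delta = 5L, minArea = 9L, maxAreaFrac = 0.4,
                       maxVariation = 0.5, minDiversity = 0.2) {
  stopifnot(delta >= 1, minArea >= 1, maxAreaFrac > 0, maxVariation > 0,
            minDiversity >= 0)
  list(delta = as.integer(delta), minArea = as.integer(minArea),
       maxAreaFrac = maxAreaFrac, maxVariation = maxVariation,
       minDiversity = minDiversity)
}

#' Quantize a slice for MSER detection
#'
#' Linear min-max quantization to at most `maxLevels` integer levels
#' (0-based). A constant slice maps to all zeros.
#'
#' @param slice 2D numeric matrix.
#' @param maxLevels number of levels (default 256).
#' @return Integer matrix of the same size.
#' @export
quantizeSlice <- function(slice, maxLevels = 256L) {
  rng <- range(slice)
  if (!all(is.finite(rng))) stop("slice must be finite")
  out <- if (rng[2] - rng[1] < 1e-300) {
    array(0L, dim(slice))
  } else {
    array(as.integer(round((slice - rng[1]) / (rng[2] - rng[1]) *
                           (maxLevels - 1L))), dim(slice))
  }
  out
}

.asRegion <- function(rec, sliceIndex = NA_integer_) {
  structure(list(pixels = rec$pixels, sliceIndex = sliceIndex,
                 level = rec$level, stability = rec$stability,
                 area = rec$area, seed = rec$seed,
                 barycenterWorld = NULL, fit = NULL),
            class = "ExtremalRegion")
}

#' Detect maximally stable extremal regions on one slice
#'
#' Bright-polarity MSERs: connected components of the upper level sets
#' `{I >= t}` whose area is locally stable across thresholds. Each returned
#' region is a local minimum of the relative growth rate
#' `q = (|R at hi-delta| - |R at hi+delta|) / |R|` along its branch of the
#' component tree, with `q <= maxVariation`; nested duplicates are
#' suppressed by the diversity rule.
#'
#' @param slice 2D numeric matrix (finite).
#' @param params parameters from [mserParams()].
#' @return List of `ExtremalRegion` records, each with `pixels` (n x 2
#'   matrix of 1-based row/col indices), quantized `level`, `stability`
#'   score and `area`.
#' @seealso [mserOracle()] for the brute-force reference implementation.
#' @export
detectMsers <- function(slice, params = mserParams()) {
  if (length(dim(slice)) != 2L)
    stop("detectMsers expects a 2D matrix")
  if (!all(is.finite(slice))) stop("slice must be finite")
  q <- quantizeSlice(slice)
  maxArea <- as.integer(floor(params$maxAreaFrac * length(q)))
  regs <- .mser_detect_cpp(q, params$delta, params$minArea, maxArea,
                           params$maxVariation, params$minDiversity)
  lapply(regs, .asRegion)
}

## 4-connected component labelling by iterative minimum propagation.
.labelComponents4 <- function(mask) {
  lab <- array(0L, dim(mask))
  lab[mask] <- seq_len(sum(mask))
  n <- dim(mask)[1]; m <- dim(mask)[2]
  big <- .Machine$integer.max
  l <- array(big, dim(mask))
  l[mask] <- lab[mask]
  repeat {
    up <- rbind(l[-1, , drop = FALSE], rep(big, m))
    dn <- rbind(rep(big, m), l[-n, , drop = FALSE])
    lf <- cbind(l[, -1, drop = FALSE], rep(big, n))
    rt <- cbind(rep(big, n), l[, -m, drop = FALSE])
    l2 <- pmin(l, up, dn, lf, rt)
    l2[!mask] <- big
    if (identical(l2, l)) break
    l <- l2
  }
  l[!mask] <- 0L
  l
}

#' Brute-force MSER oracle
#'
#' Exhaustively thresholds a small quantized slice at every intensity
#' level, tracks every connected component's area across thresholds, and
#' returns the stability minima — the same region semantics as
#' [detectMsers()] by construction, derived without the max-tree machinery.
#' Intended as an independent test reference; capped at 48 x 48 pixels and
#' 64 quantized levels.
#'
#' @inheritParams detectMsers
#' @return List of `ExtremalRegion` records as in [detectMsers()].
#' @export
mserOracle <- function(slice, params = mserParams()) {
  if (length(dim(slice)) != 2L) stop("mserOracle expects a 2D matrix")
  if (nrow(slice) > 48L || ncol(slice) > 48L)
    stop("mserOracle is capped at 48 x 48 slices")
  if (length(unique(as.vector(slice))) > 64L)
    stop("mserOracle requires intensities quantized to <= 64 levels")
  q <- quantizeSlice(slice)
  nr <- nrow(q); npix <- length(q)
  maxArea <- as.integer(floor(params$maxAreaFrac * npix))
  delta <- params$delta
  vmin <- min(q)

  # enumerate all distinct component pixel sets
  lvls <- sort(unique(as.vector(q)), decreasing = TRUE)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  nodes <- list()
  for (t in lvls) {
    lab <- .labelComponents4(q >= t)
    ids <- setdiff(unique(as.vector(lab)), 0L)
    for (id in ids) {
      pix <- sort(which(lab == id))             # linear, 1-based
      key <- paste(pix, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        nodes[[length(nodes) + 1L]] <- list(pix = pix, hi = t)
      }
    }
  }
  nn <- length(nodes)
  areas <- vapply(nodes, function(n) length(n$pix), integer(1))
  seeds <- vapply(nodes, function(n) {
    v <- q[n$pix]
    n$pix[v == max(v)][1L]                      # max value, smallest index
  }, integer(1))

  containsSeed <- function(s) which(vapply(nodes, function(n)
    s %in% n$pix, logical(1)))

  # component of {q >= t} containing pixel s: the chain node active at t,
  # i.e. the containing node with the smallest hi >= t
  compAt <- function(s, t) {
    ids <- containsSeed(s)
    his <- vapply(nodes[ids], function(n) n$hi, numeric(1))
    ids <- ids[his >= t]
    his <- his[his >= t]
    ids[which.min(his)]
  }

  qvar <- numeric(nn)
  parentOf <- integer(nn)
  childOf <- integer(nn)
  for (i in seq_len(nn)) {
    s <- seeds[i]; vs <- q[s]
    tl <- max(nodes[[i]]$hi - delta, vmin)
    th <- min(nodes[[i]]$hi + delta, vs)
    qvar[i] <- (areas[compAt(s, tl)] - areas[compAt(s, th)]) / areas[i]
    chain <- containsSeed(s)
    chain <- chain[order(areas[chain])]
    pos <- match(i, chain)
    parentOf[i] <- if (pos < length(chain)) chain[pos + 1L] else NA_integer_
    childOf[i] <- if (pos > 1L) chain[pos - 1L] else NA_integer_
  }

  cand <- which(
    areas >= params$minArea & areas <= maxArea & qvar <= params$maxVariation &
    (is.na(parentOf) | qvar <= qvar[parentOf]) &
    (is.na(childOf) | qvar <= qvar[childOf]))
  cand <- cand[order(qvar[cand], areas[cand], seeds[cand])]

  accepted <- integer(0)
  for (n in cand) {
    ok <- TRUE
    for (a in accepted) {
      big <- if (areas[a] >= areas[n]) a else n
      small <- if (big == a) n else a
      if (all(nodes[[small]]$pix %in% nodes[[big]]$pix)) {
        div <- (areas[big] - areas[small]) / areas[big]
        if (div < params$minDiversity) { ok <- FALSE; break }
      }
    }
    if (ok) accepted <- c(accepted, n)
  }
  accepted <- accepted[order(seeds[accepted])]

  lapply(accepted, function(i) {
    pix <- nodes[[i]]$pix
    pm <- cbind((pix - 1L) %% nr + 1L, (pix - 1L) %/% nr + 1L)
    .asRegion(list(pixels = pm, level = nodes[[i]]$hi, stability = qvar[i],
                   area = areas[i], seed = seeds[i]))
  })
}
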