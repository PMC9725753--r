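#' Reduce an ER mask to its tubule ridge
#'
#' Thins the thresholded ER mask to its centerline and dilates it by one
#' pixel. Using this ridge band (rather than the full diffraction-broadened
#' Otsu band) for crossing detection keeps adjacent crossings separate and
#' suppresses spurious runs where a tubule merely grazes the mitochondrion.
#'
#' @param erMask a [BinaryMask] of the ER channel.
#' @param dilate dilate the centerline by one pixel (the band used for
#'   run detection); \code{FALSE} returns the bare centerline.
#' @return a [BinaryMask].
#' @export
erRidgeMask <- function(erMask, dilate = TRUE) {
  sk <- .thin(erMask@pixels)
  if (dilate) sk <- .maxfilt3(sk * 1) > 0
  BinaryMask(sk, erMask@calibration)
}

#' Detect ER-mitochondria crossings along the skeleton
#'
#' A crossing is a maximal run of mitochondrial skeleton pixels lying inside
#' the ER mask; its position is the run midpoint. Runs longer than
#' \code{maxParallelRunUm} indicate ER lying parallel along the mitochondrion
#' rather than traversing it; such crossings are flagged unresolvable and are
#' excluded from scoring denominators.
#'
#' @param skeleton a [SkeletonGraph] of the mitochondrial channel.
#' @param erMask a [BinaryMask] of the ER channel (same frame and
#'   calibration).
#' @param maxParallelRunUm resolvability cutoff for the overlap run length.
#' @param mergeGapUm runs on the same edge separated by less than this are
#'   one crossing (bridges single-pixel mask gaps).
#' @param dedupRadiusUm crossings from different edges closer than this are
#'   deduplicated (keep the longest run).
#' @param erImage optional ER intensity plane; used to refine positions to
#'   the intensity-weighted run centroid when no \code{erRidge} is given.
#'   When \code{erRidge} is available, positions anchor at the closest
#'   approach between the run and the ER centerline instead (the run
#'   midpoint drifts on oblique runs).
#' @param requireTraverse when \code{TRUE} and \code{erRidge} is available,
#'   a crossing must have ER ridge pixels on both sides of the local
#'   mitochondrial axis — an ER tubule traversing the mitochondrion, not
#'   grazing it.
#' @param erRidge optional thinned ER centerline [BinaryMask] used by the
#'   traversal test.
#' @return a [CrossingSet].
#' @export
detectCrossings <- function(skeleton, erMask, maxParallelRunUm = 1.0,
                            mergeGapUm = 0.3, dedupRadiusUm = 0.45,
                            erImage = NULL, requireTraverse = FALSE,
                            erRidge = NULL) {
  stopifnot(is(skeleton, "SkeletonGraph"), is(erMask, "BinaryMask"))
  px <- skeleton@calibration@pixelSize
  out <- data.frame(row = numeric(), col = numeric(), xUm = numeric(),
                    yUm = numeric(), runUm = numeric(),
                    resolvable = logical(), edge = integer(),
                    arcUm = numeric())
  for (ei in seq_along(skeleton@paths)) {
    path <- skeleton@paths[[ei]]
    if (nrow(path) < 1) next
    inside <- erMask@pixels[path]
    steps <- if (nrow(path) > 1)
      c(0, sqrt(rowSums(diff(path)^2)) * px) else 0
    arc <- cumsum(steps)
    r <- rle(inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- cbind(i0 = starts[r$values], i1 = ends[r$values])
    ## bridge short gaps: consecutive runs separated by < mergeGapUm are one
    if (nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (k in 2:nrow(runs)) {
        gap <- arc[runs[k, 1]] - arc[merged[nrow(merged), 2]]
        if (gap < mergeGapUm) merged[nrow(merged), 2] <- runs[k, 2]
        else merged <- rbind(merged, runs[k, ])
      }
      runs <- merged
    }
    for (k in seq_len(nrow(runs))) {
      i0 <- runs[k, 1]; i1 <- runs[k, 2]
      runUm <- arc[i1] - arc[i0]
      if (!is.null(erRidge)) {
        ## anchor the crossing at the closest approach between the run and
        ## the ER centerline (the run midpoint drifts on oblique runs)
        j0 <- max(1L, i0 - 2L); j1 <- min(nrow(path), i1 + 2L)
        idx <- j0:j1
        sub <- path[idx, , drop = FALSE]
        rw <- max(1L, min(sub[, 1]) - 4L):min(nrow(erRidge@pixels),
                                              max(sub[, 1]) + 4L)
        cw <- max(1L, min(sub[, 2]) - 4L):min(ncol(erRidge@pixels),
                                              max(sub[, 2]) + 4L)
        rp <- which(erRidge@pixels[rw, cw, drop = FALSE], arr.ind = TRUE)
        if (nrow(rp) > 0) {
          rp[, 1] <- rp[, 1] + rw[1] - 1L
          rp[, 2] <- rp[, 2] + cw[1] - 1L
          d2 <- outer(sub[, 1], rp[, 1], "-")^2 +
                outer(sub[, 2], rp[, 2], "-")^2
          k2 <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
          rPos <- (sub[k2[1], 1] + rp[k2[2], 1]) / 2
          cPos <- (sub[k2[1], 2] + rp[k2[2], 2]) / 2
          mi <- idx[k2[1]]
        } else {
          midArc <- (arc[i0] + arc[i1]) / 2
          mi <- i0 + which.min(abs(arc[i0:i1] - midArc)) - 1L
          rPos <- path[mi, 1]; cPos <- path[mi, 2]
        }
      } else if (!is.null(erImage)) {
        ## ER-intensity-weighted centroid over the (slightly extended) run
        j0 <- max(1L, i0 - 2L); j1 <- min(nrow(path), i1 + 2L)
        idx <- j0:j1
        w <- erImage[path[idx, , drop = FALSE]]
        w <- pmax(w - min(w), 0) + 1e-9
        rPos <- sum(w * path[idx, 1]) / sum(w)
        cPos <- sum(w * path[idx, 2]) / sum(w)
        mi <- idx[which.min((path[idx, 1] - rPos)^2 +
                            (path[idx, 2] - cPos)^2)]
      } else {
        midArc <- (arc[i0] + arc[i1]) / 2
        mi <- i0 + which.min(abs(arc[i0:i1] - midArc)) - 1L
        rPos <- path[mi, 1]; cPos <- path[mi, 2]
      }
      if (requireTraverse && !is.null(erRidge) &&
          !.traverses(path, mi, erRidge@pixels)) next
      out[nrow(out) + 1L, ] <- list(
        rPos, cPos, (cPos - 0.5) * px, (rPos - 0.5) * px,
        runUm, runUm <= maxParallelRunUm, ei, arc[mi])
    }
  }
  ## spatial dedup across edges (an ER tubule crossing at a skeleton
  ## junction touches several edges)
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    ord <- order(-out$runUm)
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      for (b in seq_len(nrow(out))) {
        if (b == i || !keep[b]) next
        if (sqrt((out$xUm[i] - out$xUm[b])^2 +
                 (out$yUm[i] - out$yUm[b])^2) < dedupRadiusUm)
          keep[b] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  new("CrossingSet", crossings = out, calibration = skeleton@calibration)
}

## does the ER centerline truly traverse the mitochondrion around path
## index mi? Requires (a) ridge pixels on both sides of the local
## mitochondrial axis and (b) a ridge orientation clearly oblique to the
## mitochondrion — a tubule shadowing the filament in parallel fails both.
.traverses <- function(path, mi, ridgePix, win = 4L, reachPx = 1.2,
                       minAngleDeg = 25) {
  n <- nrow(path)
  a <- path[max(1L, mi - 3L), ]; b <- path[min(n, mi + 3L), ]
  tangent <- b - a
  tl <- sqrt(sum(tangent^2))
  if (tl == 0) return(TRUE)
  tv <- tangent / tl
  nv <- c(-tv[2], tv[1])
  ctr <- path[mi, ]
  rr <- max(1L, ctr[1] - win):min(nrow(ridgePix), ctr[1] + win)
  cc <- max(1L, ctr[2] - win):min(ncol(ridgePix), ctr[2] + win)
  sub <- which(ridgePix[rr, cc, drop = FALSE], arr.ind = TRUE)
  if (nrow(sub) == 0) return(FALSE)
  dr <- sub[, 1] + rr[1] - 1 - ctr[1]
  dc <- sub[, 2] + cc[1] - 1 - ctr[2]
  s <- dr * nv[1] + dc * nv[2]
  if (!(max(s) >= reachPx && min(s) <= -reachPx)) return(FALSE)
  ## principal direction of the ridge pixels vs the mitochondrial tangent
  if (nrow(sub) >= 3) {
    cv <- cov(cbind(dr, dc))
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    cosang <- abs(sum(ev * tv))
    if (cosang > cos(minAngleDeg * pi / 180)) return(FALSE)
  }
  TRUE
}

#' Extract an intensity line profile along a skeleton path
#'
#' Samples the image once per path pixel with bilinear interpolation; for a
#' z-stack input one profile per slice is returned. This is the automated
#' counterpart of a manual segmented-line scan along the mitochondrion.
#'
#' @param image numeric matrix (row, col), or a 3-D array (z, row, col).
#' @param path integer/numeric matrix of (row, col) positions (e.g. an
#'   element of \code{skeleton@paths}).
#' @param calibration a [Calibration] used to express arc length in um.
#' @return list with \code{arcUm} (arc-length positions) and
#'   \code{intensity} (vector, or slice x position matrix for z-stacks).
#' @export
extractLineProfile <- function(image, path, calibration = Calibration()) {
  if (is.matrix(image)) image <- array(image, c(1L, dim(image)))
  d <- dim(image)
  if (min(path[, 1]) < 1 || min(path[, 2]) < 1 ||
      max(path[, 1]) > d[2] || max(path[, 2]) > d[3])
    stop("path extends outside the image")
  arc <- c(0, cumsum(sqrt(rowSums(diff(path)^2)))) * calibration@pixelSize
  prof <- matrix(0, d[1], nrow(path))
  for (z in seq_len(d[1]))
    prof[z, ] <- .bilinear(image[z, , ], path[, 1], path[, 2])
  if (d[1] == 1L) prof <- drop(prof)
  list(arcUm = arc, intensity = prof)
}

## bilinear interpolation at (row, col) positions (may be fractional)
.bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(pmax(floor(r), 1L), nr); r1 <- pmin(r0 + 1L, nr)
  c0 <- pmin(pmax(floor(c), 1L), nc); c1 <- pmin(c0 + 1L, nc)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

## local minima/maxima of a vector (plateau-tolerant); profile endpoints
## count as flanking maxima when they rise above their inner neighbour
.localExtrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(minima = integer(0), maxima = integer(0)))
  mins <- integer(0); maxs <- integer(0)
  for (i in 2:(n - 1)) {
    l <- x[i - 1]; v <- x[i]; r <- x[i + 1]
    if (v < l && v <= r) mins <- c(mins, i)
    if (v > l && v >= r) maxs <- c(maxs, i)
  }
  if (x[1] > x[2]) maxs <- c(1L, maxs)
  if (x[n] > x[n - 1]) maxs <- c(maxs, n)
  list(minima = mins, maxima = maxs)
}

## constriction calls on a single smoothed profile: for each local minimum,
## the reference peak is the larger flanking local maximum
.callProfile <- function(arc, y, dropThreshold) {
  ex <- .localExtrema(y)
  out <- data.frame(positionUm = numeric(), dipFraction = numeric())
  for (m in ex$minima) {
    left <- ex$maxima[ex$maxima < m]
    right <- ex$maxima[ex$maxima > m]
    if (length(left) == 0 && length(right) == 0) next
    peak <- max(c(if (length(left)) y[max(left)],
                  if (length(right)) y[min(right)]))
    if (peak <= 0) next
    dip <- 1 - y[m] / peak
    if (dip >= dropThreshold)
      out[nrow(out) + 1L, ] <- list(arc[m], dip)
  }
  out
}

## centred moving average, window w (odd); edges use shrunken windows
.movavg <- function(x, w = 3L) {
  if (w <= 1L) return(x)
  n <- length(x); h <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    out[i] <- mean(x[j])
  }
  out
}

#' Call mitochondrial constrictions on a line profile
#'
#' Marks a constriction wherever the (pre-smoothed) matrix-marker intensity
#' at a local minimum has dropped by at least \code{dropThreshold} relative
#' to the neighbouring fluorescence peak — the larger of the two flanking
#' local maxima, a conservative choice. For multi-slice input a call
#' requires the dip to be present in at least \code{minZSupport} slices
#' within \code{zMatchUm} of the same position ("along several z-planes").
#'
#' @param profile output of [extractLineProfile()] (or a list with
#'   \code{arcUm} and \code{intensity}).
#' @param dropThreshold fractional intensity decrease required (default
#'   0.40, the >=40% rule).
#' @param minZSupport slices that must confirm a dip (multi-z input only).
#' @param zMatchUm arc-length radius for matching dips across slices.
#' @param smoothWindow moving-average window in samples applied before
#'   extremum finding (manual line scans implicitly smooth; raw-pixel extrema
#'   would be noise-dominated); 1 disables.
#' @return data.frame of calls: \code{positionUm}, \code{dipFraction},
#'   \code{zSupport}.
#' @export
callConstrictions <- function(profile, dropThreshold = 0.40,
                              minZSupport = 2L, zMatchUm = 0.3,
                              smoothWindow = 3L) {
  arc <- profile$arcUm
  y <- profile$intensity
  if (is.matrix(y)) {
    if (ncol(y) < 3) stop("profile must have at least 3 samples")
    perSlice <- lapply(seq_len(nrow(y)), function(z)
      .callProfile(arc, .movavg(y[z, ], smoothWindow), dropThreshold))
    ## cluster calls across slices within zMatchUm
    all <- do.call(rbind, perSlice)
    if (is.null(all) || nrow(all) == 0)
      return(data.frame(positionUm = numeric(), dipFraction = numeric(),
                        zSupport = integer()))
    all$slice <- rep(seq_along(perSlice),
                     vapply(perSlice, nrow, integer(1)))
    all <- all[order(all$positionUm), , drop = FALSE]
    out <- data.frame(positionUm = numeric(), dipFraction = numeric(),
                      zSupport = integer())
    used <- rep(FALSE, nrow(all))
    for (i in seq_len(nrow(all))) {
      if (used[i]) next
      grp <- which(!used & abs(all$positionUm - all$positionUm[i]) <= zMatchUm)
      used[grp] <- TRUE
      support <- length(unique(all$slice[grp]))
      if (support >= minZSupport)
        out[nrow(out) + 1L, ] <- list(mean(all$positionUm[grp]),
                                      max(all$dipFraction[grp]), support)
    }
    return(out)
  }
  if (length(y) < 3) stop("profile must have at least 3 samples")
  calls <- .callProfile(arc, .movavg(y, smoothWindow), dropThreshold)
  if (nrow(calls) == 0)
    return(data.frame(positionUm = numeric(), dipFraction = numeric(),
                      zSupport = integer()))
  calls$zSupport <- 1L
  calls
}

#' Fraction of resolvable crossings carrying a constriction
#'
#' Number of resolvable ER-mitochondria crossings with at least one
#' constriction call within \code{matchRadiusUm} (along the same skeleton
#' edge), divided by the number of resolvable crossings.
#'
#' @param crossingSet a [CrossingSet].
#' @param calls data.frame of constriction calls per edge: must carry
#'   columns \code{edge} and \code{positionUm} (arc position along that
#'   edge's profile).
#' @param matchRadiusUm match radius in micrometres.
#' @return fraction in [0, 1].
#' @export
fractionCrossingsConstricted <- function(crossingSet, calls,
                                         matchRadiusUm = 0.5) {
  cr <- crossingSet@crossings
  res <- cr[cr$resolvable, , drop = FALSE]
  if (nrow(res) == 0)
    stop("no resolvable crossings: fraction undefined")
  if (is.null(calls) || nrow(calls) == 0) return(0)
  hit <- vapply(seq_len(nrow(res)), function(i) {
    if (all(c("xUm", "yUm") %in% names(calls))) {
      ## spatial matching (robust to skeleton-edge splits at junctions)
      any(sqrt((calls$xUm - res$xUm[i])^2 +
               (calls$yUm - res$yUm[i])^2) <= matchRadiusUm)
    } else {
      cand <- calls[calls$edge == res$edge[i], , drop = FALSE]
      nrow(cand) > 0 &&
        any(abs(cand$positionUm - res$arcUm[i]) <= matchRadiusUm)
    }
  }, logical(1))
  mean(hit)
}

#' Binary-mask overlap fraction (Mander's coefficient)
#'
#' Fraction of the reference mask B covered by mask A: |A intersect B| / |B|.
#' For contact-site scoring the mitochondrial mask is the reference, giving
#' the percentage of mitochondrial area overlapped by ER or ddFP signal.
#'
#' @param maskA,maskB [BinaryMask]s of identical shape; B is the reference.
#' @return fraction in [0, 1].
#' @export
overlapFraction <- function(maskA, maskB) {
  stopifnot(is(maskA, "BinaryMask"), is(maskB, "BinaryMask"))
  if (!identical(dim(maskA@pixels), dim(maskB@pixels)))
    stop("masks must have the same shape")
  nB <- sum(maskB@pixels)
  if (nB == 0) stop("empty reference mask: overlap undefined")
  sum(maskA@pixels & maskB@pixels) / nB
}

#' Line profiles and constriction calls for every skeleton edge
#'
#' Convenience wrapper: extracts a per-slice profile along each skeleton
#' edge of a z-stack's mitochondrial channel and calls constrictions,
#' annotating each call with its edge id so that
#' [fractionCrossingsConstricted()] can match calls to crossings.
#'
#' @param stack an [ImageStack] (z-stack).
#' @param skeleton a [SkeletonGraph].
#' @param channel mitochondrial channel role or index.
#' @param frame frame index.
#' @param minLengthUm skip edges shorter than this (no flanking peaks fit).
#' @param ... passed to [callConstrictions()].
#' @return data.frame of calls with columns \code{edge}, \code{positionUm},
#'   \code{dipFraction}, \code{zSupport}.
#' @export
callConstrictionsAlongSkeleton <- function(stack, skeleton, channel = "mito",
                                           frame = 1L, minLengthUm = 1.0,
                                           ...) {
  ci <- channelIndex(stack, channel)
  vol <- stack@pixels[frame, , ci, , , drop = FALSE]
  dim(vol) <- dim(stack@pixels)[c(2L, 4L, 5L)]
  out <- data.frame(edge = integer(), positionUm = numeric(),
                    dipFraction = numeric(), zSupport = integer(),
                    xUm = numeric(), yUm = numeric())
  ## a deep constriction can break the skeleton entirely; paths bridged
  ## across small gaps between facing fragment ends let the dip read as an
  ## interior minimum with flanks from both fragments
  allPaths <- c(skeleton@paths,
                .bridgedPaths(skeleton, maxGapUm = 1.2))
  edgeIds <- c(seq_along(skeleton@paths),
               rep(0L, length(allPaths) - length(skeleton@paths)))
  lens <- vapply(allPaths, function(p)
    sum(sqrt(rowSums(diff(p)^2))) * skeleton@calibration@pixelSize,
    numeric(1))
  for (ei in seq_along(allPaths)) {
    if (lens[ei] < minLengthUm) next
    ## paths are also extended straight past both ends so a dip against a
    ## junction or object end still has a rising flank on both sides
    pth <- .extendPath(allPaths[[ei]], dim(vol)[2:3],
                       nSteps = round(1 / skeleton@calibration@pixelSize))
    prof <- extractLineProfile(vol, pth, skeleton@calibration)
    if (length(prof$arcUm) < 3) next
    calls <- callConstrictions(prof, ...)
    if (nrow(calls) > 0) {
      arc <- c(0, cumsum(sqrt(rowSums(diff(pth)^2)))) *
        skeleton@calibration@pixelSize
      pos <- vapply(calls$positionUm, function(a2)
        which.min(abs(arc - a2)), integer(1))
      calls$xUm <- (pth[pos, 2] - 0.5) * skeleton@calibration@pixelSize
      calls$yUm <- (pth[pos, 1] - 0.5) * skeleton@calibration@pixelSize
      out <- rbind(out, cbind(edge = edgeIds[ei], calls))
    }
  }
  out
}

## paths joining pairs of skeleton fragment ends that face each other
## across a gap of at most maxGapUm (a broken tube)
.bridgedPaths <- function(skeleton, maxGapUm = 1.2) {
  px <- skeleton@calibration@pixelSize
  ends <- list()
  for (ei in seq_along(skeleton@paths)) {
    p <- skeleton@paths[[ei]]
    n <- nrow(p)
    if (n < 4) next
    ends[[length(ends) + 1L]] <- list(edge = ei, pt = p[1, ],
                                      dir = p[1, ] - p[min(6L, n), ],
                                      path = p[rev(seq_len(n)), ])
    ends[[length(ends) + 1L]] <- list(edge = ei, pt = p[n, ],
                                      dir = p[n, ] - p[max(1L, n - 5L), ],
                                      path = p)
  }
  outPaths <- list()
  if (length(ends) < 2) return(outPaths)
  for (i in seq_len(length(ends) - 1L)) for (j in seq(i + 1L, length(ends))) {
    a <- ends[[i]]; b <- ends[[j]]
    if (a$edge == b$edge) next
    gap <- b$pt - a$pt
    d <- sqrt(sum(gap^2)) * px
    if (d < 1e-6 || d > maxGapUm) next
    ## the two ends must point at each other
    if (sum(a$dir * gap) <= 0 || sum(b$dir * -gap) <= 0) next
    nb <- max(2L, ceiling(sqrt(sum(gap^2))))
    bridge <- cbind(round(seq(a$pt[1], b$pt[1], length.out = nb)),
                    round(seq(a$pt[2], b$pt[2], length.out = nb)))
    outPaths[[length(outPaths) + 1L]] <-
      rbind(a$path, bridge[-c(1, nb), , drop = FALSE],
            b$path[rev(seq_len(nrow(b$path))), ])
  }
  outPaths
}

## prolong a pixel path linearly beyond both ends (clipped to the image)
.extendPath <- function(path, dm, nSteps = 10L) {
  n <- nrow(path)
  if (n < 3L) return(path)
  ext <- function(tip, back) {
    dir <- (tip - back) / max(sqrt(sum((tip - back)^2)), 1e-9)
    steps <- t(vapply(seq_len(nSteps), function(k)
      round(tip + dir * k), numeric(2)))
    steps[steps[, 1] >= 1 & steps[, 1] <= dm[1] &
          steps[, 2] >= 1 & steps[, 2] <= dm[2], , drop = FALSE]
  }
  headExt <- ext(path[1, ], path[min(6L, n), ])
  tailExt <- ext(path[n, ], path[max(1L, n - 5L), ])
  rbind(headExt[rev(seq_len(nrow(headExt))), , drop = FALSE], path, tailExt)
}
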