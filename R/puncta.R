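## Laplacian-of-Gaussian kernel (positive response for bright blobs after
## negation), scale-normalized by sigma^2
.logKernel <- function(sigmaPx) {
  K <- max(2L, ceiling(3 * sigmaPx))
  g <- seq(-K, K)
  xx <- matrix(g, length(g), length(g))
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- (r2 - 2 * sigmaPx^2) / sigmaPx^4 * exp(-r2 / (2 * sigmaPx^2))
  k <- k - mean(k)          # zero-mean: flat background gives zero response
  -sigmaPx^2 * k            # scale-normalized, bright blob -> positive peak
}

## 3x3 maximum filter via shifts
.maxfilt3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, .shift(m, dr, dc))
  }
  out
}

#' Detect puncta candidates in a single frame
#'
#' Scale-space Laplacian-of-Gaussian blob detection: candidates are local
#' maxima of the scale-normalized LoG response over position and scale whose
#' peak-to-background intensity ratio reaches \code{snrMin} (background =
#' median intensity). Positions are sub-pixel refined by quadratic
#' interpolation of the response.
#'
#' @param image numeric matrix (row, col).
#' @param calibration a [Calibration].
#' @param minSigmaUm,maxSigmaUm blob scale range in micrometres.
#' @param nScales number of scales spanning the range.
#' @param snrMin minimum peak/background intensity ratio.
#' @return data.frame of candidates: \code{row}, \code{col} (sub-pixel),
#'   \code{xUm}, \code{yUm}, \code{sigmaUm}, \code{intensity},
#'   \code{response}.
#' @export
detectPunctaFrame <- function(image, calibration = Calibration(),
                              minSigmaUm = 0.12, maxSigmaUm = 0.3,
                              nScales = 3L, snrMin = 2.0) {
  px <- calibration@pixelSize
  sigmas <- seq(minSigmaUm, maxSigmaUm, length.out = nScales) / px
  resp <- lapply(sigmas, function(s)
    EBImage::imageData(EBImage::filter2(EBImage::Image(image),
                                        .logKernel(s))))
  bg <- median(image)
  empty <- data.frame(row = numeric(), col = numeric(), xUm = numeric(),
                      yUm = numeric(), sigmaUm = numeric(),
                      intensity = numeric(), response = numeric())
  cand <- empty
  for (si in seq_along(sigmas)) {
    R <- resp[[si]]
    isMax <- R >= .maxfilt3(R) & R > 0
    ## scale-space maximum: at least as large as adjacent-scale responses
    if (si > 1) isMax <- isMax & R >= resp[[si - 1]]
    if (si < length(sigmas)) isMax <- isMax & R >= resp[[si + 1]]
    idx <- which(isMax, arr.ind = TRUE)
    ## exclude the image border (no sub-pixel fit there)
    idx <- idx[idx[, 1] > 1 & idx[, 1] < nrow(image) &
               idx[, 2] > 1 & idx[, 2] < ncol(image), , drop = FALSE]
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c <- idx[k, 2]
      peak <- image[r, c]
      if (bg > 0 && peak / bg < snrMin) next
      if (bg == 0 && peak <= 0) next
      ## quadratic sub-pixel refinement on the response
      dr <- .qoff(R[r - 1, c], R[r, c], R[r + 1, c])
      dc <- .qoff(R[r, c - 1], R[r, c], R[r, c + 1])
      cand[nrow(cand) + 1L, ] <- list(
        r + dr, c + dc, (c + dc - 0.5) * px, (r + dr - 0.5) * px,
        sigmas[si] * px, peak, R[r, c])
    }
  }
  if (nrow(cand) == 0) return(empty)
  ## non-maximum suppression across scales/adjacent pixels
  cand <- cand[order(-cand$response), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    d <- sqrt((cand$row[i] - cand$row[keep])^2 +
              (cand$col[i] - cand$col[keep])^2)
    keep[i] <- all(d > 1.5 * max(sigmas))
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## quadratic 1-D sub-pixel offset, clamped to half a pixel
.qoff <- function(a, b, c) {
  den <- a - 2 * b + c
  if (den >= 0) return(0)            # not a proper maximum
  max(-0.5, min(0.5, 0.5 * (a - c) / den))
}

#' Link per-frame puncta candidates into persistent puncta
#'
#' Greedy nearest-neighbour linking across frames within \code{linkRadiusUm};
#' tracks detected in at least \code{minPersistence} of the movie's frames
#' are retained as persistent puncta (the scoring rule "present throughout a
#' 2 min movie", relaxed to tolerate isolated detection dropouts).
#'
#' @param frames list of per-frame candidate data.frames (from
#'   [detectPunctaFrame()]), one element per movie frame.
#' @param calibration a [Calibration].
#' @param linkRadiusUm maximum frame-to-frame displacement.
#' @param minPersistence minimum detected-frame fraction for retention.
#' @param role role tag stored on the output (for bookkeeping).
#' @return a [PunctaSet].
#' @export
linkPersistentPuncta <- function(frames, calibration = Calibration(),
                                 linkRadiusUm = 0.3, minPersistence = 0.8,
                                 role = "puncta") {
  nF <- length(frames)
  if (nF < 2) stop("need at least 2 frames to assess persistence")
  px <- calibration@pixelSize
  tracks <- list()   # each: list(pos = c(row, col), frames, rows, cols)
  for (t in seq_len(nF)) {
    det <- frames[[t]]
    if (is.null(det) || nrow(det) == 0) next
    assigned <- rep(FALSE, nrow(det))
    if (length(tracks) > 0) {
      last <- t(vapply(tracks, `[[`, numeric(2), "pos"))
      ## all candidate (track, detection) pairs within the radius,
      ## nearest-first one-to-one
      d <- sqrt(outer(last[, 1], det$row, "-")^2 +
                outer(last[, 2], det$col, "-")^2) * px
      pairs <- which(d <= linkRadiusUm, arr.ind = TRUE)
      if (nrow(pairs) > 0) {
        pairs <- pairs[order(d[pairs]), , drop = FALSE]
        usedTrack <- rep(FALSE, length(tracks))
        for (k in seq_len(nrow(pairs))) {
          ti <- pairs[k, 1]; di <- pairs[k, 2]
          if (usedTrack[ti] || assigned[di]) next
          usedTrack[ti] <- TRUE; assigned[di] <- TRUE
          tracks[[ti]]$pos <- c(det$row[di], det$col[di])
          tracks[[ti]]$frames <- c(tracks[[ti]]$frames, t)
          tracks[[ti]]$rows <- c(tracks[[ti]]$rows, det$row[di])
          tracks[[ti]]$cols <- c(tracks[[ti]]$cols, det$col[di])
        }
      }
    }
    for (di in which(!assigned))
      tracks[[length(tracks) + 1L]] <- list(
        pos = c(det$row[di], det$col[di]), frames = t,
        rows = det$row[di], cols = det$col[di])
  }
  persist <- vapply(tracks, function(tr) length(tr$frames) / nF, numeric(1))
  keep <- which(persist >= minPersistence)
  pu <- data.frame(
    id = seq_along(keep), role = rep(role, length(keep)),
    row = vapply(keep, function(i) mean(tracks[[i]]$rows), numeric(1)),
    col = vapply(keep, function(i) mean(tracks[[i]]$cols), numeric(1)),
    persistence = persist[keep],
    nFrames = vapply(keep, function(i) length(tracks[[i]]$frames),
                     numeric(1)))
  pu$xUm <- (pu$col - 0.5) * px
  pu$yUm <- (pu$row - 0.5) * px
  new("PunctaSet", puncta = pu,
      tracks = lapply(keep, function(i)
        data.frame(frame = tracks[[i]]$frames, row = tracks[[i]]$rows,
                   col = tracks[[i]]$cols)),
      nFramesMovie = as.integer(nF), calibration = calibration)
}

## all skeleton pixel positions in um
.skeletonPointsUm <- function(skeleton) {
  px <- skeleton@calibration@pixelSize
  pts <- do.call(rbind, skeleton@paths)
  if (is.null(pts)) return(matrix(numeric(0), 0, 2))
  cbind(x = (pts[, 2] - 0.5) * px, y = (pts[, 1] - 0.5) * px)
}

#' Puncta per micrometre of mitochondrial length
#'
#' Counts the persistent puncta assigned to the mitochondrial skeleton
#' (nearest skeleton distance at most \code{assignRadiusUm}) and divides by
#' the skeleton length — e.g. the Mfn1 density readout of fusion-machinery
#' recruitment.
#'
#' @param punctaSet a [PunctaSet].
#' @param skeleton a [SkeletonGraph]; its total length is the denominator.
#'   Alternatively pass \code{mitoLengthUm} and omit the skeleton to count
#'   all puncta against a known length.
#' @param mitoLengthUm mitochondrial length in micrometres (overrides the
#'   skeleton's).
#' @param assignRadiusUm punctum-to-mitochondrion assignment radius.
#' @return puncta per micrometre.
#' @export
punctaDensity <- function(punctaSet, skeleton = NULL, mitoLengthUm = NULL,
                          assignRadiusUm = 0.5) {
  if (is.null(mitoLengthUm)) {
    if (is.null(skeleton)) stop("need a skeleton or mitoLengthUm")
    mitoLengthUm <- totalLength(skeleton)
  }
  if (!is.finite(mitoLengthUm) || mitoLengthUm <= 0)
    stop("mitochondrial length must be positive")
  pu <- punctaSet@puncta
  if (nrow(pu) == 0) return(0)
  if (!is.null(skeleton)) {
    sk <- .skeletonPointsUm(skeleton)
    if (nrow(sk) == 0) return(0)
    dmin <- vapply(seq_len(nrow(pu)), function(i)
      min(sqrt((sk[, 1] - pu$xUm[i])^2 + (sk[, 2] - pu$yUm[i])^2)),
      numeric(1))
    n <- sum(dmin <= assignRadiusUm)
  } else n <- nrow(pu)
  n / mitoLengthUm
}

#' Fraction of resolvable crossings occupied by a punctum
#'
#' Fraction of resolvable ER-mitochondria crossings with at least one
#' persistent punctum within \code{matchRadiusUm} — the Drp1 recruitment
#' readout ("percent of ER crossings containing Drp1 puncta").
#'
#' @param crossingSet a [CrossingSet].
#' @param punctaSet a [PunctaSet].
#' @param matchRadiusUm match radius in micrometres (~ the diffraction
#'   limit).
#' @return fraction in [0, 1].
#' @export
fractionCrossingsWithPuncta <- function(crossingSet, punctaSet,
                                        matchRadiusUm = 0.3) {
  cr <- crossingSet@crossings
  res <- cr[cr$resolvable, , drop = FALSE]
  if (nrow(res) == 0) stop("no resolvable crossings: fraction undefined")
  pu <- punctaSet@puncta
  if (nrow(pu) == 0) return(0)
  hit <- vapply(seq_len(nrow(res)), function(i)
    any(sqrt((pu$xUm - res$xUm[i])^2 + (pu$yUm - res$yUm[i])^2) <=
          matchRadiusUm), logical(1))
  mean(hit)
}

#' Node density: colocalized puncta pairs per micrometre
#'
#' A node is a punctum of set A with a punctum of set B within
#' \code{colocRadiusUm} under one-to-one nearest-first matching (ties broken
#' by smaller punctum index), so one B punctum cannot validate several A
#' puncta; the matching is symmetric in A and B. Node count divided by
#' mitochondrial length gives the density of spots carrying both fission and
#' fusion machinery.
#'
#' @param punctaA,punctaB [PunctaSet]s (e.g. Drp1 and Mfn1).
#' @param skeleton a [SkeletonGraph] providing the length denominator, or
#'   \code{NULL} if \code{mitoLengthUm} is given.
#' @param mitoLengthUm mitochondrial length in micrometres.
#' @param colocRadiusUm colocalization radius.
#' @return nodes per micrometre.
#' @export
nodeDensity <- function(punctaA, punctaB, skeleton = NULL,
                        mitoLengthUm = NULL, colocRadiusUm = 0.3) {
  if (is.null(mitoLengthUm)) {
    if (is.null(skeleton)) stop("need a skeleton or mitoLengthUm")
    mitoLengthUm <- totalLength(skeleton)
  }
  if (!is.finite(mitoLengthUm) || mitoLengthUm <= 0)
    stop("mitochondrial length must be positive")
  countNodes(punctaA, punctaB, colocRadiusUm) / mitoLengthUm
}

#' @rdname nodeDensity
#' @export
countNodes <- function(punctaA, punctaB, colocRadiusUm = 0.3) {
  a <- punctaA@puncta; b <- punctaB@puncta
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  d <- sqrt(outer(a$xUm, b$xUm, "-")^2 + outer(a$yUm, b$yUm, "-")^2)
  pairs <- which(d <= colocRadiusUm, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0L)
  ## nearest-first one-to-one matching; ties by smaller index pair
  ord <- order(d[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  usedA <- rep(FALSE, nrow(a)); usedB <- rep(FALSE, nrow(b))
  n <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (usedA[i] || usedB[j]) next
    usedA[i] <- TRUE; usedB[j] <- TRUE
    n <- n + 1L
  }
  n
}

#' Detect and link puncta across a whole movie
#'
#' Runs [detectPunctaFrame()] on every frame of one channel and links the
#' candidates with [linkPersistentPuncta()].
#'
#' @param stack an [ImageStack] movie.
#' @param channel channel role or index.
#' @param z z-slice to analyse.
#' @param ... passed to [detectPunctaFrame()] and [linkPersistentPuncta()]
#'   (matched by name).
#' @return a [PunctaSet].
#' @export
detectMoviePuncta <- function(stack, channel, z = 1L, ...) {
  dots <- list(...)
  detArgs <- dots[names(dots) %in% c("minSigmaUm", "maxSigmaUm", "nScales",
                                     "snrMin")]
  linkArgs <- dots[names(dots) %in% c("linkRadiusUm", "minPersistence")]
  frames <- lapply(seq_len(nFrames(stack)), function(t)
    do.call(detectPunctaFrame,
            c(list(getPlane(stack, channel, frame = t, z = z),
                   stack@calibration), detArgs)))
  role <- if (is.character(channel)) channel else "puncta"
  do.call(linkPersistentPuncta,
          c(list(frames, stack@calibration, role = role), linkArgs))
}
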