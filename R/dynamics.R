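#' Segment a movie frame-by-frame into labeled objects
#'
#' Otsu threshold plus connected-component labeling per frame, with objects
#' below \code{minSizePx} removed (segmentation specks would otherwise seed
#' spurious tracks).
#'
#' @param stack an [ImageStack] movie.
#' @param channel channel role or index to segment.
#' @param z z-slice.
#' @param minSizePx minimum object size in pixels.
#' @param connectivity 4 or 8.
#' @return list of [LabeledObjects], one per frame.
#' @export
segmentMovie <- function(stack, channel = "native", z = 1L, minSizePx = 5L,
                         connectivity = 8) {
  lapply(seq_len(nFrames(stack)), function(t) {
    m <- otsuMask(getPlane(stack, channel, frame = t, z = z),
                  stack@calibration)
    lo <- labelComponents(m, connectivity)
    drop <- which(lo@counts < minSizePx)
    if (length(drop) > 0) {
      lab <- lo@labels
      lab[lab %in% drop] <- 0L
      lo <- labelComponents(BinaryMask(lab > 0L, stack@calibration),
                            connectivity)
    }
    lo
  })
}

#' Track objects across frames by mask overlap
#'
#' Frame-to-frame linking by maximal pixel overlap. One-to-one overlaps
#' continue a track; a one-to-many overlap map (each partner covering at
#' least \code{minOverlapFrac} of the smaller mask) records a split, a
#' many-to-one map records a merge; in both cases the outgoing objects start
#' new tracks with parent links.
#'
#' @param movieMasks list of per-frame [LabeledObjects] (see
#'   [segmentMovie()]).
#' @param minOverlapFrac minimum overlap, as a fraction of the smaller
#'   object, for a split/merge partner.
#' @return list with \code{tracks} (data.frame id, birth, death, plus the
#'   per-frame object label in \code{labelOf}), \code{assign} (per-frame
#'   integer vector label -> track id), and \code{links} (data.frame frame,
#'   type, parents, children as comma-separated track ids).
#' @export
trackComponents <- function(movieMasks, minOverlapFrac = 0.2) {
  nF <- length(movieMasks)
  if (nF < 2) stop("need at least 2 frames")
  tracks <- data.frame(id = integer(), birth = integer(), death = integer())
  assign <- vector("list", nF)
  links <- data.frame(frame = integer(), type = character(),
                      parents = character(), children = character())
  newTrack <- function(t) {
    id <- nrow(tracks) + 1L
    tracks[nrow(tracks) + 1L, ] <<- list(id, t, t)
    id
  }
  nA <- length(movieMasks[[1]]@counts)
  assign[[1]] <- vapply(seq_len(max(nA, 0L)), function(i) newTrack(1L),
                        integer(1))
  for (t in seq_len(nF - 1L)) {
    A <- movieMasks[[t]]@labels; B <- movieMasks[[t + 1L]]@labels
    sa <- movieMasks[[t]]@counts; sb <- movieMasks[[t + 1L]]@counts
    nAo <- length(sa); nBo <- length(sb)
    assign[[t + 1L]] <- integer(nBo)
    both <- A > 0L & B > 0L
    if (any(both)) {
      ov <- table(factor(A[both], levels = seq_len(nAo)),
                  factor(B[both], levels = seq_len(nBo)))
      ov <- matrix(as.integer(ov), nAo, nBo)
    } else ov <- matrix(0L, nAo, nBo)
    frac <- ov / outer(sa, sb, pmin)
    qual <- frac >= minOverlapFrac & ov > 0
    childrenOf <- lapply(seq_len(nAo), function(a) which(qual[a, ]))
    parentsOf <- lapply(seq_len(nBo), function(b) which(qual[, b]))
    handledB <- rep(FALSE, nBo)
    ## merges: child with >= 2 qualifying parents
    for (b in seq_len(nBo)) {
      pa <- parentsOf[[b]]
      if (length(pa) >= 2) {
        pids <- assign[[t]][pa]
        cid <- newTrack(t + 1L)
        assign[[t + 1L]][b] <- cid
        handledB[b] <- TRUE
        links[nrow(links) + 1L, ] <- list(
          t + 1L, "merge", paste(pids, collapse = ","), as.character(cid))
      }
    }
    ## splits: parent with >= 2 qualifying children (not already merged away)
    for (a in seq_len(nAo)) {
      ch <- childrenOf[[a]]
      ch <- ch[!handledB[ch]]
      if (length(ch) >= 2) {
        cids <- integer(0)
        for (b in ch) {
          cid <- newTrack(t + 1L)
          assign[[t + 1L]][b] <- cid
          handledB[b] <- TRUE
          cids <- c(cids, cid)
        }
        links[nrow(links) + 1L, ] <- list(
          t + 1L, "split", as.character(assign[[t]][a]),
          paste(cids, collapse = ","))
      }
    }
    ## one-to-one continuations: unhandled child with exactly one parent
    ## that maps back uniquely
    for (b in seq_len(nBo)) {
      if (handledB[b]) next
      pa <- parentsOf[[b]]
      if (length(pa) == 1L && length(childrenOf[[pa]]) == 1L &&
          childrenOf[[pa]] == b) {
        tid <- assign[[t]][pa]
        assign[[t + 1L]][b] <- tid
        tracks$death[tid] <- t + 1L
        handledB[b] <- TRUE
      }
    }
    ## births: children with no qualifying parent
    for (b in seq_len(nBo)) {
      if (!handledB[b]) {
        if (length(parentsOf[[b]]) == 1L) {
          ## parent had several children but below split criteria; continue
          tid <- assign[[t]][parentsOf[[b]]]
          if (tracks$death[tid] < t + 1L && !(tid %in% assign[[t + 1L]])) {
            assign[[t + 1L]][b] <- tid
            tracks$death[tid] <- t + 1L
            next
          }
        }
        assign[[t + 1L]][b] <- newTrack(t + 1L)
      }
    }
  }
  list(tracks = tracks, assign = assign, links = links)
}

## pixel indices of a track's mask at frame t (or NULL)
.trackMaskIdx <- function(tracking, movieMasks, tid, t) {
  lab <- match(tid, tracking$assign[[t]])
  if (is.na(lab)) return(NULL)
  which(movieMasks[[t]]@labels == lab)
}

## mean of an image over pixel indices
.meanOver <- function(plane, idx) if (length(idx) == 0) NA_real_ else
  mean(plane[idx])

## contact geometry (um) between two masks from the closest pixel pair:
## the midpoint plus the closest pixel on each partner's own side (the
## partners may still be approaching, so per-side points locate the contact
## on each object more faithfully than the midpoint)
.contactPoint <- function(labels, labA, labB, pixelSize) {
  pa <- which(labels == labA, arr.ind = TRUE)
  pb <- which(labels == labB, arr.ind = TRUE)
  if (nrow(pa) > 400) pa <- pa[seq(1, nrow(pa), length.out = 400), ]
  if (nrow(pb) > 400) pb <- pb[seq(1, nrow(pb), length.out = 400), ]
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  k <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  toUm <- function(p) c((p[2] - 0.5) * pixelSize, (p[1] - 0.5) * pixelSize)
  mid <- (pa[k[1], ] + pb[k[2], ]) / 2
  c(xUm = toUm(mid)[1], yUm = toUm(mid)[2],
    xA = toUm(pa[k[1], ])[1], yA = toUm(pa[k[1], ])[2],
    xB = toUm(pb[k[2], ])[1], yB = toUm(pb[k[2], ])[2])
}

.emptyEventRecords <- function() {
  data.frame(frame = integer(), timeS = numeric(), kind = character(),
             class = character(), p1 = integer(), p2 = integer(),
             xUm = numeric(), yUm = numeric(), xP1Um = numeric(),
             yP1Um = numeric(), xP2Um = numeric(), yP2Um = numeric(),
             evidence = numeric())
}

#' Detect fusion events by converted-fluorescence mixing
#'
#' Requires a single photoconverted source object at movie start (the object
#' whose mean converted-channel intensity stands clearly above background).
#' A fusion is recorded when an object that was not previously converted
#' merges with a converted object and, within a few frames, the
#' newly-added region's mean converted intensity reaches
#' \code{mixingRatioMin} times the donor's pre-merge mean — fluorescence
#' mixing. A transient contact without label transfer (kiss-and-run) is not
#' a fusion. A merge between two already-converted objects (e.g. a lineage
#' fragment re-fusing) carries no mixing signal and is instead scored as
#' fusion when the merge is sustained for \code{minPersistFrames} without
#' the pair re-splitting.
#'
#' @param tracking output of [trackComponents()].
#' @param movieMasks per-frame [LabeledObjects].
#' @param convertedSeries list of converted-channel planes (matrices), one
#'   per frame, or an [ImageStack] with a \code{"converted"} channel.
#' @param calibration a [Calibration] (taken from the stack if one is
#'   given).
#' @param mixingRatioMin fraction of the donor mean defining mixing.
#' @param mixWindow frames after a merge in which mixing may appear.
#' @param minPersistFrames sustained-merge requirement for converted pairs.
#' @return data.frame of fusion event records (frame, timeS, kind, class,
#'   p1 = donor track, p2 = acceptor track, contact xUm/yUm, evidence =
#'   mixing ratio).
#' @export
detectFusionEvents <- function(tracking, movieMasks, convertedSeries,
                               calibration = Calibration(),
                               mixingRatioMin = 0.1, mixWindow = 999L,
                               minPersistFrames = 3L) {
  if (is(convertedSeries, "ImageStack")) {
    calibration <- convertedSeries@calibration
    convertedSeries <- lapply(seq_len(nFrames(convertedSeries)), function(t)
      getPlane(convertedSeries, "converted", frame = t))
  }
  nF <- length(convertedSeries)
  px <- calibration@pixelSize
  interval <- calibration@frameInterval
  ## source object(s) at frame 1
  bg1 <- median(convertedSeries[[1]])
  lab1 <- movieMasks[[1]]@labels
  n1 <- length(movieMasks[[1]]@counts)
  if (n1 == 0) stop("no objects at movie start")
  means1 <- vapply(seq_len(n1), function(l)
    mean(convertedSeries[[1]][lab1 == l]), numeric(1)) - bg1
  isSrc <- means1 >= pmax(2 * mad(convertedSeries[[1]]), 0.25 * max(means1))
  if (max(means1) <= 0 || sum(isSrc) == 0)
    stop("no photoconverted source object found at movie start")
  srcMean <- max(means1)
  bgAt <- function(t) median(convertedSeries[[t]])
  ## an object's converted status is read off the converted channel
  ## directly: mean intensity over its mask relative to the source object
  ## (robust to tracking hiccups, unlike label bookkeeping)
  convAt <- function(tid, t) {
    idx <- .trackMaskIdx(tracking, movieMasks, tid, t)
    if (is.null(idx)) return(NA)
    (.meanOver(convertedSeries[[t]], idx) - bgAt(t)) >= 0.3 * srcMean
  }
  events <- .emptyEventRecords()
  links <- tracking$links
  links <- links[tracking$links$type == "merge", , drop = FALSE]
  links <- links[order(links$frame), , drop = FALSE]
  for (li in seq_len(nrow(links))) {
    f <- links$frame[li]
    pids <- as.integer(strsplit(links$parents[li], ",")[[1]])
    cid <- as.integer(links$children[li])
    if (f <= 2L || f >= nF) next            # boundary events unverifiable
    isConv <- vapply(pids, function(p) isTRUE(convAt(p, f - 1L)),
                     logical(1))
    convP <- pids[isConv]
    naiveP <- pids[!isConv]
    if (length(convP) == 0) next
    donorIdx <- lapply(convP, function(p)
      .trackMaskIdx(tracking, movieMasks, p, f - 1L))
    donorMeans <- vapply(seq_along(convP), function(k)
      .meanOver(convertedSeries[[f - 1L]], donorIdx[[k]]) - bgAt(f - 1L),
      numeric(1))
    donor <- convP[which.max(donorMeans)]
    donorMean <- max(donorMeans)
    donorFoot <- unlist(donorIdx)
    if (length(naiveP) >= 1) {
      ## one candidate fusion per naive partner (several may dock at once);
      ## each is confirmed by mixing over that partner's own pre-merge
      ## footprint, so simultaneous arrivals are scored separately
      dm <- dim(movieMasks[[1]]@labels)
      convDil <- .dilateIdx(donorFoot, dm, 2L)
      for (acceptor in naiveP) {
        ## the partner may still be moving when the masks first touch, so
        ## its region is the merged mask minus the (static) converted
        ## cluster, windowed to a generous neighbourhood of the partner's
        ## pre-merge footprint (separates simultaneous arrivals)
        aFoot <- .trackMaskIdx(tracking, movieMasks, acceptor, f - 1L)
        othersFoot <- unlist(lapply(setdiff(naiveP, acceptor), function(a2)
          .trackMaskIdx(tracking, movieMasks, a2, f - 1L)))
        region0 <- setdiff(.dilateIdx(aFoot, dm, 10L), convDil)
        if (length(othersFoot) > 0)
          region0 <- setdiff(region0, .dilateIdx(othersFoot, dm, 2L))
        mixedAt <- NA_integer_; ratio <- NA_real_
        curCid <- cid
        for (ft in seq(f, min(f + mixWindow, nF))) {
          cidx <- .trackMaskIdx(tracking, movieMasks, curCid, ft)
          if (is.null(cidx)) {
            ## the merged object may itself merge onward before mixing is
            ## read out; follow the successor object
            nxt <- .mergeSuccessor(tracking, curCid, ft)
            if (is.na(nxt)) break           # contact ended (re-split)
            curCid <- nxt
            cidx <- .trackMaskIdx(tracking, movieMasks, curCid, ft)
            if (is.null(cidx)) break
          }
          region <- intersect(region0, cidx)
          r <- (.meanOver(convertedSeries[[ft]], region) - bgAt(ft)) /
            donorMean
          if (is.finite(r) && r >= mixingRatioMin) {
            mixedAt <- ft; ratio <- r
            break
          }
        }
        if (!is.na(mixedAt)) {
          labA <- match(donor, tracking$assign[[f - 1L]])
          labB <- match(acceptor, tracking$assign[[f - 1L]])
          cp <- .contactPoint(movieMasks[[f - 1L]]@labels, labA, labB, px)
          events[nrow(events) + 1L, ] <- list(
            mixedAt, (mixedAt - 1) * interval, "fusion", "unclassified",
            donor, acceptor, cp[1], cp[2], cp[3], cp[4], cp[5], cp[6],
            ratio)
        }
        ## no mixing before the contact ends: kiss-and-run, not fusion
      }
    } else {
      ## converted + converted: sustained-merge criterion
      endF <- tracking$tracks$death[cid]
      sustained <- (endF - f + 1L) >= minPersistFrames || endF == nF ||
        .endsInMerge(tracking, cid, endF)
      if (sustained) {
        labA <- match(convP[1], tracking$assign[[f - 1L]])
        labB <- match(convP[2], tracking$assign[[f - 1L]])
        cp <- .contactPoint(movieMasks[[f - 1L]]@labels, labA, labB, px)
        events[nrow(events) + 1L, ] <- list(
          f, (f - 1) * interval, "fusion", "unclassified",
          convP[1], convP[2], cp[1], cp[2], cp[3], cp[4], cp[5], cp[6],
          NA_real_)
      }
    }
  }
  events
}

## dilate a set of linear pixel indices by r (chebyshev) in an nr x nc image
.dilateIdx <- function(idx, dm, r = 1L) {
  if (length(idx) == 0) return(integer(0))
  nr <- dm[1]; nc <- dm[2]
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  out <- integer(0)
  for (dr in -r:r) for (dc in -r:r) {
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out <- c(out, (c2[ok] - 1L) * nr + r2[ok])
  }
  unique(out)
}

#' Detect fission events from track splits
#'
#' A fission is a split whose children both persist at least
#' \code{minPersistFrames} (or to movie end) without re-merging with each
#' other — distinguishing division from transient segmentation breaks. A
#' split that undoes a merge occurring within the same window (the two
#' children matching the merge's parents) is scored as the end of a
#' transient contact, not fission. Events within one frame of the movie
#' boundaries are excluded.
#'
#' @param tracking output of [trackComponents()].
#' @param movieMasks per-frame [LabeledObjects].
#' @param calibration a [Calibration].
#' @param minPersistFrames persistence requirement in frames.
#' @return data.frame of fission event records.
#' @export
detectFissionEvents <- function(tracking, movieMasks,
                                calibration = Calibration(),
                                minPersistFrames = 3L) {
  links <- tracking$links
  nF <- length(tracking$assign)
  px <- calibration@pixelSize
  interval <- calibration@frameInterval
  events <- .emptyEventRecords()
  splits <- links[links$type == "split", , drop = FALSE]
  merges <- links[links$type == "merge", , drop = FALSE]
  for (si in seq_len(nrow(splits))) {
    f <- splits$frame[si]
    if (f <= 2L || f >= nF) next
    pid <- as.integer(splits$parents[si])
    cids <- as.integer(strsplit(splits$children[si], ",")[[1]])
    ## transient contact: parent born from a merge just before, and the
    ## split restores the merged partners (each child matching one parent)
    birth <- tracking$tracks$birth[pid]
    recent <- merges[merges$frame == birth &
                       merges$children == as.character(pid), , drop = FALSE]
    if (nrow(recent) > 0 && f - birth < minPersistFrames) {
      mp <- as.integer(strsplit(recent$parents[1], ",")[[1]])
      if (length(mp) == length(cids)) {
        assign1 <- vapply(cids, function(cid) {
          ci <- .trackMaskIdx(tracking, movieMasks, cid, f)
          best <- vapply(mp, function(p) {
            pi <- .trackMaskIdx(tracking, movieMasks, p, birth - 1L)
            length(intersect(ci, pi)) /
              max(1L, min(length(ci), length(pi)))
          }, numeric(1))
          which.max(best)
        }, integer(1))
        if (length(unique(assign1)) == length(cids)) next
      }
    }
    ## children persistence without mutual re-merge; a child that ends by
    ## merging into another object has not vanished and still counts
    persists <- vapply(cids, function(cid) {
      d <- tracking$tracks$death[cid]
      (d - f + 1L) >= minPersistFrames || d == nF ||
        .endsInMerge(tracking, cid, d)
    }, logical(1))
    if (!all(persists)) next
    remerged <- any(vapply(seq_len(nrow(merges)), function(mi) {
      merges$frame[mi] > f & merges$frame[mi] <= f + minPersistFrames &
        all(cids %in% as.integer(strsplit(merges$parents[mi], ",")[[1]]))
    }, logical(1)))
    if (remerged) next
    ## contact point: closest approach of the first child pair at frame f;
    ## a split into m pieces stands for m - 1 division events
    labA <- match(cids[1], tracking$assign[[f]])
    labB <- match(cids[2], tracking$assign[[f]])
    cp <- .contactPoint(movieMasks[[f]]@labels, labA, labB, px)
    persist <- min(vapply(cids, function(cid)
      tracking$tracks$death[cid], integer(1)) - f + 1L)
    for (m in seq_len(length(cids) - 1L))
      events[nrow(events) + 1L, ] <- list(
        f, (f - 1) * interval, "fission", "none", pid, NA_integer_,
        cp[1], cp[2], cp[3], cp[4], cp[5], cp[6], persist)
  }
  events
}

#' Classify a fusion event as tip-to-tip or tip-to-middle
#'
#' Tip-to-tip when the contact point lies within \code{dEndUm} of an
#' endpoint of both partners' pre-merge skeletons; tip-to-middle when it is
#' within \code{dEndUm} of a donor endpoint but at least \code{dEndUm} from
#' every acceptor endpoint (a tip travelling to a spot along the middle of
#' the acceptor). Any other geometry is returned as tip-to-middle with an
#' atypical flag.
#'
#' @param contactUm numeric (x, y) contact point in micrometres.
#' @param donorSkeleton,acceptorSkeleton [SkeletonGraph]s of the two
#'   partners at the frame preceding the event.
#' @param dEndUm distance defining a "tip".
#' @return list with \code{class} ("tip_to_tip"/"tip_to_middle") and
#'   \code{atypical} flag.
#' @export
classifyFusionEvent <- function(contactUm, donorSkeleton, acceptorSkeleton,
                                dEndUm = 0.5) {
  dEnds <- .endpointDistances(donorSkeleton, contactUm)
  aEnds <- .endpointDistances(acceptorSkeleton, contactUm)
  if (length(dEnds) == 0 || length(aEnds) == 0)
    stop("degenerate skeleton without endpoints: event left unclassified")
  dTip <- min(dEnds) <= dEndUm
  aTip <- min(aEnds) <= dEndUm
  if (dTip && aTip) return(list(class = "tip_to_tip", atypical = FALSE))
  if (dTip && !aTip) return(list(class = "tip_to_middle", atypical = FALSE))
  if (!dTip && aTip) return(list(class = "tip_to_middle", atypical = FALSE))
  list(class = "tip_to_middle", atypical = TRUE)
}

## distance from a partner's contacting locus (its skeleton point nearest
## the contact) to its nearest skeleton endpoint — robust to the mask halo
## extending beyond the skeleton tip
.contactLocusTipDist <- function(skeleton, contactUm) {
  pts <- .skeletonPointsUm(skeleton)
  if (nrow(pts) == 0) return(NA_real_)
  locus <- pts[which.min((pts[, 1] - contactUm[1])^2 +
                         (pts[, 2] - contactUm[2])^2), ]
  e <- .endpointDistances(skeleton, locus)
  if (length(e) == 0) NA_real_ else min(e)
}

.endpointDistances <- function(skeleton, contactUm) {
  nodes <- skeleton@nodes
  ep <- nodes[nodes$type == "endpoint", , drop = FALSE]
  if (nrow(ep) == 0) return(numeric(0))
  px <- skeleton@calibration@pixelSize
  sqrt(((ep$col - 0.5) * px - contactUm[1])^2 +
       ((ep$row - 0.5) * px - contactUm[2])^2)
}

#' Event rates per mitochondrion per minute
#'
#' Rate = event count / (number of mitochondria x duration in minutes), per
#' kind and fusion class; class rates sum exactly to the fusion total. The
#' mitochondrion denominator is the object count in the scoring field at the
#' first frame.
#'
#' @param events data.frame of event records (columns kind, class).
#' @param nMitochondria object count at the first frame.
#' @param durationMin movie duration in minutes.
#' @return data.frame with kind, class, n, rate; attributes
#'   \code{nMitochondria} and \code{durationMin}.
#' @export
computeEventRates <- function(events, nMitochondria, durationMin) {
  if (nMitochondria < 1) stop("need at least one mitochondrion")
  if (durationMin <= 0) stop("duration must be positive")
  denom <- nMitochondria * durationMin
  nFus <- sum(events$kind == "fusion")
  nT2M <- sum(events$kind == "fusion" & events$class == "tip_to_middle")
  nT2T <- sum(events$kind == "fusion" & events$class == "tip_to_tip")
  nOther <- nFus - nT2M - nT2T
  nFis <- sum(events$kind == "fission")
  out <- data.frame(
    kind = c("fusion", "fusion", "fusion", "fusion", "fission"),
    class = c("total", "tip_to_middle", "tip_to_tip", "unclassified",
              "total"),
    n = c(nFus, nT2M, nT2T, nOther, nFis),
    rate = c(nFus, nT2M, nT2T, nOther, nFis) / denom)
  attr(out, "nMitochondria") <- nMitochondria
  attr(out, "durationMin") <- durationMin
  out
}

#' Score a photoconversion movie end-to-end
#'
#' Segments the native channel, tracks objects, detects fusion (fluorescence
#' mixing) and fission (persistent separation) events, classifies fusions by
#' tip geometry of the pre-merge skeletons, and returns event records plus
#' the rate table with the first-frame object count as denominator.
#'
#' @param stack an [ImageStack] with \code{"native"} and \code{"converted"}
#'   channels.
#' @param minSizePx,minOverlapFrac segmentation/tracking parameters.
#' @param mixingRatioMin,mixWindow,minPersistFrames event-detection
#'   parameters.
#' @param dEndUm tip distance for classification.
#' @return list with \code{events}, \code{rates}, \code{nMitochondria},
#'   \code{tracking}.
#' @export
scoreDynamics <- function(stack, minSizePx = 5L, minOverlapFrac = 0.2,
                          mixingRatioMin = 0.1, mixWindow = 999L,
                          minPersistFrames = 3L, dEndUm = 0.5) {
  masks <- segmentMovie(stack, "native", minSizePx = minSizePx)
  tracking <- trackComponents(masks, minOverlapFrac)
  fus <- detectFusionEvents(tracking, masks, stack,
                            mixingRatioMin = mixingRatioMin,
                            mixWindow = mixWindow,
                            minPersistFrames = minPersistFrames)
  fis <- detectFissionEvents(tracking, masks, stack@calibration,
                             minPersistFrames = minPersistFrames)
  ## classify each fusion at its event frame, when the partners are in
  ## full contact
  for (i in seq_len(nrow(fus))) {
    cls <- .classifyDockedFusion(tracking, masks, fus$p1[i], fus$p2[i],
                                 fus$frame[i], dEndUm)
    if (!is.na(cls)) fus$class[i] <- cls
  }
  events <- rbind(fus, fis)
  nMito <- length(masks[[1]]@counts)
  durMin <- (length(masks) * stack@calibration@frameInterval) / 60
  list(events = events, rates = computeEventRates(events, nMito, durMin),
       nMitochondria = nMito, tracking = tracking)
}

## the track a merged-away track `tid` continued as at frame `ft` (NA if
## tid did not merge onward at that frame)
.mergeSuccessor <- function(tracking, tid, ft) {
  m <- tracking$links[tracking$links$type == "merge" &
                        tracking$links$frame == ft, , drop = FALSE]
  for (i in seq_len(nrow(m)))
    if (tid %in% as.integer(strsplit(m$parents[i], ",")[[1]]))
      return(as.integer(m$children[i]))
  NA_integer_
}

## did track `tid` (dead at frame d) end by merging into another object?
.endsInMerge <- function(tracking, tid, d) {
  m <- tracking$links[tracking$links$type == "merge" &
                        tracking$links$frame == d + 1L, , drop = FALSE]
  any(vapply(seq_len(nrow(m)), function(i)
    tid %in% as.integer(strsplit(m$parents[i], ",")[[1]]), logical(1)))
}

## Classify a fusion at its event frame. The partner that kept its
## pre-merge footprint (the static one) is identified by containment in the
## merged mask; the mover's final footprint is the merged mask minus the
## static partner. Each partner is a tip partner when its skeleton point
## facing the interface lies within dEndUm of one of its endpoints.
.classifyDockedFusion <- function(tracking, movieMasks, p1, p2, fEvt,
                                  dEndUm = 0.5) {
  nF <- length(movieMasks)
  fEvt <- min(fEvt, nF)
  cal <- movieMasks[[1]]@calibration
  dm <- dim(movieMasks[[1]]@labels)
  fPre <- max(1L, .mergeFrameOf(tracking, p1, p2) - 1L)
  idx1 <- .trackMaskIdx(tracking, movieMasks, p1, fPre)
  idx2 <- .trackMaskIdx(tracking, movieMasks, p2, fPre)
  if (is.null(idx1) || is.null(idx2)) return(NA_character_)
  ## merged object at the event frame: follow successor merges if needed
  child <- .mergeSuccessor(tracking, p1, fPre + 1L)
  if (is.na(child)) return(NA_character_)
  mIdx <- NULL
  for (ft in seq(fPre + 1L, fEvt)) {
    cur <- .trackMaskIdx(tracking, movieMasks, child, ft)
    if (is.null(cur)) {
      nxt <- .mergeSuccessor(tracking, child, ft)
      if (is.na(nxt)) break
      child <- nxt
      cur <- .trackMaskIdx(tracking, movieMasks, child, ft)
    }
    if (!is.null(cur)) mIdx <- cur
  }
  if (is.null(mIdx)) return(NA_character_)
  contain <- c(length(intersect(idx1, mIdx)) / length(idx1),
               length(intersect(idx2, mIdx)) / length(idx2))
  statIdx <- if (contain[1] >= contain[2]) idx1 else idx2
  statDil <- .dilateIdx(statIdx, dm, 1L)
  movIdx <- setdiff(mIdx, statDil)
  if (length(movIdx) < 5) return(NA_character_)
  mkSk <- function(idx) {
    m <- matrix(FALSE, dm[1], dm[2]); m[idx] <- TRUE
    skeletonizeMask(BinaryMask(m, cal))
  }
  toUm <- function(idx) {
    r <- ((idx - 1L) %% dm[1]) + 1L
    c2 <- ((idx - 1L) %/% dm[1]) + 1L
    cbind((c2 - 0.5) * cal@pixelSize, (r - 0.5) * cal@pixelSize)
  }
  ## topological signature on the merged skeleton: a tip joining the
  ## middle of the partner creates a branch junction at the contact,
  ## whereas tip-to-tip joins end-to-end without one
  mMask <- matrix(FALSE, dm[1], dm[2]); mMask[mIdx] <- TRUE
  ## heavier spur pruning: corner artifacts and the small overshoot poke at
  ## an end-to-end joint must not masquerade as branch junctions
  skM <- skeletonizeMask(BinaryMask(mMask, cal), pruneUm = 0.55)
  iface <- intersect(movIdx, .dilateIdx(statIdx, dm, 3L))
  if (length(iface) == 0) iface <- movIdx
  ifUm <- toUm(iface)
  ifC <- colMeans(ifUm)
  nodes <- skM@nodes
  jn <- nodes[nodes$type == "junction", , drop = FALSE]
  px <- cal@pixelSize
  junctionSaysBranch <- nrow(jn) > 0 &&
    min(sqrt(((jn$col - 0.5) * px - ifC[1])^2 +
             ((jn$row - 0.5) * px - ifC[2])^2)) <= 2 * dEndUm
  if (!junctionSaysBranch) return("tip_to_tip")
  ## corroborate with the pre-merge tip geometry: the partners' contacting
  ## skeleton loci must also place the contact away from an endpoint
  skStat <- mkSk(statIdx)
  dStat <- .contactLocusTipDist(skStat, ifC)
  if (!is.na(dStat) && dStat <= dEndUm) "tip_to_tip" else "tip_to_middle"
}

## frame at which tracks p1 and p2 merged (from the links table)
.mergeFrameOf <- function(tracking, p1, p2) {
  m <- tracking$links[tracking$links$type == "merge", , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    pids <- as.integer(strsplit(m$parents[i], ",")[[1]])
    if (all(c(p1, p2) %in% pids)) return(m$frame[i])
  }
  ## fall back: last frame both existed
  min(tracking$tracks$death[c(p1, p2)]) + 1L
}

.trackSkeleton <- function(tracking, movieMasks, tid, t) {
  idx <- .trackMaskIdx(tracking, movieMasks, tid, t)
  m <- matrix(FALSE, nrow(movieMasks[[1]]@labels),
              ncol(movieMasks[[1]]@labels))
  m[idx] <- TRUE
  skeletonizeMask(BinaryMask(m, movieMasks[[1]]@calibration))
}
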