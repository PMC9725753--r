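#' Labeled connected components
#'
#' Integer label image (0 = background, objects 1..K) with per-object pixel
#' counts; the automated counterpart of particle analysis on a thresholded
#' image.
#'
#' @slot labels integer matrix.
#' @slot counts integer vector, pixel count per label.
#' @slot calibration a [Calibration].
#' @export
setClass("LabeledObjects", representation(
  labels = "matrix", counts = "integer", calibration = "Calibration"
))

setValidity("LabeledObjects", function(object) {
  k <- length(object@counts)
  if (k > 0 && max(object@labels) != k)
    return("labels must be contiguous 1..K")
  if (sum(object@counts) != sum(object@labels > 0))
    return("pixel counts must sum to foreground size")
  TRUE
})

setMethod("show", "LabeledObjects", function(object) {
  cat(sprintf("LabeledObjects: %d object(s), %d foreground px\n",
              length(object@counts), sum(object@counts)))
})

#' @rdname LabeledObjects-class
#' @param object a \code{LabeledObjects}.
#' @export
labelImage <- function(object) object@labels
#' @rdname LabeledObjects-class
#' @export
objectSizes <- function(object) object@counts

#' Otsu threshold mask
#'
#' Thresholds a single-channel plane at the 256-bin Otsu threshold (the one
#' maximizing between-class variance of the intensity histogram); foreground
#' is strictly above the threshold. The threshold is computed on the
#' min-max-normalized histogram, so the mask is invariant to affine intensity
#' rescaling.
#'
#' @param image numeric matrix (row, col).
#' @param calibration a [Calibration] attached to the mask.
#' @return a [BinaryMask].
#' @export
otsuMask <- function(image, calibration = Calibration()) {
  BinaryMask(image > otsuThreshold(image), calibration)
}

#' @rdname otsuMask
#' @return \code{otsuThreshold()}: the threshold on the image's own
#'   intensity scale.
#' @export
otsuThreshold <- function(image) {
  rng <- range(image)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("image has no contrast (constant intensities)")
  norm <- (image - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  thr * diff(rng) + rng[1L]
}

#' Label connected foreground components
#'
#' Maximal connected sets of foreground pixels under 4- or 8-connectivity
#' (default 8, matching common particle-analysis behaviour). 8-connectivity
#' is obtained by merging 4-connected labels that touch diagonally.
#'
#' @param mask a [BinaryMask].
#' @param connectivity 4 or 8.
#' @return a [LabeledObjects].
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is(mask, "BinaryMask"), connectivity %in% c(4, 8))
  m <- mask@pixels
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  storage.mode(lab) <- "integer"
  if (connectivity == 8 && max(lab) > 1L) {
    pairs <- rbind(.diagPairs(lab, 1L, 1L), .diagPairs(lab, 1L, -1L))
    if (nrow(pairs) > 0) {
      g <- igraph::graph_from_edgelist(
        matrix(as.character(pairs), ncol = 2L), directed = FALSE)
      g <- igraph::add_vertices(
        g, length(setdiff(seq_len(max(lab)),
                          as.integer(igraph::V(g)$name))),
        name = as.character(setdiff(seq_len(max(lab)),
                                    as.integer(igraph::V(g)$name))))
      comp <- igraph::components(g)$membership
      remap <- integer(max(lab))
      remap[as.integer(names(comp))] <- comp
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  ## compact to contiguous 1..K ordered by first occurrence
  if (max(lab) > 0L) {
    ids <- sort(unique(lab[lab > 0L]))
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    counts <- as.integer(tabulate(lab[lab > 0L], nbins = length(ids)))
  } else counts <- integer(0)
  new("LabeledObjects", labels = lab, counts = counts,
      calibration = mask@calibration)
}

## label pairs straddling a diagonal step (dr, dc)
.diagPairs <- function(lab, dr, dc) {
  nr <- nrow(lab); nc <- ncol(lab)
  r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
  if (dr < 0) r1 <- r1 + abs(dr)
  if (dc < 0) c1 <- c1 + abs(dc)
  a <- lab[r1, c1, drop = FALSE]
  b <- lab[r1 + dr, c1 + dc, drop = FALSE]
  keep <- a > 0L & b > 0L & a != b
  cbind(a[keep], b[keep])
}

#' Mean area per mitochondrion in a ROI
#'
#' Total thresholded mitochondrial area inside the ROI divided by the number
#' of mitochondria (objects of at least \code{minSizePx} pixels) intersecting
#' the ROI — the average area per mitochondrion in square micrometres.
#'
#' @param mask a [BinaryMask] of the mitochondrial channel.
#' @param roi a [ROI]; \code{NULL} uses the whole mask.
#' @param minSizePx minimum object size in pixels (suppresses specks).
#' @param connectivity object connectivity, 4 or 8.
#' @return one-row data.frame: \code{meanAreaUm2}, \code{count},
#'   \code{totalAreaUm2}.
#' @export
meanAreaPerMitochondrion <- function(mask, roi = NULL, minSizePx = 5L,
                                     connectivity = 8) {
  lo <- labelComponents(mask, connectivity)
  px2 <- mask@calibration@pixelSize^2
  if (is.null(roi)) {
    inroi <- matrix(TRUE, nrow(mask@pixels), ncol(mask@pixels))
  } else {
    idx <- roiToPixels(roi, mask@calibration)
    if (max(idx$rows) > nrow(mask@pixels) || max(idx$cols) > ncol(mask@pixels))
      stop("ROI extends outside the mask")
    inroi <- matrix(FALSE, nrow(mask@pixels), ncol(mask@pixels))
    inroi[idx$rows, idx$cols] <- TRUE
  }
  keep <- which(lo@counts >= minSizePx)
  touching <- unique(lo@labels[inroi & lo@labels > 0L])
  n <- length(intersect(keep, touching))
  if (n == 0L)
    stop("no mitochondria of at least ", minSizePx, " px intersect the ROI")
  total <- sum(mask@pixels & inroi) * px2
  data.frame(meanAreaUm2 = total / n, count = n, totalAreaUm2 = total)
}

## ---- skeletonization --------------------------------------------------------

## shift a logical/numeric matrix by (dr, dc), zero fill
.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs + dr; cdst <- cs + dc
  ok_r <- rdst >= 1 & rdst <= nr; ok_c <- cdst >= 1 & cdst <= nc
  out[rdst[ok_r], cdst[ok_c]] <- m[rs[ok_r], cs[ok_c]]
  out
}

## Guo-Hall thinning to a 1-px-wide skeleton (vectorized subiterations;
## preserves diagonal lines that two-subiteration Zhang-Suen erodes)
.thin <- function(m) {
  m <- m * 1
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p2 <- .shift(m, 1, 0);  p3 <- .shift(m, 1, -1)  # N, NE (row-1 = up)
      p4 <- .shift(m, 0, -1); p5 <- .shift(m, -1, -1) # E, SE
      p6 <- .shift(m, -1, 0); p7 <- .shift(m, -1, 1)  # S, SW
      p8 <- .shift(m, 0, 1);  p9 <- .shift(m, 1, 1)   # W, NW
      C <- (1 - p2) * pmax(p3, p4) + (1 - p4) * pmax(p5, p6) +
           (1 - p6) * pmax(p7, p8) + (1 - p8) * pmax(p9, p2)
      N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      N <- pmin(N1, N2)
      mm <- if (step == 0) pmax(p6, p7, 1 - p9) * p8
            else pmax(p2, p3, 1 - p5) * p4
      del <- m == 1 & C == 1 & N >= 2 & N <= 3 & mm == 0
      if (any(del)) { m[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

## grow each skeleton endpoint along its local direction to the mask edge
## (thinning retracts line ends by a few pixels; lengths would be biased)
.extendEndpoints <- function(sk, mask, maxSteps = 6L) {
  cnt <- .neighborCount(sk)
  ends <- which(sk & cnt == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(ends))) {
    cur <- as.integer(ends[i, ])
    nb <- sweep(.OFFSETS, 2, as.numeric(cur), "+")
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(sk) &
             nb[, 2] >= 1 & nb[, 2] <= ncol(sk), , drop = FALSE]
    nb <- nb[sk[nb], , drop = FALSE]
    if (nrow(nb) != 1L) next
    dir <- cur - as.integer(nb[1, ])
    for (s in seq_len(maxSteps)) {
      nxt <- cur + dir
      if (nxt[1] < 1 || nxt[1] > nrow(sk) || nxt[2] < 1 ||
          nxt[2] > ncol(sk)) break
      if (!mask[nxt[1], nxt[2]] || sk[nxt[1], nxt[2]]) break
      ## avoid creating new junctions: the added pixel may only touch the
      ## current tip
      nb2 <- sweep(.OFFSETS, 2, as.numeric(nxt), "+")
      nb2 <- nb2[nb2[, 1] >= 1 & nb2[, 1] <= nrow(sk) &
                 nb2[, 2] >= 1 & nb2[, 2] <= ncol(sk), , drop = FALSE]
      if (sum(sk[nb2]) > 1L) break
      sk[nxt[1], nxt[2]] <- TRUE
      cur <- nxt
    }
  }
  sk
}

## 8-neighbour count of skeleton pixels
.neighborCount <- function(sk) {
  s <- sk * 1
  .shift(s, 1, 0) + .shift(s, -1, 0) + .shift(s, 0, 1) + .shift(s, 0, -1) +
    .shift(s, 1, 1) + .shift(s, 1, -1) + .shift(s, -1, 1) + .shift(s, -1, -1)
}

.OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

## prune skeleton spurs shorter than pruneUm (thinning artifacts)
.pruneSpurs <- function(sk, pixelSize, pruneUm) {
  if (pruneUm <= 0) return(sk)
  repeat {
    cnt <- .neighborCount(sk)
    ends <- which(sk & cnt == 1, arr.ind = TRUE)
    removed_any <- FALSE
    for (i in seq_len(nrow(ends))) {
      path <- list(ends[i, ]); len <- 0; prev <- c(NA, NA)
      cur <- ends[i, ]
      repeat {
        nb <- sweep(.OFFSETS, 2, as.numeric(cur), "+")
        nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(sk) &
                 nb[, 2] >= 1 & nb[, 2] <= ncol(sk), , drop = FALSE]
        nb <- nb[sk[nb], , drop = FALSE]
        isPrev <- !is.na(prev[1]) & nb[, 1] == prev[1] & nb[, 2] == prev[2]
        nb <- nb[!isPrev, , drop = FALSE]
        if (nrow(nb) != 1L) break  # junction, another end, or isolated
        nxt <- nb[1, ]
        len <- len + sqrt(sum((nxt - cur)^2)) * pixelSize
        if (len >= pruneUm) break
        if (cnt[nxt[1], nxt[2]] >= 3) {  # reached a junction: spur confirmed
          for (p in path) sk[p[1], p[2]] <- FALSE
          removed_any <- TRUE
          break
        }
        prev <- cur; cur <- nxt; path <- c(path, list(cur))
      }
    }
    if (!removed_any) break
  }
  sk
}

#' Skeletonize a mitochondrial mask into a centerline graph
#'
#' Thins the mask to a one-pixel-wide medial line (Zhang-Suen), prunes spurs
#' shorter than \code{pruneUm} (thinning artifacts that would inflate
#' endpoint counts), and organises the result as a graph of endpoint and
#' junction nodes joined by pixel-polyline edges. Edge length is the sum of
#' step lengths (1 or sqrt(2) pixels) times the pixel size, replacing the
#' manual segmented-line length measurement.
#'
#' @param mask a [BinaryMask].
#' @param pruneUm spur-pruning cutoff in micrometres.
#' @return a [SkeletonGraph]; an empty mask gives an empty graph.
#' @export
skeletonizeMask <- function(mask, pruneUm = 0.3) {
  stopifnot(is(mask, "BinaryMask"))
  pxs <- mask@calibration@pixelSize
  empty <- new("SkeletonGraph",
               nodes = data.frame(id = integer(), row = integer(),
                                  col = integer(), type = character()),
               edges = data.frame(id = integer(), from = integer(),
                                  to = integer(), lengthUm = numeric()),
               paths = list(), calibration = mask@calibration)
  if (!any(mask@pixels)) return(empty)
  sk <- .pruneSpurs(.thin(mask@pixels), pxs, pruneUm)
  if (!any(sk)) return(empty)
  sk <- .extendEndpoints(sk, mask@pixels)
  cnt <- .neighborCount(sk)
  nodePix <- sk & cnt != 2
  ## cluster adjacent node pixels (junction clusters) into single nodes
  nodeLab <- labelComponents(BinaryMask(nodePix, mask@calibration), 8)@labels
  nNodes <- max(nodeLab)
  nodes <- data.frame(id = integer(), row = integer(), col = integer(),
                      type = character())
  for (k in seq_len(nNodes)) {
    pix <- which(nodeLab == k, arr.ind = TRUE)
    deg <- cnt[nodeLab == k]
    type <- if (max(deg) >= 3) "junction"
            else if (max(deg) == 1) "endpoint" else "isolated"
    nodes <- rbind(nodes, data.frame(
      id = k, row = round(mean(pix[, 1])), col = round(mean(pix[, 2])),
      type = type))
  }
  visited <- matrix(FALSE, nrow(sk), ncol(sk))
  visited[nodePix] <- TRUE
  edges <- data.frame(id = integer(), from = integer(), to = integer(),
                      lengthUm = numeric())
  paths <- list()
  addEdge <- function(from, to, path) {
    steps <- diff(path)
    len <- if (nrow(path) < 2) 0 else
      sum(sqrt(rowSums(steps^2))) * pxs
    id <- nrow(edges) + 1L
    edges[nrow(edges) + 1L, ] <<- list(id, from, to, len)
    paths[[id]] <<- path
  }
  nbOf <- function(cur) {
    nb <- sweep(.OFFSETS, 2, as.numeric(cur), "+")
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(sk) &
             nb[, 2] >= 1 & nb[, 2] <= ncol(sk), , drop = FALSE]
    nb[sk[nb], , drop = FALSE]
  }
  ## trace from every node-pixel into each unvisited degree-2 neighbour
  nodePixList <- which(nodePix, arr.ind = TRUE)
  for (i in seq_len(nrow(nodePixList))) {
    start <- nodePixList[i, ]
    for (j in seq_len(nrow(nb0 <- nbOf(start)))) {
      nxt <- nb0[j, , drop = TRUE]
      if (nodePix[nxt[1], nxt[2]]) {
        ## direct node-node adjacency: record once (ordered) if distinct nodes
        a <- nodeLab[start[1], start[2]]; b <- nodeLab[nxt[1], nxt[2]]
        if (a < b)
          addEdge(a, b, rbind(start, nxt))
        next
      }
      if (visited[nxt[1], nxt[2]]) next
      path <- rbind(start, nxt)
      visited[nxt[1], nxt[2]] <- TRUE
      prev <- start; cur <- nxt
      repeat {
        nb <- nbOf(cur)
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        nodeHit <- nb[nodePix[nb], , drop = FALSE]
        if (nrow(nodeHit) > 0) {
          path <- rbind(path, nodeHit[1, ])
          addEdge(nodeLab[start[1], start[2]],
                  nodeLab[nodeHit[1, 1], nodeHit[1, 2]], path)
          break
        }
        nb <- nb[!visited[nb], , drop = FALSE]
        if (nrow(nb) == 0) { # dead end without node pixel (shouldn't happen)
          addEdge(nodeLab[start[1], start[2]],
                  nodeLab[start[1], start[2]], path)
          break
        }
        prev <- cur; cur <- nb[1, , drop = TRUE]
        visited[cur[1], cur[2]] <- TRUE
        path <- rbind(path, cur)
      }
    }
  }
  ## pure cycles (no node pixel): trace each remaining loop
  left <- which(sk & !visited, arr.ind = TRUE)
  while (nrow(left) > 0) {
    start <- left[1, ]
    nid <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(id = nid, row = start[1],
                                     col = start[2], type = "junction"))
    visited[start[1], start[2]] <- TRUE
    nb <- nbOf(start); nb <- nb[!visited[nb], , drop = FALSE]
    path <- rbind(start)
    if (nrow(nb) > 0) {
      prev <- start; cur <- nb[1, , drop = TRUE]
      visited[cur[1], cur[2]] <- TRUE
      path <- rbind(path, cur)
      repeat {
        nb2 <- nbOf(cur)
        nb2 <- nb2[!visited[nb2], , drop = FALSE]
        if (nrow(nb2) == 0) { path <- rbind(path, start); break }
        prev <- cur; cur <- nb2[1, , drop = TRUE]
        visited[cur[1], cur[2]] <- TRUE
        path <- rbind(path, cur)
      }
    }
    addEdge(nid, nid, path)
    left <- which(sk & !visited, arr.ind = TRUE)
  }
  rownames(nodes) <- NULL
  new("SkeletonGraph", nodes = nodes, edges = edges, paths = paths,
      calibration = mask@calibration)
}
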