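#' Score machinery recruitment densities on a puncta movie
#'
#' Per-cell recruitment scoring: segments the mitochondrial channel,
#' skeletonizes it for the length denominator, detects ER crossings, tracks
#' persistent puncta in the requested channels over the movie, and returns
#' the three recruitment metrics — Mfn1 puncta per micrometre, the fraction
#' of resolvable ER crossings occupied by a Drp1 punctum, and node
#' (Drp1+Mfn1 colocalized) density per micrometre.
#'
#' @param stack an [ImageStack] movie with a \code{"mito"} channel and any
#'   of \code{"er"}, \code{"drp1"}, \code{"mfn1"}.
#' @param snrMin punctum detection threshold.
#' @param minPersistence persistent-punctum retention fraction.
#' @param crossingMatchUm Drp1-to-crossing match radius.
#' @param colocRadiusUm node colocalization radius.
#' @return list with \code{mfn1Density}, \code{drp1CrossingFraction},
#'   \code{nodeDensity} (NA where the needed channel is absent),
#'   \code{mitoLengthUm}, \code{nCrossings}, plus the intermediate
#'   \code{skeleton}, \code{crossings}, \code{punctaSets}.
#' @export
scoreDensities <- function(stack, snrMin = 2.0, minPersistence = 0.8,
                           crossingMatchUm = 0.3, colocRadiusUm = 0.3) {
  roles <- channelRoles(stack)
  mito <- getPlane(stack, "mito", frame = 1L)
  ## the skeleton must bridge constrictions (which can dip below the Otsu
  ## level) or crossings at constricted sites disappear with it
  thr <- otsuThreshold(mito)
  bg <- median(mito)
  mask <- BinaryMask(mito > bg + 0.45 * (thr - bg), stack@calibration)
  skel <- skeletonizeMask(mask)
  L <- totalLength(skel)
  cross <- NULL
  if ("er" %in% roles) {
    erPlane <- getPlane(stack, "er", frame = 1L)
    erMask <- otsuMask(erPlane, stack@calibration)
    cross <- detectCrossings(skel, erRidgeMask(erMask),
                             erImage = erPlane, requireTraverse = TRUE,
                             erRidge = erRidgeMask(erMask, dilate = FALSE))
  }
  sets <- list()
  for (role in intersect(c("drp1", "mfn1"), roles))
    sets[[role]] <- detectMoviePuncta(stack, role, snrMin = snrMin,
                                      minPersistence = minPersistence)
  mfn1Density <- if (!is.null(sets$mfn1))
    punctaDensity(sets$mfn1, skeleton = skel) else NA_real_
  drp1Frac <- if (!is.null(sets$drp1) && !is.null(cross) &&
                  sum(cross@crossings$resolvable) > 0)
    fractionCrossingsWithPuncta(cross, sets$drp1, crossingMatchUm)
  else NA_real_
  nodeDens <- if (!is.null(sets$drp1) && !is.null(sets$mfn1))
    nodeDensity(sets$drp1, sets$mfn1, skeleton = skel,
                colocRadiusUm = colocRadiusUm) else NA_real_
  list(mfn1Density = mfn1Density, drp1CrossingFraction = drp1Frac,
       nodeDensity = nodeDens, mitoLengthUm = L,
       nCrossings = if (is.null(cross)) NA_integer_ else
         sum(cross@crossings$resolvable),
       skeleton = skel, crossings = cross, punctaSets = sets)
}

#' Score ER-associated constrictions on a z-stack
#'
#' Constriction scoring as performed on 12-slice z-stacks: the mitochondrial
#' channel is max-projected and skeletonized, ER crossings are detected on
#' the projection, per-slice line profiles are scanned for >=40% intensity
#' dips confirmed over several z-planes, and the fraction of resolvable
#' crossings coincident with a constriction is returned.
#'
#' @param stack an [ImageStack] z-stack with \code{"mito"} and \code{"er"}
#'   channels.
#' @param dropThreshold fractional dip required (default 0.40).
#' @param minZSupport slices that must confirm a dip.
#' @param matchRadiusUm crossing-to-call match radius.
#' @return list with \code{fractionConstricted}, \code{nCrossings},
#'   \code{calls}, \code{crossings}, \code{skeleton}.
#' @export
scoreConstrictions <- function(stack, dropThreshold = 0.40, minZSupport = 2L,
                               matchRadiusUm = 0.5) {
  proj <- zProject(stack, "mito")
  ## the skeleton must bridge deep constrictions (whose intensity can fall
  ## below the Otsu threshold), the way a manually drawn segmented line
  ## follows the dim neck: threshold halfway between background and Otsu
  thr <- otsuThreshold(proj)
  bg <- median(proj)
  mask <- BinaryMask(proj > bg + 0.45 * (thr - bg), stack@calibration)
  skel <- skeletonizeMask(mask)
  erPlane <- zProject(stack, "er")
  erMask <- otsuMask(erPlane, stack@calibration)
  cross <- detectCrossings(skel, erRidgeMask(erMask),
                           erImage = erPlane, requireTraverse = TRUE,
                           erRidge = erRidgeMask(erMask, dilate = FALSE))
  calls <- callConstrictionsAlongSkeleton(stack, skel,
                                          dropThreshold = dropThreshold,
                                          minZSupport = minZSupport)
  nRes <- sum(cross@crossings$resolvable)
  frac <- if (nRes > 0)
    fractionCrossingsConstricted(cross, calls, matchRadiusUm) else NA_real_
  list(fractionConstricted = frac, nCrossings = nRes, calls = calls,
       crossings = cross, skeleton = skel)
}
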