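#' @import methods
#' @importFrom stats quantile rpois rnorm runif rbinom sd var cov dist aov
#'   TukeyHSD t.test median mad pf approx setNames
#' @importFrom utils combn head tail
NULL

## Channel role vocabulary shared by stacks and scenes.
.VALID_ROLES <- c("mito", "er", "drp1", "mfn1", "ddfp", "converted", "native")

#' Spatial and temporal calibration of an acquisition
#'
#' Holds the physical scale of an image stack: lateral pixel size, axial
#' z-step, and frame interval. Defaults follow a typical 100x/1.4 NA
#' spinning-disk configuration (0.1 um/px), z-stacks of 0.2 um spacing and
#' time-lapse movies at 5 s intervals.
#'
#' @slot pixelSize lateral size of one pixel in micrometres.
#' @slot zStep axial spacing between z-slices in micrometres.
#' @slot frameInterval time between frames in seconds.
#' @export
setClass("Calibration", representation(
  pixelSize = "numeric", zStep = "numeric", frameInterval = "numeric"
))

setValidity("Calibration", function(object) {
  v <- c(object@pixelSize, object@zStep, object@frameInterval)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    return("pixelSize, zStep and frameInterval must be single positive numbers")
  TRUE
})

#' @param pixelSize,zStep,frameInterval see slots.
#' @rdname Calibration-class
#' @export
Calibration <- function(pixelSize = 0.1, zStep = 0.2, frameInterval = 5) {
  new("Calibration", pixelSize = pixelSize, zStep = zStep,
      frameInterval = frameInterval)
}

#' Calibrated multi-channel image stack
#'
#' A non-negative intensity array indexed (frame, z, channel, row, col)
#' together with a channel-role map and a [Calibration]. Roles name what each
#' channel images: \code{"mito"} (matrix marker), \code{"er"} (ER membrane),
#' \code{"drp1"}/\code{"mfn1"} (machinery puncta), \code{"ddfp"}
#' (contact-site reporter), \code{"native"}/\code{"converted"}
#' (photoconvertible outer-membrane label before/after conversion).
#'
#' @slot pixels 5-D numeric array, dimensions (T, Z, C, Y, X).
#' @slot channelRoles character vector of length C with role tags.
#' @slot calibration a [Calibration].
#' @export
setClass("ImageStack", representation(
  pixels = "array", channelRoles = "character", calibration = "Calibration"
))

setValidity("ImageStack", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 5L)
    return("pixels must be a 5-D array (frame, z, channel, row, col)")
  if (length(object@channelRoles) != d[3L])
    return("channelRoles length must equal the channel dimension")
  if (!all(object@channelRoles %in% .VALID_ROLES))
    return(paste("channel roles must be one of:",
                 paste(.VALID_ROLES, collapse = ", ")))
  if (anyDuplicated(object@channelRoles))
    return("channel roles must be unique")
  px <- object@pixels
  if (any(!is.finite(px)) || any(px < 0))
    return("intensities must be finite and >= 0")
  TRUE
})

#' @param pixels array of intensities; 2-D (Y,X) up to 5-D (T,Z,C,Y,X) input
#'   is promoted to 5-D, missing leading dimensions taken as singletons in the
#'   order channel, z, frame.
#' @param channelRoles character vector of role tags, one per channel.
#' @param calibration a [Calibration].
#' @rdname ImageStack-class
#' @export
ImageStack <- function(pixels, channelRoles = "mito",
                       calibration = Calibration()) {
  d <- dim(pixels)
  if (is.null(d)) stop("pixels must be an array")
  if (length(d) == 2L) d <- c(1L, 1L, 1L, d)
  else if (length(d) == 3L) d <- c(1L, 1L, d)       # (C, Y, X)
  else if (length(d) == 4L) d <- c(1L, d)           # (Z, C, Y, X)
  else if (length(d) != 5L) stop("pixels must have 2 to 5 dimensions")
  new("ImageStack", pixels = array(as.numeric(pixels), dim = d),
      channelRoles = channelRoles, calibration = calibration)
}

#' Rectangular region of interest
#'
#' Origin is the top-left pixel (1-based row/col); size is given in
#' micrometres and converted with the stack's pixel size when applied. The
#' two ROI geometries used for scoring are 15x15 um (morphology,
#' constrictions) and 20x20 um (overlap).
#'
#' @slot origin integer (row, col) of the top-left pixel, 1-based.
#' @slot sizeUm numeric (height, width) in micrometres.
#' @export
setClass("ROI", representation(origin = "integer", sizeUm = "numeric"))

setValidity("ROI", function(object) {
  if (length(object@origin) != 2L || any(object@origin < 1L))
    return("origin must be two 1-based pixel indices (row, col)")
  if (length(object@sizeUm) != 2L || any(object@sizeUm <= 0))
    return("sizeUm must be two positive lengths (height, width) in um")
  TRUE
})

#' @param origin,sizeUm see slots; sizeUm of length 1 is recycled (square ROI).
#' @rdname ROI-class
#' @export
ROI <- function(origin = c(1L, 1L), sizeUm = 15) {
  if (length(sizeUm) == 1L) sizeUm <- rep(sizeUm, 2L)
  new("ROI", origin = as.integer(origin), sizeUm = as.numeric(sizeUm))
}

#' Binary segmentation mask
#'
#' A logical (row, col) plane with the calibration of its source image.
#'
#' @slot pixels logical matrix.
#' @slot calibration a [Calibration].
#' @export
setClass("BinaryMask", representation(
  pixels = "matrix", calibration = "Calibration"
))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("mask pixels must be logical")
  TRUE
})

#' @param pixels logical matrix (row, col).
#' @param calibration a [Calibration].
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(pixels, calibration = Calibration()) {
  storage.mode(pixels) <- "logical"
  new("BinaryMask", pixels = pixels, calibration = calibration)
}

#' Mitochondrial centerline graph
#'
#' One-pixel-wide medial representation of a mitochondrial mask, organised as
#' a graph: nodes are endpoints and junctions, edges are pixel polylines with
#' path lengths in micrometres. Replaces the manual segmented-line length
#' measurement with a reproducible skeleton.
#'
#' @slot nodes data.frame with columns id, row, col, type
#'   ("endpoint"/"junction"/"isolated").
#' @slot edges data.frame with columns id, from, to, lengthUm.
#' @slot paths list of integer matrices (row, col), one polyline per edge.
#' @slot calibration a [Calibration].
#' @export
setClass("SkeletonGraph", representation(
  nodes = "data.frame", edges = "data.frame", paths = "list",
  calibration = "Calibration"
))

setValidity("SkeletonGraph", function(object) {
  if (nrow(object@edges) != length(object@paths))
    return("one path per edge required")
  if (nrow(object@edges) > 0) {
    if (any(object@edges$lengthUm < 0)) return("edge lengths must be >= 0")
    if (!all(c(object@edges$from, object@edges$to) %in% object@nodes$id))
      return("every edge endpoint must be a node")
  }
  TRUE
})

#' Set of ER-mitochondria crossings
#'
#' Positions where an ER tubule traverses the mitochondrial skeleton. Each
#' crossing is the midpoint of a maximal run of skeleton pixels inside the ER
#' mask; runs longer than the parallel-run cutoff are flagged unresolvable
#' and excluded from scoring denominators.
#'
#' @slot crossings data.frame with columns row, col (pixel midpoint), xUm,
#'   yUm, runUm (overlap run length), resolvable (logical), edge (edge id).
#' @slot calibration a [Calibration].
#' @export
setClass("CrossingSet", representation(
  crossings = "data.frame", calibration = "Calibration"
))

#' Persistent puncta detections
#'
#' Machinery puncta tracked across a movie. A punctum is retained when
#' detected in at least the persistence fraction of frames (the scoring rule
#' "present throughout a 2 min movie", relaxed to tolerate detection
#' dropouts).
#'
#' @slot puncta data.frame with columns id, role, row, col (mean centroid,
#'   pixels), xUm, yUm, persistence (fraction of frames), nFrames.
#' @slot tracks list of per-punctum data.frames (frame, row, col).
#' @slot nFramesMovie integer, frames in the source movie.
#' @slot calibration a [Calibration].
#' @export
setClass("PunctaSet", representation(
  puncta = "data.frame", tracks = "list", nFramesMovie = "integer",
  calibration = "Calibration"
))

#' Synthetic ground-truth scene
#'
#' Generator output: mitochondrial filaments (centerline polylines in um with
#' radius and per-vertex constriction factors), ER tubules, puncta with
#' persistence windows, a Poisson event schedule, and photoconversion label
#' states. Scenes are rendered to [ImageStack] movies/z-stacks and exported
#' as ground-truth tables; identical parameters and seed give identical
#' scenes.
#'
#' @slot filaments list; each element has points (n x 2 matrix, um x/y),
#'   radiusUm, constriction (per-vertex factor in (0,1]), tStart/tEnd frame
#'   window, convertedFrom (frame or Inf), group (object id per frame basis),
#'   offsets (T x 2 per-frame translation, um).
#' @slot tubules list of n x 2 um polylines.
#' @slot puncta data.frame (role, filament, arc, x, y, from, to).
#' @slot events data.frame schedule (see [exportGroundTruth]).
#' @slot fovUm numeric (height, width) field size in um.
#' @slot durationS movie duration in seconds.
#' @slot nFrames integer number of frames.
#' @slot params list of generator parameters.
#' @slot seed integer seed the scene was built from.
#' @export
setClass("SceneGraph", representation(
  filaments = "list", tubules = "list", puncta = "data.frame",
  events = "data.frame", fovUm = "numeric", durationS = "numeric",
  nFrames = "integer", params = "list", seed = "integer"
))

## ---- show methods -----------------------------------------------------------

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.4g um/px, z-step %.4g um, %.4g s/frame\n",
              object@pixelSize, object@zStep, object@frameInterval))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageStack: %d frame(s) x %d z x %d channel(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat("  roles:", paste(object@channelRoles, collapse = ", "), "\n")
  show(object@calibration)
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI: origin (%d, %d) px, size %.3g x %.3g um\n",
              object@origin[1], object@origin[2],
              object@sizeUm[1], object@sizeUm[2]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask: %d x %d px, %d foreground\n",
              d[1], d[2], sum(object@pixels)))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf(
    "SkeletonGraph: %d node(s), %d edge(s), total length %.3g um\n",
    nrow(object@nodes), nrow(object@edges), totalLength(object)))
})

setMethod("show", "CrossingSet", function(object) {
  cat(sprintf("CrossingSet: %d crossing(s), %d resolvable\n",
              nrow(object@crossings), sum(object@crossings$resolvable)))
})

setMethod("show", "PunctaSet", function(object) {
  cat(sprintf("PunctaSet: %d persistent punctum/a over %d frame(s)\n",
              nrow(object@puncta), object@nFramesMovie))
})

setMethod("show", "SceneGraph", function(object) {
  cat(sprintf(
    "SceneGraph: %d filament(s), %d ER tubule(s), %d punctum/a, %d event(s)\n",
    length(object@filaments), length(object@tubules),
    nrow(object@puncta), nrow(object@events)))
  cat(sprintf("  fov %.3g x %.3g um, %d frame(s) over %.4g s\n",
              object@fovUm[1], object@fovUm[2], object@nFrames,
              object@durationS))
})

## ---- accessors --------------------------------------------------------------

#' Accessors for calibrated containers
#'
#' @param object an object carrying a [Calibration] (stack, mask, skeleton).
#' @return \code{calibration()} the [Calibration]; \code{pixelSize()},
#'   \code{zStep()}, \code{frameInterval()} the corresponding scalars;
#'   \code{nFrames()}, \code{nSlices()}, \code{nChannels()} stack dimensions;
#'   \code{channelRoles()} the role tags.
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

#' @rdname calibration
#' @export
setMethod("calibration", "ImageStack", function(object) object@calibration)
#' @rdname calibration
#' @export
setMethod("calibration", "BinaryMask", function(object) object@calibration)
#' @rdname calibration
#' @export
setMethod("calibration", "SkeletonGraph", function(object) object@calibration)
#' @rdname calibration
#' @export
setMethod("calibration", "CrossingSet", function(object) object@calibration)
#' @rdname calibration
#' @export
setMethod("calibration", "PunctaSet", function(object) object@calibration)

#' @rdname calibration
#' @export
pixelSize <- function(object) calibration(object)@pixelSize
#' @rdname calibration
#' @export
zStep <- function(object) calibration(object)@zStep
#' @rdname calibration
#' @export
frameInterval <- function(object) calibration(object)@frameInterval
#' @rdname calibration
#' @export
nFrames <- function(object) dim(object@pixels)[1L]
#' @rdname calibration
#' @export
nSlices <- function(object) dim(object@pixels)[2L]
#' @rdname calibration
#' @export
nChannels <- function(object) dim(object@pixels)[3L]
#' @rdname calibration
#' @export
channelRoles <- function(object) object@channelRoles

#' Extract a single image plane from a stack
#'
#' @param stack an [ImageStack].
#' @param channel channel role tag (e.g. \code{"mito"}) or integer index.
#' @param frame frame index (1-based).
#' @param z z-slice index (1-based).
#' @return numeric matrix (row, col).
#' @export
getPlane <- function(stack, channel = 1L, frame = 1L, z = 1L) {
  ci <- channelIndex(stack, channel)
  stack@pixels[frame, z, ci, , , drop = TRUE]
}

#' Resolve a channel role to its index
#'
#' @param stack an [ImageStack].
#' @param channel role tag or integer index.
#' @return integer channel index.
#' @export
channelIndex <- function(stack, channel) {
  if (is.numeric(channel)) {
    ci <- as.integer(channel)
    if (ci < 1L || ci > nChannels(stack)) stop("channel index out of range")
    return(ci)
  }
  ci <- match(channel, stack@channelRoles)
  if (is.na(ci)) stop("no channel with role '", channel, "'")
  ci
}

#' Skeleton accessors
#'
#' @param object a [SkeletonGraph].
#' @return \code{totalLength()}: summed edge length in micrometres;
#'   \code{skeletonNodes()} / \code{skeletonEdges()}: the node/edge tables.
#' @export
totalLength <- function(object) {
  if (nrow(object@edges) == 0) 0 else sum(object@edges$lengthUm)
}
#' @rdname totalLength
#' @export
skeletonNodes <- function(object) object@nodes
#' @rdname totalLength
#' @export
skeletonEdges <- function(object) object@edges

#' Crossing and puncta table accessors
#'
#' @param object a [CrossingSet] or [PunctaSet].
#' @return the underlying data.frame.
#' @export
crossings <- function(object) object@crossings
#' @rdname crossings
#' @export
puncta <- function(object) object@puncta
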