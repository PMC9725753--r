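#' Read a calibrated image stack from TIFF
#'
#' Reads a multi-page TIFF written by [writeStack()] (or any plain TIFF) into
#' an [ImageStack]. Stack geometry, channel roles and calibration are taken
#' from the JSON sidecar \code{<path>.json}; when the sidecar is absent the
#' pages are interpreted as frames of a single-channel, single-slice movie
#' and the default calibration (0.1 um/px, 0.2 um z-step, 5 s/frame) is used
#' with a warning.
#'
#' @param path path to a TIFF file.
#' @return an [ImageStack].
#' @seealso [writeStack()], [cropRoi()]
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!all(vapply(pages, is.numeric, logical(1))))
    stop("non-numeric pixel data in ", path)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    d <- as.integer(meta$dim)
    if (length(d) != 5L || prod(d[1:3]) != length(pages))
      stop("sidecar dimensions inconsistent with TIFF page count")
    roles <- as.character(meta$channelRoles)
    cal <- Calibration(meta$calibration$pixelSize, meta$calibration$zStep,
                       meta$calibration$frameInterval)
    scale <- if (is.null(meta$intensityScale)) 1 else meta$intensityScale
  } else {
    warning("no metadata sidecar for ", path,
            "; assuming single-channel movie with default calibration")
    d <- c(length(pages), 1L, 1L, dim(pages[[1L]]))
    roles <- "mito"
    cal <- Calibration()
    scale <- 1
  }
  px <- array(0, dim = d)
  k <- 1L
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) for (c in seq_len(d[3L])) {
    page <- pages[[k]]
    if (!identical(dim(page)[1:2], d[4:5]))
      stop("page ", k, " spatial size differs from declared shape")
    if (length(dim(page)) > 2L) page <- page[, , 1L]  # tolerate grey+alpha
    px[t, z, c, , ] <- page * scale
    k <- k + 1L
  }
  ImageStack(px, channelRoles = roles, calibration = cal)
}

#' Write a calibrated image stack to TIFF
#'
#' Writes planes as 32-bit float TIFF pages in (frame, z, channel) order,
#' plus a JSON sidecar \code{<path>.json} carrying dimensions, channel roles
#' and calibration so that [readStack()] reproduces the stack exactly.
#' Intensities are stored unscaled; values above 1 are preserved (float
#' samples).
#'
#' @param stack an [ImageStack].
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  validObject(stack)
  d <- dim(stack@pixels)
  ## float TIFF samples are defined on [0, 1]; store normalized intensities
  ## and keep the scale in the sidecar
  scale <- max(stack@pixels)
  if (scale <= 0) scale <- 1
  pages <- vector("list", prod(d[1:3]))
  k <- 1L
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) for (c in seq_len(d[3L])) {
    pages[[k]] <- stack@pixels[t, z, c, , , drop = TRUE] / scale
    k <- k + 1L
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
                 error = function(e) stop("cannot write TIFF: ",
                                          conditionMessage(e)))
  cal <- stack@calibration
  jsonlite::write_json(
    list(dim = d, channelRoles = stack@channelRoles, intensityScale = scale,
         calibration = list(pixelSize = cal@pixelSize, zStep = cal@zStep,
                            frameInterval = cal@frameInterval)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a ROI to pixel bounds
#'
#' Micrometre sizes are converted with the pixel size and rounded to whole
#' pixels; the ROI is half-open, covering rows
#' \code{origin[1] .. origin[1] + h - 1}.
#'
#' @param roi a [ROI].
#' @param calibration a [Calibration].
#' @return list with integer \code{rows} and \code{cols} index vectors.
#' @export
roiToPixels <- function(roi, calibration = Calibration()) {
  px <- calibration@pixelSize
  h <- as.integer(round(roi@sizeUm[1L] / px))
  w <- as.integer(round(roi@sizeUm[2L] / px))
  list(rows = seq.int(roi@origin[1L], length.out = h),
       cols = seq.int(roi@origin[2L], length.out = w))
}

#' Crop a stack to a rectangular ROI
#'
#' Extracts the exact pixel sub-array covered by the ROI (no interpolation);
#' calibration and channel roles are unchanged.
#'
#' @param stack an [ImageStack].
#' @param roi a [ROI].
#' @return an [ImageStack] of spatial size \code{round(sizeUm / pixelSize)}.
#' @export
cropRoi <- function(stack, roi) {
  stopifnot(is(stack, "ImageStack"), is(roi, "ROI"))
  idx <- roiToPixels(roi, stack@calibration)
  d <- dim(stack@pixels)
  if (min(idx$rows) < 1L || min(idx$cols) < 1L ||
      max(idx$rows) > d[4L] || max(idx$cols) > d[5L])
    stop("ROI extends outside the image")
  ImageStack(stack@pixels[, , , idx$rows, idx$cols, drop = FALSE],
             channelRoles = stack@channelRoles,
             calibration = stack@calibration)
}

#' Crop a binary mask to a ROI
#'
#' @param mask a [BinaryMask].
#' @param roi a [ROI].
#' @return a [BinaryMask].
#' @export
cropMask <- function(mask, roi) {
  idx <- roiToPixels(roi, mask@calibration)
  d <- dim(mask@pixels)
  if (min(idx$rows) < 1L || min(idx$cols) < 1L ||
      max(idx$rows) > d[1L] || max(idx$cols) > d[2L])
    stop("ROI extends outside the mask")
  BinaryMask(mask@pixels[idx$rows, idx$cols, drop = FALSE], mask@calibration)
}

#' Maximum (or mean) z-projection of one channel
#'
#' The scoring pipeline operates on a z-projection of the mitochondrial
#' channel by default; whether the original analysis excluded out-of-focus
#' slices is not recorded, so the projection mode is explicit here.
#'
#' @param stack an [ImageStack].
#' @param channel role tag or index.
#' @param frame frame index.
#' @param method \code{"max"} (default) or \code{"mean"}.
#' @return numeric matrix (row, col).
#' @export
zProject <- function(stack, channel = "mito", frame = 1L,
                     method = c("max", "mean")) {
  method <- match.arg(method)
  ci <- channelIndex(stack, channel)
  planes <- stack@pixels[frame, , ci, , , drop = FALSE]
  dim(planes) <- dim(stack@pixels)[c(2L, 4L, 5L)]
  if (method == "max") apply(planes, c(2L, 3L), max)
  else apply(planes, c(2L, 3L), mean)
}
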