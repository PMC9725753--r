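## ---- seeded evaluation ------------------------------------------------------

## run fn() under a temporary RNG state seeded with `seed`; the caller's
## global RNG state is restored afterwards (no global random state leaks)
.withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

## ---- optics -----------------------------------------------------------------

#' Optical and camera model for rendering
#'
#' Parameters of the confocal-like forward model used by [renderMovie()] and
#' [renderZStack()]: Gaussian lateral PSF, constant background, photon scale
#' (counts at an unobstructed filament centerline), Poisson shot noise and
#' Gaussian read noise.
#'
#' @param psfSigmaUm lateral PSF sigma in micrometres.
#' @param background background level in counts.
#' @param photonScale counts per unit emitter density (a filament of
#'   constriction factor 1 peaks at roughly \code{background + photonScale}).
#' @param readNoiseSd Gaussian read-noise standard deviation in counts.
#' @param poissonNoise logical, apply Poisson shot noise.
#' @param axialSigmaUm axial extent of the detection profile used by
#'   [renderZStack()] (Gaussian attenuation with defocus).
#' @return a list of class \code{"OpticsModel"}.
#' @export
opticsModel <- function(psfSigmaUm = 0.15, background = 100,
                        photonScale = 400, readNoiseSd = 3,
                        poissonNoise = TRUE, axialSigmaUm = 0.35) {
  stopifnot(psfSigmaUm > 0, photonScale > 0, background >= 0,
            readNoiseSd >= 0, axialSigmaUm > 0)
  structure(list(psfSigmaUm = psfSigmaUm, background = background,
                 photonScale = photonScale, readNoiseSd = readNoiseSd,
                 poissonNoise = isTRUE(poissonNoise),
                 axialSigmaUm = axialSigmaUm),
            class = "OpticsModel")
}

## ---- scene parameters -------------------------------------------------------

#' Parameters of a synthetic scene
#'
#' Defaults reproduce the control-condition geometry the scoring pipeline was
#' designed for: a 15 x 15 um field holding 8 mitochondrial filaments and 6
#' ER tubules; 2-min movies at 5-s intervals for puncta scoring; 60% of ER
#' crossings constricted; Mfn1 puncta at 0.30 per um; Drp1 at 47% of
#' crossings; fusion/fission scheduled as homogeneous Poisson processes at
#' per-mitochondrion-per-minute rates. Every density/rate can be set per
#' condition.
#'
#' @param nMito number of mitochondrial filaments.
#' @param mitoLengthUm length range (uniform) in micrometres.
#' @param mitoRadiusUm tube radius range in micrometres.
#' @param nErTubules number of ER tubules spanning the field.
#' @param crossingConstrictionProb probability that an ER crossing carries a
#'   constriction.
#' @param constrictionMinFactor range of the minimum radius factor at a
#'   constriction site (a factor f renders as a fractional intensity dip of
#'   1 - f^2 for a matrix marker).
#' @param mfn1PerUm persistent Mfn1 puncta per micrometre of filament.
#' @param drp1AtCrossingProb probability a resolvable crossing carries a
#'   persistent Drp1 punctum.
#' @param nodePerUm coincident Drp1+Mfn1 punctum pairs (nodes) per
#'   micrometre.
#' @param transientPerUm short-lived (2-frame) distractor puncta per
#'   micrometre, per punctum channel.
#' @param fusionRatePerMitoMin,fissionRatePerMitoMin event rates per
#'   mitochondrion per minute.
#' @param tipToMiddleFraction fraction of fusion events of the tip-to-middle
#'   class.
#' @param classMode \code{"bernoulli"} draws each fusion class independently;
#'   \code{"exact"} fixes the class counts at the rounded programmed
#'   fraction.
#' @param photoconvert logical; designate a conversion seed filament and
#'   schedule all fusions to involve its lineage (the scorable events in a
#'   photoconversion assay).
#' @param durationS movie duration in seconds.
#' @param frameIntervalS frame interval in seconds.
#' @param fovUm field of view (height, width) in micrometres.
#' @return named list of parameters.
#' @export
sceneParams <- function(nMito = 8, mitoLengthUm = c(2.5, 5.5),
                        mitoRadiusUm = c(0.16, 0.24), nErTubules = 6,
                        crossingConstrictionProb = 0.6,
                        constrictionMinFactor = c(0.3, 0.5),
                        mfn1PerUm = 0, drp1AtCrossingProb = 0,
                        nodePerUm = 0, transientPerUm = 0,
                        fusionRatePerMitoMin = 0, fissionRatePerMitoMin = 0,
                        tipToMiddleFraction = 0.74,
                        classMode = c("bernoulli", "exact"),
                        photoconvert = FALSE, durationS = 120,
                        frameIntervalS = 5, fovUm = c(15, 15)) {
  classMode <- match.arg(classMode)
  if (length(fovUm) == 1L) fovUm <- rep(fovUm, 2L)
  p <- list(nMito = nMito, mitoLengthUm = mitoLengthUm,
            mitoRadiusUm = mitoRadiusUm, nErTubules = nErTubules,
            crossingConstrictionProb = crossingConstrictionProb,
            constrictionMinFactor = constrictionMinFactor,
            mfn1PerUm = mfn1PerUm, drp1AtCrossingProb = drp1AtCrossingProb,
            nodePerUm = nodePerUm, transientPerUm = transientPerUm,
            fusionRatePerMitoMin = fusionRatePerMitoMin,
            fissionRatePerMitoMin = fissionRatePerMitoMin,
            tipToMiddleFraction = tipToMiddleFraction, classMode = classMode,
            photoconvert = photoconvert, durationS = durationS,
            frameIntervalS = frameIntervalS, fovUm = fovUm)
  rates <- c(p$mfn1PerUm, p$drp1AtCrossingProb, p$nodePerUm, p$transientPerUm,
             p$fusionRatePerMitoMin, p$fissionRatePerMitoMin,
             p$crossingConstrictionProb)
  if (any(rates < 0)) stop("densities, probabilities and rates must be >= 0")
  if (p$nMito * 1.2 > prod(p$fovUm) / 4)
    stop("field of view too small for the requested number of filaments")
  p
}

## ---- polyline helpers -------------------------------------------------------

## resample a polyline at arc step ds; returns x, y, arc, and linear
## interpolation of an optional per-vertex attribute
.resamplePolyline <- function(points, ds, attr = NULL) {
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  s <- seq(0, L, by = ds)
  x <- approx(arc, points[, 1], xout = s)$y
  y <- approx(arc, points[, 2], xout = s)$y
  a <- if (is.null(attr)) NULL else approx(arc, attr, xout = s)$y
  list(x = x, y = y, arc = s, attr = a, length = L)
}

.polylineLength <- function(points)
  sum(sqrt(rowSums(diff(points)^2)))

## point at arc position s along polyline
.pointAtArc <- function(points, s) {
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  s <- min(max(s, 0), arc[length(arc)])
  c(approx(arc, points[, 1], xout = s)$y, approx(arc, points[, 2], xout = s)$y)
}

## all intersections between two polylines; returns data.frame with the
## intersection point, the arc position on polyline P, and the crossing
## angle (degrees, in [0, 90])
.segIntersections <- function(P, Q) {
  out <- data.frame(x = numeric(), y = numeric(), arcP = numeric(),
                    angleDeg = numeric())
  arcP <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  for (i in seq_len(nrow(P) - 1L)) {
    p1 <- P[i, ]; p2 <- P[i + 1L, ]; d1 <- p2 - p1
    for (j in seq_len(nrow(Q) - 1L)) {
      q1 <- Q[j, ]; q2 <- Q[j + 1L, ]; d2 <- q2 - q1
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < 1e-12) next
      t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
      u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
      if (t >= 0 && t <= 1 && u >= 0 && u <= 1) {
        pt <- p1 + t * d1
        cosang <- abs(sum(d1 * d2)) /
          (sqrt(sum(d1^2)) * sqrt(sum(d2^2)))
        out <- rbind(out, data.frame(
          x = pt[1], y = pt[2],
          arcP = arcP[i] + t * sqrt(sum(d1^2)),
          angleDeg = acos(pmin(cosang, 1)) * 180 / pi))
      }
    }
  }
  out
}

## minimum distance between two polylines (coarse resample)
.polyDistMin <- function(P, Q, ds = 0.15) {
  rp <- .resamplePolyline(P, ds); rq <- .resamplePolyline(Q, ds)
  min(.crossdistMin(cbind(rp$x, rp$y), cbind(rq$x, rq$y)))
}

## random curvilinear filament: persistent random walk steered back into the
## field near the margin
.randomFilament <- function(lengthUm, fov, margin = 1, step = 0.35,
                            jitterSd = 0.25) {
  n <- max(3L, ceiling(lengthUm / step) + 1L)
  pts <- matrix(0, n, 2)
  pts[1, ] <- c(runif(1, margin, fov[2] - margin),
                runif(1, margin, fov[1] - margin))
  th <- runif(1, 0, 2 * pi)
  for (i in 2:n) {
    th <- th + rnorm(1, 0, jitterSd)
    cand <- pts[i - 1, ] + step * c(cos(th), sin(th))
    k <- 0
    while ((cand[1] < margin || cand[1] > fov[2] - margin ||
            cand[2] < margin || cand[2] > fov[1] - margin) && k < 20) {
      ctr <- c(fov[2], fov[1]) / 2
      th <- atan2(ctr[2] - pts[i - 1, 2], ctr[1] - pts[i - 1, 1]) +
        rnorm(1, 0, 0.3)
      cand <- pts[i - 1, ] + step * c(cos(th), sin(th))
      k <- k + 1
    }
    pts[i, ] <- cand
  }
  pts
}

## ER tubule spanning the field with a sinusoidal wiggle
.randomTubule <- function(fov, step = 0.4) {
  th <- runif(1, 0, pi)
  ctr <- c(runif(1, 0.15 * fov[2], 0.85 * fov[2]),
           runif(1, 0.15 * fov[1], 0.85 * fov[1]))
  dvec <- c(cos(th), sin(th)); nvec <- c(-sin(th), cos(th))
  half <- sqrt(sum(fov^2))
  s <- seq(-half, half, by = step)
  amp <- runif(1, 0.1, 0.4); freq <- runif(1, 0.2, 0.6)
  phase <- runif(1, 0, 2 * pi)
  pts <- cbind(ctr[1] + s * dvec[1] + amp * sin(freq * s + phase) * nvec[1],
               ctr[2] + s * dvec[2] + amp * sin(freq * s + phase) * nvec[2])
  keep <- pts[, 1] >= 0.2 & pts[, 1] <= fov[2] - 0.2 &
          pts[, 2] >= 0.2 & pts[, 2] <= fov[1] - 0.2
  if (!any(keep)) return(NULL)
  ## largest contiguous run inside the field
  r <- rle(keep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  pts[starts[best]:ends[best], , drop = FALSE]
}

## ---- scene construction -----------------------------------------------------

#' Build a synthetic ground-truth scene
#'
#' Places non-overlapping curvilinear mitochondrial filaments and ER tubules
#' in the field, marks ER crossings (with constrictions at the programmed
#' probability), lays down persistent and transient machinery puncta, and
#' schedules fusion/fission events as homogeneous Poisson processes with
#' intensity rate x nMito. The same parameters and seed always produce the
#' identical scene.
#'
#' When \code{photoconvert = TRUE} the filament nearest the field centre is
#' designated the conversion seed (label state converted from frame 1) and
#' every scheduled fusion involves the converted lineage, since those are the
#' only events scorable by fluorescence mixing; fission events partition the
#' label to both daughters.
#'
#' @param params parameter list from [sceneParams()].
#' @param seed integer seed.
#' @return a [SceneGraph].
#' @export
buildScene <- function(params = sceneParams(), seed = 1L) {
  .withSeed(seed, function() .buildSceneImpl(params, seed))
}

.buildSceneImpl <- function(p, seed) {
  fov <- p$fovUm
  nFrames <- as.integer(round(p$durationS / p$frameIntervalS))
  ## --- filaments, rejection-sampled for mutual clearance
  fil <- list()
  occ <- matrix(numeric(0), 0, 2)     # coarse occupancy samples
  for (i in seq_len(p$nMito)) {
    placed <- FALSE
    for (try in 1:80) {
      L <- runif(1, p$mitoLengthUm[1], p$mitoLengthUm[2])
      pts <- .randomFilament(L, fov)
      rs <- .resamplePolyline(pts, 0.25)
      cand <- cbind(rs$x, rs$y)
      if (nrow(occ) > 0) {
        dmin <- min(.crossdistMin(cand, occ))
        if (dmin < 1.5) next
      }
      ## self-clearance: filament should not fold onto itself
      fil[[i]] <- list(points = pts, radiusUm = runif(1, p$mitoRadiusUm[1],
                                                      p$mitoRadiusUm[2]),
                       constriction = rep(1, nrow(pts)),
                       tStart = 1L, tEnd = nFrames, convertedFrom = Inf,
                       parent = NA_integer_,
                       offsets = matrix(0, nFrames, 2))
      occ <- rbind(occ, cand)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible geometry: cannot place ", p$nMito,
           " filaments without overlap")
  }
  ## --- ER tubules. Scenes are kept unambiguous: a tubule either crosses a
  ## filament cleanly (angle >= 30 degrees) or stays >= 0.4 um clear of it;
  ## near-tangency passes that a detector (or an annotator) would read as a
  ## crossing are rejected, and crossings keep >= 0.6 um apart.
  tub <- list()
  tries <- 0L
  heldCrossings <- matrix(numeric(0), 0, 2)
  while (length(tub) < p$nErTubules && tries < 400L) {
    tries <- tries + 1L
    tq <- .randomTubule(fov)
    if (is.null(tq) || .polylineLength(tq) < 3) next
    ok <- TRUE
    newX <- matrix(numeric(0), 0, 2)
    for (i in seq_along(fil)) {
      ints <- .segIntersections(fil[[i]]$points, tq)
      if (nrow(ints) == 0) {
        if (.polyDistMin(fil[[i]]$points, tq) < 0.4) { ok <- FALSE; break }
      } else {
        if (any(ints$angleDeg < 30)) { ok <- FALSE; break }
        Lf <- .polylineLength(fil[[i]]$points)
        if (any(ints$arcP < 1.0 | ints$arcP > Lf - 1.0)) { ok <- FALSE; break }
        newX <- rbind(newX, cbind(ints$x, ints$y))
      }
    }
    if (ok && nrow(newX) > 0 && nrow(heldCrossings) > 0 &&
        min(.crossdistMin(newX, heldCrossings)) < 0.6) ok <- FALSE
    if (ok && nrow(newX) > 1 &&
        min(dist(newX)) < 0.6) ok <- FALSE
    if (!ok) next
    tub[[length(tub) + 1L]] <- tq
    heldCrossings <- rbind(heldCrossings, newX)
  }
  if (length(tub) < p$nErTubules && p$nErTubules > 0)
    warning("placed ", length(tub), " of ", p$nErTubules,
            " ER tubules before exhausting retries")
  ## --- ER crossings on each filament; programmed constrictions
  crossings <- data.frame(filament = integer(), arc = numeric(),
                          x = numeric(), y = numeric(),
                          constricted = logical(), minFactor = numeric())
  for (i in seq_along(fil)) {
    for (tq in tub) {
      ints <- .segIntersections(fil[[i]]$points, tq)
      for (k in seq_len(nrow(ints))) {
        crossings <- rbind(crossings, data.frame(
          filament = i, arc = ints$arcP[k], x = ints$x[k], y = ints$y[k],
          constricted = FALSE, minFactor = 1))
      }
    }
  }
  ## merge crossings closer than 0.5 um along the same filament (a detector
  ## sees one overlap run) and keep clear of the very tips
  if (nrow(crossings) > 0) {
    keep <- logical(nrow(crossings))
    for (i in unique(crossings$filament)) {
      idx <- which(crossings$filament == i)
      idx <- idx[order(crossings$arc[idx])]
      L <- .polylineLength(fil[[i]]$points)
      lastArc <- -Inf
      for (j in idx) {
        a <- crossings$arc[j]
        if (a > 1.0 && a < L - 1.0 && a - lastArc >= 0.5) {
          keep[j] <- TRUE; lastArc <- a
        }
      }
    }
    crossings <- crossings[keep, , drop = FALSE]
    rownames(crossings) <- NULL
  }
  ## constrictions: Gaussian multiplicative dip in radius centred at the
  ## crossing (sigma 0.35 um), minimum factor drawn from the programmed range
  if (nrow(crossings) > 0) {
    con <- runif(nrow(crossings)) < p$crossingConstrictionProb
    crossings$constricted <- con
    for (j in which(con)) {
      i <- crossings$filament[j]
      f <- runif(1, p$constrictionMinFactor[1], p$constrictionMinFactor[2])
      crossings$minFactor[j] <- f
      seg <- sqrt(rowSums(diff(fil[[i]]$points)^2))
      varc <- c(0, cumsum(seg))
      dip <- 1 - (1 - f) * exp(-(varc - crossings$arc[j])^2 / (2 * 0.35^2))
      fil[[i]]$constriction <- pmin(fil[[i]]$constriction, dip)
    }
  }
  ## --- puncta
  puncta <- data.frame(role = character(), filament = integer(),
                       arc = numeric(), x = numeric(), y = numeric(),
                       from = integer(), to = integer())
  addPunctum <- function(role, filament, arc, from = 1L, to = nFrames) {
    pt <- .pointAtArc(fil[[filament]]$points, arc)
    puncta[nrow(puncta) + 1L, ] <<- list(role, filament, arc, pt[1], pt[2],
                                         as.integer(from), as.integer(to))
  }
  ## same-channel puncta keep >= 0.6 um apart on a filament: machinery
  ## puncta are discrete structures, and closer pairs would not be
  ## resolvable as two spots at this diffraction limit anyway
  drawArc <- function(filament, role, L) {
    have <- puncta$arc[puncta$filament == filament & puncta$role == role]
    for (try in 1:40) {
      a <- runif(1, 0.2, L - 0.2)
      if (length(have) == 0 || min(abs(have - a)) >= 0.6) return(a)
    }
    NA_real_
  }
  for (i in seq_along(fil)) {
    L <- .polylineLength(fil[[i]]$points)
    for (k in seq_len(rpois(1, L * p$mfn1PerUm))) {
      a <- drawArc(i, "mfn1", L)
      if (!is.na(a)) addPunctum("mfn1", i, a)
    }
    for (k in seq_len(rpois(1, L * p$nodePerUm))) {
      a <- drawArc(i, "mfn1", L)
      if (!is.na(a)) { addPunctum("drp1", i, a); addPunctum("mfn1", i, a) }
    }
    if (p$transientPerUm > 0) {
      for (role in c("drp1", "mfn1"))
        for (k in seq_len(rpois(1, L * p$transientPerUm))) {
          f0 <- sample.int(nFrames - 1L, 1L)
          a <- drawArc(i, role, L)
          if (!is.na(a)) addPunctum(role, i, a, f0, f0 + 1L)
        }
    }
  }
  if (p$drp1AtCrossingProb > 0 && nrow(crossings) > 0) {
    for (j in seq_len(nrow(crossings)))
      if (runif(1) < p$drp1AtCrossingProb)
        addPunctum("drp1", crossings$filament[j], crossings$arc[j])
  }
  scene <- new("SceneGraph", filaments = fil, tubules = tub, puncta = puncta,
               events = .emptyEvents(), fovUm = fov, durationS = p$durationS,
               nFrames = nFrames, params = c(p, list(crossings = crossings)),
               seed = as.integer(seed))
  ## --- event schedule
  if (p$fusionRatePerMitoMin > 0 || p$fissionRatePerMitoMin > 0)
    scene <- .scheduleEvents(scene)
  scene
}

## min distance from each row of A to the point cloud B (coarse, vectorized)
.crossdistMin <- function(A, B) {
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

.emptyEvents <- function() {
  data.frame(frame = integer(), timeS = numeric(), kind = character(),
             class = character(), p1 = integer(), p2 = integer(),
             c1 = integer(), c2 = integer(), xUm = numeric(),
             yUm = numeric(), realized = logical())
}

## ---- event scheduling -------------------------------------------------------

## Schedules Poisson fusion/fission event times and realizes them as scene
## geometry: fusion donors glide tip-first onto the acceptor lineage and the
## groups merge; fissions split a filament, one daughter drifting away.
.scheduleEvents <- function(scene) {
  p <- scene@params
  nF <- scene@nFrames
  durMin <- scene@durationS / 60
  interval <- p$frameIntervalS
  fil <- scene@filaments
  nObj <- length(fil)
  group <- seq_len(nObj)          # group id per filament
  busyUntil <- rep(0L, nObj * 4L) # indexed by group id (generous)
  joints <- data.frame(x = numeric(), y = numeric(), donor = integer(),
                       frame = integer())
  glideStep <- 0.3                # um per frame during donor approach
  driftStep <- 0.25               # um per frame post-fission
  events <- .emptyEvents()
  seedFil <- NA_integer_
  if (isTRUE(p$photoconvert)) {
    ## seed = the longest filament: the experimenter picks a well-resolved
    ## mitochondrion, and a long acceptor keeps interior (tip-to-middle)
    ## contact sites available
    lens <- vapply(fil, function(f) .polylineLength(f$points), numeric(1))
    seedFil <- which.max(lens)
    fil[[seedFil]]$convertedFrom <- 1L
  }
  nFus <- rpois(1, p$fusionRatePerMitoMin * p$nMito * durMin)
  nFis <- rpois(1, p$fissionRatePerMitoMin * p$nMito * durMin)
  sched <- data.frame(
    timeS = c(runif(nFus, 0, scene@durationS), runif(nFis, 0, scene@durationS)),
    kind = rep(c("fusion", "fission"), c(nFus, nFis)))
  if (nFus > 0) {
    cls <- if (p$classMode == "exact") {
      k <- round(p$tipToMiddleFraction * nFus)
      sample(rep(c("tip_to_middle", "tip_to_tip"), c(k, nFus - k)))
    } else ifelse(runif(nFus) < p$tipToMiddleFraction,
                  "tip_to_middle", "tip_to_tip")
  } else cls <- character(0)
  sched$class <- c(cls, rep("none", nFis))
  sched <- sched[order(sched$timeS), , drop = FALSE]

  for (e in seq_len(nrow(sched))) {
    kind <- sched$kind[e]
    frame <- max(4L, min(nF - 5L, 1L + floor(sched$timeS[e] / interval)))
    realized <- FALSE
    rec <- list(frame = frame, timeS = (frame - 1) * interval, kind = kind,
                class = sched$class[e], p1 = NA_integer_, p2 = NA_integer_,
                c1 = NA_integer_, c2 = NA_integer_, xUm = NA_real_,
                yUm = NA_real_, realized = FALSE)
    if (kind == "fusion") {
      ## the drawn time is the event's propensity; if the encounter is
      ## infeasible right then (no free partner, no clear pose), retry a
      ## few frames later rather than losing the event
      res <- NULL
      fr <- frame
      for (try in 1:6) {
        for (lv in 0:2) {
          res <- .realizeFusion(fil, group, busyUntil, joints, seedFil,
                                sched$class[e], fr, glideStep, p,
                                scene@fovUm, relax = lv)
          if (!is.null(res)) break
        }
        if (!is.null(res) || fr + 4L > nF - 5L) break
        fr <- fr + 4L
      }
      if (!is.null(res)) {
        fil <- res$fil; group <- res$group; busyUntil <- res$busyUntil
        joints <- res$joints
        rec$p1 <- res$donor; rec$p2 <- res$acceptor
        rec$xUm <- res$contact[1]; rec$yUm <- res$contact[2]
        rec$frame <- res$frame; rec$timeS <- (res$frame - 1) * interval
        rec$realized <- TRUE
      }
    } else {
      res <- .realizeFission(fil, group, busyUntil, joints, frame,
                             driftStep, scene@fovUm, seedFil)
      if (is.null(res))
        res <- .realizeFission(fil, group, busyUntil, joints, frame,
                               driftStep, scene@fovUm, seedFil,
                               relax = TRUE)
      if (!is.null(res)) {
        fil <- res$fil; group <- res$group; busyUntil <- res$busyUntil
        joints <- res$joints
        rec$p1 <- res$parent; rec$c1 <- res$d1; rec$c2 <- res$d2
        rec$xUm <- res$at[1]; rec$yUm <- res$at[2]
        rec$realized <- TRUE
      }
    }
    events[nrow(events) + 1L, ] <- rec
  }
  scene@filaments <- fil
  scene@events <- events
  scene@params$seedFilament <- seedFil
  scene
}

## choose and realize one fusion; returns updated state or NULL if infeasible
.realizeFusion <- function(fil, group, busyUntil, joints, seedFil,
                           class, frame, glideStep, p, fov,
                           relax = 0L) {
  clearUm <- c(0.85, 0.75, 0.7)[relax + 1L]
  contactSepUm <- c(0.45, 0.35, 0.3)[relax + 1L]
  t2mMarginUm <- c(1.3, 1.1, 1.0)[relax + 1L]
  n <- length(fil)
  active <- which(vapply(seq_len(n), function(i)
    fil[[i]]$tStart <= frame & fil[[i]]$tEnd >= frame, logical(1)))
  if (length(active) < 2) return(NULL)
  grp <- group[active]
  if (isTRUE(p$photoconvert)) {
    accGroup <- group[seedFil]
    if (fil[[seedFil]]$tEnd < frame) {
      ## seed split away; lineage group = any converted filament's group
      conv <- active[vapply(active, function(i)
        is.finite(fil[[i]]$convertedFrom) &&
          fil[[i]]$convertedFrom <= frame, logical(1))]
      if (length(conv) == 0) return(NULL)
      accGroup <- group[conv[1]]
    }
  } else {
    ug <- unique(grp)
    accGroup <- if (length(ug) == 1) ug else sample(ug, 1)
  }
  ## shift the event a few frames (later preferred, earlier as fallback)
  ## if the lineage is mid-event at the drawn time
  nFr <- nrow(fil[[1]]$offsets)
  if (busyUntil[accGroup] >= frame) {
    cand <- c(frame + 1:8, frame - 1:6)
    cand <- cand[cand >= 4L & cand <= nFr - 3L]
    cand <- cand[busyUntil[accGroup] < cand]
    if (length(cand) == 0) return(NULL)
    frame <- cand[1]
    ## membership may differ at the shifted frame
    active <- which(vapply(seq_len(n), function(i)
      fil[[i]]$tStart <= frame & fil[[i]]$tEnd >= frame, logical(1)))
    if (length(active) < 2) return(NULL)
  }
  accMembers <- active[group[active] == accGroup]
  if (length(accMembers) == 0) return(NULL)
  ## donor: a single-filament group, not busy, not the acceptor group
  donFilter <- function(cand, fr)
    cand[vapply(cand, function(i) {
      g <- group[i]
      sum(group[active] == g) == 1L && busyUntil[g] < fr &&
        nrow(fil[[i]]$points) >= 4
    }, logical(1))]
  donCand0 <- active[group[active] != accGroup]
  donCand <- donFilter(donCand0, frame)
  ## a busy donor may free up shortly: delay the event rather than drop it
  while (length(donCand) == 0 && frame < nFr - 5L) {
    frame <- frame + 2L
    donCand <- donFilter(donCand0, frame)
  }
  if (length(donCand) == 0) return(NULL)
  ## contact point on the acceptor: for tip-to-middle pick a member long
  ## enough to hold an interior contact; retry the arc draw a few times to
  ## stay clear of previously used contact sites
  prefDir <- NULL
  contactFree <- function(pt)
    nrow(joints) == 0 ||
      min(.crossdistMin(rbind(pt), as.matrix(joints[, c("x", "y")]))) >=
        contactSepUm
  contact <- NULL
  if (class == "tip_to_tip") {
    ## any free tip across the acceptor group
    tips <- do.call(rbind, lapply(accMembers, function(i) {
      pts <- sweep(fil[[i]]$points, 2, fil[[i]]$offsets[frame, ], "+")
      rbind(pts[1, ], pts[nrow(pts), ])
    }))
    free <- which(vapply(seq_len(nrow(tips)), function(k)
      contactFree(tips[k, ]), logical(1)))
    if (length(free) == 0) return(NULL)
    pick <- if (length(free) == 1) free else sample(free, 1)
    contact <- tips[pick, ]
    accFil <- accMembers[ceiling(pick / 2)]
    ## tips fuse end-to-end: the donor approaches along the acceptor's
    ## axis so the joint continues the tube rather than forming an elbow
    aPts <- sweep(fil[[accFil]]$points, 2, fil[[accFil]]$offsets[frame, ],
                  "+")
    inward <- if (pick %% 2 == 1L) aPts[min(3L, nrow(aPts)), ] - aPts[1, ]
              else aPts[max(1L, nrow(aPts) - 2L), ] - aPts[nrow(aPts), ]
    prefDir <- -inward / max(sqrt(sum(inward^2)), 1e-9)
  } else {
    ## interior contact on a member long enough to hold one
    Ls <- vapply(accMembers, function(i)
      .polylineLength(fil[[i]]$points), numeric(1))
    accMembers <- accMembers[Ls >= 2 * t2mMarginUm + 0.2]
    if (length(accMembers) == 0) return(NULL)
    for (try in 1:8) {
      accFil <- if (length(accMembers) == 1) accMembers
                else sample(accMembers, 1)
      accPts <- sweep(fil[[accFil]]$points, 2,
                      fil[[accFil]]$offsets[frame, ], "+")
      Lacc <- .polylineLength(accPts)
      arcC <- runif(1, t2mMarginUm, Lacc - t2mMarginUm)
      candC <- .pointAtArc(accPts, arcC)
      if (contactFree(candC)) {
        contact <- candC
        ## a tip fusing into the middle approaches side-on, perpendicular
        ## to the acceptor's local axis (the canonical branch geometry)
        aLo <- .pointAtArc(accPts, max(0, arcC - 0.4))
        aHi <- .pointAtArc(accPts, min(Lacc, arcC + 0.4))
        tang <- aHi - aLo
        tang <- tang / max(sqrt(sum(tang^2)), 1e-9)
        prefDir <- c(-tang[2], tang[1])
        break
      }
    }
    if (is.null(contact)) return(NULL)
  }
  ## nearest-tip donor keeps the approach glide short; the donor's path to
  ## the contact must stay clear of every uninvolved object so the approach
  ## does not create accidental contacts
  tipDist <- vapply(donCand, function(i) {
    pts <- sweep(fil[[i]]$points, 2, fil[[i]]$offsets[frame, ], "+")
    min(sqrt(sum((pts[1, ] - contact)^2)),
        sqrt(sum((pts[nrow(pts), ] - contact)^2)))
  }, numeric(1))
  donCand <- donCand[order(tipDist)]
  nF <- nrow(fil[[1]]$offsets)
  ## Donor transport is not modelled continuously (motility is out of
  ## scope): the donor relocates to a docking position just outside
  ## touching distance of the contact a few frames before the event, then
  ## approaches continuously over the last ~1 um so the merge is a clean
  ## frame-to-frame contact. The docking pose must be clear of every
  ## object and inside the field.
  dockLead <- 4L
  tryDock <- function(don) {
    fr <- max(frame, fil[[don]]$tStart + 3L + dockLead)
    if (fr > nF - 3L || busyUntil[accGroup] >= fr) return(NULL)
    ## clearance is judged at the frame the donor actually appears at its
    ## dock, with every previously scheduled motion applied
    tDock <- max(1L, fr - dockLead)
    allPts <- do.call(rbind, lapply(seq_along(fil), function(j) {
      f2 <- fil[[j]]
      if (j == don || f2$tStart > tDock || f2$tEnd < tDock) return(NULL)
      rs <- .resamplePolyline(f2$points, 0.4)
      sweep(cbind(rs$x, rs$y), 2, f2$offsets[tDock, ], "+")
    }))
    if (is.null(allPts)) allPts <- matrix(numeric(0), 0, 2)
    pts <- fil[[don]]$points
    dirs <- t(vapply(seq(0, 2 * pi, length.out = 25)[-25],
                     function(a) c(cos(a), sin(a)), numeric(2)))
    if (!is.null(prefDir)) {
      ## try approach directions closest to the preferred one first (for
      ## an interior contact both sides of the acceptor are equivalent)
      ali <- as.numeric(dirs %*% prefDir)
      score <- if (class == "tip_to_middle") -abs(ali) else -ali
      dirs <- dirs[order(score), , drop = FALSE]
    }
    best <- NULL
    minClear <- c(0.8, 0.55, 0.5)[relax + 1L]  # minimum acceptable clearance
    for (dockGapUm in c(1.1, 1.5)) {
      for (k in seq_len(nrow(dirs))) {
        dir <- dirs[k, ]
        dockTip <- contact + dir * dockGapUm
        for (tipEnd in c(1L, nrow(pts))) {
          ## the docked leading segment (about 1 um of it, the zone that
          ## shapes the joint) must point into the contact along the
          ## approach so the joint geometry matches the programmed class
          Ld <- .polylineLength(pts)
          gate <- c(0.8, 0.65, 0.2)[relax + 1L]
          alignOK <- all(vapply(c(1.0, 1.8), function(w) {
            backPt <- if (tipEnd == 1L) .pointAtArc(pts, min(w, Ld))
                      else .pointAtArc(pts, max(0, Ld - w))
            outT <- pts[tipEnd, ] - backPt
            outT <- outT / max(sqrt(sum(outT^2)), 1e-9)
            sum(outT * (-dir)) >= gate
          }, logical(1)))
          if (!alignOK) next
          disp <- dockTip - pts[tipEnd, ]
          body <- sweep(pts, 2, disp, "+")
          if (any(body[, 1] < 0.3 | body[, 1] > fov[2] - 0.3 |
                  body[, 2] < 0.3 | body[, 2] > fov[1] - 0.3)) next
          rs <- .resamplePolyline(body, 0.4)
          bodyS <- cbind(rs$x, rs$y)
          clear <- if (nrow(allPts) == 0) Inf
                   else min(.crossdistMin(bodyS, allPts))
          if (clear < minClear) next
          ## the fully docked pose must also be clear: away from the
          ## contact site, the donor body may not brush any object (a
          ## secondary touch would fake a second fusion site)
          finBody <- sweep(bodyS, 2, dir * (dockGapUm + 0.25), "-")
          dC <- sqrt((finBody[, 1] - contact[1])^2 +
                     (finBody[, 2] - contact[2])^2)
          finAway <- finBody[dC > 0.9, , drop = FALSE]
          dCo <- sqrt((allPts[, 1] - contact[1])^2 +
                      (allPts[, 2] - contact[2])^2)
          othAway <- allPts[dCo > 0.45, , drop = FALSE]
          if (nrow(finAway) > 0 && nrow(othAway) > 0 &&
              min(.crossdistMin(finAway, othAway)) < 0.6) next
          best <- list(disp = disp, dir = dir, frame = fr, gap = dockGapUm)
          break
        }
        if (!is.null(best)) break
      }
      if (!is.null(best)) break
    }
    best
  }
  donor <- NA_integer_; g <- NULL
  for (dc in donCand) {
    g <- tryDock(dc)
    if (!is.null(g)) { donor <- dc; break }
  }
  if (is.na(donor)) return(NULL)
  frame <- g$frame
  dockOff <- g$disp
  ## the docked tip sits dockGapUm from the contact; close the gap and
  ## overshoot slightly so the contact overlap is deep enough not to
  ## flicker under segmentation noise
  finalOff <- dockOff - g$dir * (g$gap + 0.25)
  for (t in seq_len(nF)) {
    if (t >= frame) {
      fil[[donor]]$offsets[t, ] <- finalOff
    } else if (t >= frame - dockLead) {
      a <- (t - (frame - dockLead)) / dockLead
      fil[[donor]]$offsets[t, ] <- dockOff + (finalOff - dockOff) * a
    }
  }
  ## merge groups; propagate converted label across the merged object
  oldg <- group[donor]
  group[group == oldg] <- accGroup
  convA <- any(vapply(c(accMembers), function(i)
    fil[[i]]$convertedFrom <= frame, logical(1)))
  convD <- fil[[donor]]$convertedFrom <= frame
  if (convA || convD) {
    for (i in which(group == accGroup))
      if (fil[[i]]$tEnd >= frame)
        fil[[i]]$convertedFrom <- min(fil[[i]]$convertedFrom, frame)
  }
  busyUntil[accGroup] <- frame
  joints[nrow(joints) + 1L, ] <- list(contact[1], contact[2], donor, frame)
  list(fil = fil, group = group, busyUntil = busyUntil, joints = joints,
       donor = donor, acceptor = accFil, contact = contact, frame = frame)
}

## would gliding filament `don` from its position at `frame` to `contact`
## sweep within 0.75 um of any object outside the donor and acceptor groups?
.glidePathClear <- function(fil, group, active, don, accGroup, contact,
                            frame, clearUm = 0.85) {
  f <- fil[[don]]
  pts <- sweep(f$points, 2, f$offsets[frame, ], "+")
  tips <- rbind(pts[1, ], pts[nrow(pts), ])
  tipIdx <- which.min(c(sqrt(sum((tips[1, ] - contact)^2)),
                        sqrt(sum((tips[2, ] - contact)^2))))
  disp <- contact - tips[tipIdx, ]
  others <- do.call(rbind, lapply(active, function(j) {
    if (j == don || group[j] == accGroup) return(NULL)
    f2 <- fil[[j]]
    rs <- .resamplePolyline(f2$points, 0.5)
    sweep(cbind(rs$x, rs$y), 2, f2$offsets[frame, ], "+")
  }))
  if (is.null(others)) return(TRUE)
  rs <- .resamplePolyline(pts, 0.5)
  body <- cbind(rs$x, rs$y)
  for (tf in seq(0.125, 1, by = 0.125)) {
    moved <- sweep(body, 2, disp * tf, "+")
    if (min(.crossdistMin(moved, others)) < clearUm) return(FALSE)
  }
  TRUE
}

## drift-direction choice for a moving body: prefer the candidate keeping
## the displaced body farthest from every other object and inside the field
.chooseDriftDir <- function(bodyPts, others, axis, driftStep, fov) {
  cand <- rbind(axis, t(vapply(seq(0, 2 * pi, length.out = 9)[-9],
                               function(a) c(cos(a), sin(a)), numeric(2))))
  score <- apply(cand, 1, function(v) {
    disp <- v * 10 * driftStep
    moved <- sweep(bodyPts, 2, disp, "+")
    inFov <- all(moved[, 1] > 0.3 & moved[, 1] < fov[2] - 0.3 &
                 moved[, 2] > 0.3 & moved[, 2] < fov[1] - 0.3)
    clear <- if (is.null(others) || nrow(others) == 0) Inf
             else min(.crossdistMin(moved, others))
    if (!inFov) clear - 100 else clear
  })
  cand[which.max(score), ]
}

## choose and realize one fission. Two modes: detachment of a previously
## fused partner at its fusion joint (preferred when a mature joint exists;
## division at former contact sites keeps the fused cluster bounded), or a
## body split of a free filament into two daughters.
.realizeFission <- function(fil, group, busyUntil, joints, frame, driftStep,
                            fov, seedFil = NA_integer_, relax = FALSE) {
  n <- length(fil)
  nFr <- nrow(fil[[1]]$offsets)
  ## --- detachment candidates: joints at least 5 frames old whose donor is
  ## still whole, attached and not mid-motion
  jAge <- frame - joints$frame
  jMinAge <- if (relax) 3 else 5
  jOK <- which(jAge >= jMinAge & vapply(seq_len(nrow(joints)), function(k) {
    d <- joints$donor[k]
    f <- fil[[d]]
    if (!(f$tEnd >= frame && busyUntil[group[d]] < frame &&
          all(f$offsets[max(1L, frame - 2L), ] == f$offsets[nFr, ])))
      return(FALSE)
    ## only leaf partners detach cleanly: nothing else may be glued onto
    ## this filament (its own joint is at one end)
    othersJ <- joints[-k, , drop = FALSE]
    if (nrow(othersJ) == 0) return(TRUE)
    rs <- .resamplePolyline(f$points, 0.5)
    pts <- sweep(cbind(rs$x, rs$y), 2, f$offsets[frame, ], "+")
    min(.crossdistMin(as.matrix(othersJ[, c("x", "y")]), pts)) >= 0.5
  }, logical(1)))
  if (length(jOK) > 0 && runif(1) < 0.7) {
    k <- if (length(jOK) == 1) jOK else sample(jOK, 1)
    don <- joints$donor[k]
    f <- fil[[don]]
    at <- c(joints$x[k], joints$y[k])
    pts <- sweep(f$points, 2, f$offsets[frame, ], "+")
    rs <- .resamplePolyline(pts, 0.5)
    body <- cbind(rs$x, rs$y)
    others <- do.call(rbind, lapply(seq_len(n), function(j) {
      f2 <- fil[[j]]
      if (j == don || f2$tStart > frame || f2$tEnd < frame) return(NULL)
      r2 <- .resamplePolyline(f2$points, 0.5)
      sweep(cbind(r2$x, r2$y), 2, f2$offsets[frame, ], "+")
    }))
    ## move tip-first away from the joint
    tips <- rbind(pts[1, ], pts[nrow(pts), ])
    far <- tips[which.max(c(sqrt(sum((tips[1, ] - at)^2)),
                            sqrt(sum((tips[2, ] - at)^2)))), ]
    axis <- (far - at) / max(sqrt(sum((far - at)^2)), 1e-6)
    dir <- .chooseDriftDir(body, others, axis, driftStep, fov)
    for (t in seq(frame, nFr)) {
      d <- min(t - frame + 1L, 10L) * driftStep
      fil[[don]]$offsets[t, ] <- fil[[don]]$offsets[t, ] + dir * d
    }
    oldg <- group[don]
    group[don] <- max(group) + 1L
    if (length(busyUntil) < max(group))
      busyUntil <- c(busyUntil, rep(0L, max(group) - length(busyUntil)))
    busyUntil[group[don]] <- frame + 2L
    busyUntil[oldg] <- frame + 2L
    joints <- joints[-k, , drop = FALSE]
    return(list(fil = fil, group = group, busyUntil = busyUntil,
                joints = joints, parent = don, d1 = don, d2 = NA_integer_,
                at = at))
  }
  ## --- body split of a free-standing filament. A cut inside a fused
  ## cluster is invisible to component tracking (both halves stay connected
  ## through the rest of the object), so only mask-isolated filaments split;
  ## a lone converted lineage additionally stays long enough to go on
  ## hosting interior fusion contacts.
  lineageGroup <- if (is.na(seedFil)) NA_integer_ else group[seedFil]
  cand <- which(vapply(seq_len(n), function(i) {
    f <- fil[[i]]
    minLen <- if (!is.na(lineageGroup) && group[i] == lineageGroup) {
      if (relax) 3.2 else 4.0
    } else 2.0
    f$tStart <= frame - 1L && f$tEnd >= frame &&
      busyUntil[group[i]] < frame &&
      sum(group == group[i] &
            vapply(fil, function(x) x$tEnd >= frame, logical(1))) == 1L &&
      .polylineLength(f$points) >= minLen &&
      all(f$offsets[frame, ] == f$offsets[nrow(f$offsets), ])
  }, logical(1)))
  if (length(cand) == 0) return(NULL)
  parent <- if (length(cand) == 1) cand else sample(cand, 1)
  f <- fil[[parent]]
  seg <- sqrt(rowSums(diff(f$points)^2))
  varc <- c(0, cumsum(seg))
  L <- varc[length(varc)]
  sCut <- runif(1, 0.35 * L, 0.65 * L)
  iCut <- findInterval(sCut, varc)
  cutPt <- .pointAtArc(f$points, sCut)
  at <- cutPt + f$offsets[frame, ]
  pts1 <- rbind(f$points[seq_len(iCut), , drop = FALSE], cutPt)
  pts2 <- rbind(cutPt, f$points[seq(iCut + 1L, nrow(f$points)), , drop = FALSE])
  if (nrow(pts1) < 3 || nrow(pts2) < 3) return(NULL)
  nF <- nrow(f$offsets)
  mkDaughter <- function(pts, vi) {
    list(points = pts, radiusUm = f$radiusUm,
         constriction = approx(varc, f$constriction,
                               xout = pmin(pmax(vi, 0), L))$y,
         tStart = frame, tEnd = nF,
         convertedFrom = if (f$convertedFrom <= frame) f$convertedFrom
                         else Inf,
         parent = parent, offsets = f$offsets)
  }
  vi1 <- c(varc[seq_len(iCut)], sCut)
  vi2 <- c(sCut, varc[seq(iCut + 1L, length(varc))])
  d1 <- mkDaughter(pts1, vi1)
  d2 <- mkDaughter(pts2, vi2)
  ## daughter 2 drifts away for 8 frames so a gap opens; the direction is
  ## chosen (from the local axis and 8 compass candidates) to stay clear of
  ## every other object, avoiding accidental contacts
  axis <- pts2[min(3L, nrow(pts2)), ] - pts2[1, ]
  axis <- axis / sqrt(sum(axis^2))
  cand <- rbind(axis, t(sapply(seq(0, 2 * pi, length.out = 9)[-9],
                               function(a) c(cos(a), sin(a)))))
  tEval <- min(frame + 10L, nF)
  others <- do.call(rbind, lapply(seq_along(fil), function(j) {
    f2 <- fil[[j]]
    if (j == parent || f2$tStart > tEval || f2$tEnd < tEval) return(NULL)
    rs <- .resamplePolyline(f2$points, 0.5)
    sweep(cbind(rs$x, rs$y), 2, f2$offsets[tEval, ], "+")
  }))
  ## the staying daughter counts as an obstacle too: the mover must not
  ## drift back over its sibling or the pair never separates
  rs1 <- .resamplePolyline(pts1, 0.5)
  others <- rbind(others,
                  sweep(cbind(rs1$x, rs1$y), 2, f$offsets[tEval, ], "+"))
  p2s <- local({
    rs <- .resamplePolyline(pts2, 0.5)
    sweep(cbind(rs$x, rs$y), 2, f$offsets[tEval, ], "+")
  })
  score <- apply(cand, 1, function(v) {
    disp <- v * 10 * driftStep
    moved <- sweep(p2s, 2, disp, "+")
    inFov <- all(moved[, 1] > 0.3 & moved[, 1] < fov[2] - 0.3 &
                 moved[, 2] > 0.3 & moved[, 2] < fov[1] - 0.3)
    clear <- if (is.null(others)) Inf else min(.crossdistMin(moved, others))
    if (!inFov) clear - 100 else clear
  })
  axis <- cand[which.max(score), ]
  for (t in seq(frame, nF)) {
    d <- min(t - frame + 1L, 10L) * driftStep
    d2$offsets[t, ] <- d2$offsets[t, ] + axis * d
  }
  fil[[parent]]$tEnd <- frame - 1L
  fil[[length(fil) + 1L]] <- d1
  fil[[length(fil) + 1L]] <- d2
  id1 <- length(fil) - 1L; id2 <- length(fil)
  group <- c(group, group[parent], max(group) + 1L)
  if (length(busyUntil) < max(group))
    busyUntil <- c(busyUntil, rep(0L, max(group) - length(busyUntil)))
  busyUntil[group[parent]] <- frame + 2L
  busyUntil[group[id2]] <- frame + 2L
  list(fil = fil, group = group, busyUntil = busyUntil, joints = joints,
       parent = parent, d1 = id1, d2 = id2, at = at)
}

## ---- photoconversion --------------------------------------------------------

#' Photoconvert the mitochondrion under a ROI
#'
#' Switches the label state of the filament with the largest overlap with the
#' stimulation ROI to converted from time \code{t0S} onward, and propagates
#' the converted label through the event schedule: fusion transfers the label
#' to the whole merged object (equilibration within one frame), fission
#' partitions it to both daughters.
#'
#' @param scene a [SceneGraph].
#' @param roi stimulation [ROI] (pixel origin interpreted with
#'   \code{calibration}).
#' @param t0S conversion time in seconds.
#' @param calibration [Calibration] mapping the ROI to micrometres.
#' @return the modified [SceneGraph].
#' @export
applyPhotoconversion <- function(scene, roi, t0S = 0,
                                 calibration = Calibration()) {
  stopifnot(is(scene, "SceneGraph"), is(roi, "ROI"))
  px <- calibration@pixelSize
  idx <- roiToPixels(roi, calibration)
  xr <- range((idx$cols - 0.5) * px) + c(-0.5, 0.5) * px
  yr <- range((idx$rows - 0.5) * px) + c(-0.5, 0.5) * px
  f0 <- max(1L, min(scene@nFrames,
                    1L + as.integer(floor(t0S / scene@params$frameIntervalS))))
  overlap <- vapply(seq_along(scene@filaments), function(i) {
    f <- scene@filaments[[i]]
    if (f$tStart > f0 || f$tEnd < f0) return(0L)
    rs <- .resamplePolyline(f$points, 0.1)
    x <- rs$x + f$offsets[f0, 1]; y <- rs$y + f$offsets[f0, 2]
    sum(x >= xr[1] & x <= xr[2] & y >= yr[1] & y <= yr[2])
  }, integer(1))
  if (all(overlap == 0L))
    stop("no filament intersects the photoconversion ROI at t0")
  seed <- which.max(overlap)
  ## reset all label states, then replay the event schedule
  for (i in seq_along(scene@filaments))
    scene@filaments[[i]]$convertedFrom <- Inf
  scene@filaments[[seed]]$convertedFrom <- f0
  scene@params$seedFilament <- seed
  ev <- scene@events
  ev <- ev[ev$realized, , drop = FALSE]
  ev <- ev[order(ev$frame), , drop = FALSE]
  ## group replay for label propagation
  group <- seq_along(scene@filaments)
  for (e in seq_len(nrow(ev))) {
    fr <- ev$frame[e]
    if (ev$kind[e] == "fission") {
      par <- ev$p1[e]; d1 <- ev$c1[e]; d2 <- ev$c2[e]
      if (is.na(d2)) {
        ## detachment at a fusion joint: the filament leaves its group
        group[d1] <- max(group) + 1L
        next
      }
      cf <- scene@filaments[[par]]$convertedFrom
      if (cf <= fr) {
        scene@filaments[[d1]]$convertedFrom <- cf
        scene@filaments[[d2]]$convertedFrom <- cf
      }
      group[d1] <- group[par]
      group[d2] <- max(group) + 1L
    } else {
      gA <- group[ev$p2[e]]; gD <- group[ev$p1[e]]
      members <- which(group %in% c(gA, gD))
      conv <- any(vapply(members, function(i)
        scene@filaments[[i]]$convertedFrom <= fr, logical(1)))
      group[group == gD] <- gA
      if (conv)
        for (i in members)
          if (scene@filaments[[i]]$tEnd >= fr)
            scene@filaments[[i]]$convertedFrom <-
              min(scene@filaments[[i]]$convertedFrom, fr)
    }
  }
  scene
}

## ---- rendering --------------------------------------------------------------

## accumulate Gaussian splats (kernel peak = amp) into an nr x nc image
.splat <- function(nr, nc, rows, cols, amps, sigmaPx) {
  n <- length(rows)
  if (n == 0) return(matrix(0, nr, nc))
  K <- max(2L, ceiling(3 * sigmaPx))
  offs <- seq(-K, K)
  K2 <- length(offs)^2
  gridR <- rep(offs, times = length(offs))
  gridC <- rep(offs, each = length(offs))
  r0 <- round(rows); c0 <- round(cols)
  Rm <- matrix(gridR, K2, n) + matrix(r0, K2, n, byrow = TRUE)
  Cm <- matrix(gridC, K2, n) + matrix(c0, K2, n, byrow = TRUE)
  dx <- Rm - matrix(rows, K2, n, byrow = TRUE)
  dy <- Cm - matrix(cols, K2, n, byrow = TRUE)
  w <- exp(-(dx^2 + dy^2) / (2 * sigmaPx^2)) *
    matrix(amps, K2, n, byrow = TRUE)
  valid <- Rm >= 1 & Rm <= nr & Cm >= 1 & Cm <= nc
  lin <- (Cm - 1L) * nr + Rm
  agg <- rowsum(w[valid], lin[valid])
  img <- numeric(nr * nc)
  img[as.integer(rownames(agg))] <- agg
  matrix(img, nr, nc)
}

## emitter-density image (peak-normalized units) for one channel at frame t;
## `cache` (an environment) memoizes splats of spatially static content so a
## movie only re-rasterizes what moves
.renderChannel <- function(scene, role, frame, optics, cal, zAtten = 1,
                           cache = new.env(parent = emptyenv())) {
  px <- cal@pixelSize
  nr <- round(scene@fovUm[1] / px); nc <- round(scene@fovUm[2] / px)
  img <- matrix(0, nr, nc)
  psf <- optics$psfSigmaUm
  toPx <- function(x, y) list(col = x / px + 0.5, row = y / px + 0.5)
  memo <- function(key, fn) {
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- fn()
    cache[[key]] <- v
    v
  }
  if (role %in% c("mito", "native", "converted")) {
    for (i in seq_along(scene@filaments)) {
      f <- scene@filaments[[i]]
      if (f$tStart > frame || f$tEnd < frame) next
      if (role == "converted" && !(f$convertedFrom <= frame)) next
      off <- f$offsets[frame, ]
      key <- sprintf("fil:%d:%.5f:%.5f", i, off[1], off[2])
      img <- img + memo(key, function() {
        rs <- .resamplePolyline(f$points, px, attr = f$constriction)
        sigmaPx <- sqrt(f$radiusUm^2 + psf^2) / px
        ## per-point amp so an unconstricted ridge peaks at ~1; a matrix
        ## marker scales with cross-sectional area => factor^2 dip
        amp <- rs$attr^2 * 1 / (sqrt(2 * pi) * sigmaPx)
        at <- toPx(rs$x + off[1], rs$y + off[2])
        .splat(nr, nc, at$row, at$col, amp, sigmaPx)
      })
    }
  } else if (role == "er") {
    img <- img + memo("er", function() {
      acc <- matrix(0, nr, nc)
      for (tq in scene@tubules) {
        rs <- .resamplePolyline(tq, px)
        sigmaPx <- sqrt(0.12^2 + psf^2) / px
        amp <- rep(0.9 / (sqrt(2 * pi) * sigmaPx), length(rs$x))
        at <- toPx(rs$x, rs$y)
        acc <- acc + .splat(nr, nc, at$row, at$col, amp, sigmaPx)
      }
      acc
    })
  } else {                       # punctum channels
    pu <- scene@puncta
    pu <- pu[pu$role == role & pu$from <= frame & pu$to >= frame, ,
             drop = FALSE]
    if (nrow(pu) > 0) {
      sigmaPx <- sqrt(0.13^2 + psf^2) / px
      xs <- numeric(0); ys <- numeric(0)
      for (k in seq_len(nrow(pu))) {
        if (!is.na(pu$filament[k])) {
          f <- scene@filaments[[pu$filament[k]]]
          if (f$tStart > frame || f$tEnd < frame) next
          pt <- .pointAtArc(f$points, pu$arc[k]) + f$offsets[frame, ]
        } else pt <- c(pu$x[k], pu$y[k])
        xs <- c(xs, pt[1]); ys <- c(ys, pt[2])
      }
      key <- sprintf("pu:%s:%s", role,
                     paste(sprintf("%.4f", c(xs, ys)), collapse = ","))
      img <- img + memo(key, function()
        .splat(nr, nc, toPx(xs, ys)$row, toPx(xs, ys)$col,
               rep(1.4, length(xs)), sigmaPx))
    }
  }
  img * zAtten
}

## counts image = background + photonScale * density (+ noise)
.exposeImage <- function(dens, optics, noise = TRUE) {
  img <- optics$background + optics$photonScale * dens
  if (noise && optics$poissonNoise)
    img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  if (noise && optics$readNoiseSd > 0)
    img <- img + rnorm(length(img), 0, optics$readNoiseSd)
  pmax(img, 0)
}

#' Render a scene into a multi-channel movie
#'
#' Rasterizes each channel's emitter density per frame (filament intensity
#' scales with the square of the local constriction factor, so a programmed
#' constriction renders as an intensity dip), convolves with the Gaussian
#' PSF, and applies the camera model (background, Poisson shot noise,
#' Gaussian read noise). Noise-free renders are deterministic.
#'
#' @param scene a [SceneGraph].
#' @param optics an [opticsModel()].
#' @param calibration a [Calibration].
#' @param seed integer seed for the noise realization.
#' @param channels channel roles to render; default: every role present in
#'   the scene.
#' @param noise logical; \code{FALSE} for a noise-free render.
#' @return an [ImageStack] with one channel per role, frames as in the scene.
#' @export
renderMovie <- function(scene, optics = opticsModel(),
                        calibration = Calibration(), seed = 1L,
                        channels = NULL, noise = TRUE) {
  stopifnot(is(scene, "SceneGraph"))
  if (is.null(channels)) channels <- .sceneRoles(scene)
  px <- calibration@pixelSize
  nr <- round(scene@fovUm[1] / px); nc <- round(scene@fovUm[2] / px)
  nF <- scene@nFrames
  out <- array(0, dim = c(nF, 1L, length(channels), nr, nc))
  cache <- new.env(parent = emptyenv())
  .withSeed(seed, function() {
    for (t in seq_len(nF)) for (ci in seq_along(channels)) {
      dens <- .renderChannel(scene, channels[ci], t, optics, calibration,
                             cache = cache)
      out[t, 1L, ci, , ] <<- .exposeImage(dens, optics, noise)
    }
  })
  cal <- Calibration(px, calibration@zStep, scene@params$frameIntervalS)
  ImageStack(out, channelRoles = channels, calibration = cal)
}

#' Render a single-frame z-stack of a scene
#'
#' Builds the 12-slice (default) z-stack geometry used for constriction
#' scoring: the scene lies in one focal plane and slices are attenuated by a
#' Gaussian axial detection profile, so the constriction dip is visible over
#' several z-planes near focus.
#'
#' @param scene a [SceneGraph].
#' @param optics an [opticsModel()].
#' @param calibration a [Calibration] (z-step taken from here).
#' @param seed seed for the noise realization.
#' @param frame scene frame to image.
#' @param nz number of z-slices.
#' @param channels roles to render.
#' @param noise logical.
#' @return an [ImageStack] with 1 frame, \code{nz} slices.
#' @export
renderZStack <- function(scene, optics = opticsModel(),
                         calibration = Calibration(), seed = 1L, frame = 1L,
                         nz = 12L, channels = c("mito", "er"),
                         noise = TRUE) {
  stopifnot(is(scene, "SceneGraph"))
  px <- calibration@pixelSize
  nr <- round(scene@fovUm[1] / px); nc <- round(scene@fovUm[2] / px)
  zf <- (nz + 1) / 2
  out <- array(0, dim = c(1L, nz, length(channels), nr, nc))
  .withSeed(seed, function() {
    for (ci in seq_along(channels)) {
      dens <- .renderChannel(scene, channels[ci], frame, optics, calibration)
      for (z in seq_len(nz)) {
        att <- exp(-((z - zf) * calibration@zStep)^2 /
                     (2 * optics$axialSigmaUm^2))
        out[1L, z, ci, , ] <<- .exposeImage(dens * att, optics, noise)
      }
    }
  })
  ImageStack(out, channelRoles = channels, calibration = calibration)
}

.sceneRoles <- function(scene) {
  p <- scene@params
  roles <- if (isTRUE(p$photoconvert)) c("native", "converted") else "mito"
  if (length(scene@tubules) > 0) roles <- c(roles, "er")
  ## punctum channels implied by the parameters are rendered even when the
  ## realized scene happens to hold no punctum (a blank channel is data)
  if (p$mfn1PerUm > 0 || p$nodePerUm > 0 || p$transientPerUm > 0)
    roles <- c(roles, "mfn1")
  if (p$drp1AtCrossingProb > 0 || p$nodePerUm > 0 || p$transientPerUm > 0)
    roles <- c(roles, "drp1")
  unique(c(roles, unique(scene@puncta$role)))
}

## ---- ground truth -----------------------------------------------------------

#' Export the ground truth of a scene
#'
#' Tabulates the generator's truth for every scored quantity: filaments
#' (lengths, label states), ER crossings (constriction flags and programmed
#' dip depths), puncta, the realized event list with classes, and true event
#' rates recomputed from the realized schedule as
#' count / (nMito x duration).
#'
#' @param scene a [SceneGraph].
#' @return list with data.frames \code{filaments}, \code{crossings},
#'   \code{puncta}, \code{events}, and \code{rates}.
#' @export
exportGroundTruth <- function(scene) {
  stopifnot(is(scene, "SceneGraph"))
  fil <- data.frame(
    id = seq_along(scene@filaments),
    lengthUm = vapply(scene@filaments, function(f)
      .polylineLength(f$points), numeric(1)),
    radiusUm = vapply(scene@filaments, `[[`, numeric(1), "radiusUm"),
    tStart = vapply(scene@filaments, `[[`, numeric(1), "tStart"),
    tEnd = vapply(scene@filaments, `[[`, numeric(1), "tEnd"),
    convertedFrom = vapply(scene@filaments, `[[`, numeric(1),
                           "convertedFrom"),
    parent = vapply(scene@filaments, function(f)
      as.integer(f$parent), integer(1)))
  cr <- scene@params$crossings
  if (is.null(cr)) cr <- data.frame()
  else if (nrow(cr) > 0) cr$dipDepth <- 1 - cr$minFactor^2
  ev <- scene@events[scene@events$realized, , drop = FALSE]
  durMin <- scene@durationS / 60
  nMito <- sum(fil$tStart == 1)
  rate <- function(sel) nrow(ev[sel, , drop = FALSE]) / (nMito * durMin)
  rates <- data.frame(
    kind = c("fusion", "fusion", "fusion", "fission"),
    class = c("total", "tip_to_middle", "tip_to_tip", "total"),
    rate = c(rate(ev$kind == "fusion"),
             rate(ev$kind == "fusion" & ev$class == "tip_to_middle"),
             rate(ev$kind == "fusion" & ev$class == "tip_to_tip"),
             rate(ev$kind == "fission")))
  list(filaments = fil, crossings = cr, puncta = scene@puncta, events = ev,
       rates = rates, nMito = nMito, durationMin = durMin)
}
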