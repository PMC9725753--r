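test_that("identical parameters and seed give identical scenes", {
  p <- sceneParams(mfn1PerUm = 0.3, drp1AtCrossingProb = 0.5)
  s1 <- buildScene(p, seed = 7)
  s2 <- buildScene(p, seed = 7)
  expect_identical(s1@filaments, s2@filaments)
  expect_identical(s1@puncta, s2@puncta)
  expect_identical(s1@params$crossings, s2@params$crossings)
  s3 <- buildScene(p, seed = 8)
  expect_false(identical(s1@filaments, s3@filaments))
})

test_that("filament count equals the requested number", {
  for (n in c(3, 5, 8))
    expect_length(buildScene(sceneParams(nMito = n), seed = 1)@filaments, n)
})

test_that("scheduled event counts follow the programmed Poisson law", {
  p <- sceneParams(nMito = 8, nErTubules = 0, durationS = 300,
                   fusionRatePerMitoMin = 0.25, photoconvert = TRUE,
                   fovUm = c(18, 18))
  counts <- vapply(1:150, function(s) {
    ev <- buildScene(p, seed = s)@events
    sum(ev$kind == "fusion")          # scheduled (realized or not)
  }, numeric(1))
  lambda <- 0.25 * 8 * 5
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  ## chi-square goodness of fit against the Poisson pmf, alpha = 0.01
  br <- c(-0.5, seq(4.5, 15.5), Inf)
  obs <- table(cut(counts, br))
  pr <- diff(ppois(c(-1, seq(4, 15), Inf), lambda))
  keep <- pr * length(counts) >= 1
  gof <- suppressWarnings(chisq.test(as.integer(obs[keep]),
                                     p = pr[keep] / sum(pr[keep])))
  expect_gt(gof$p.value, 0.01)
})

test_that("photoconversion converts the ROI's filament and follows events", {
  p <- sceneParams(nMito = 4, nErTubules = 0, fovUm = c(16, 16),
                   durationS = 300, fusionRatePerMitoMin = 0.15,
                   photoconvert = TRUE)
  sc <- buildScene(p, seed = 5)
  seed <- sc@params$seedFilament
  ## ROI over the designated filament reproduces the stored label states
  pt <- sc@filaments[[seed]]$points[2, ]
  roi <- ROI(c(max(1, round(pt[2] / 0.1) - 5), max(1, round(pt[1] / 0.1) - 5)),
             1.2)
  before <- vapply(sc@filaments, `[[`, numeric(1), "convertedFrom")
  sc2 <- applyPhotoconversion(sc, roi, t0S = 0)
  after <- vapply(sc2@filaments, `[[`, numeric(1), "convertedFrom")
  expect_identical(before, after)
  ## fusion partners must carry the label from the event frame onward
  ev <- sc2@events[sc2@events$realized & sc2@events$kind == "fusion", ]
  for (i in seq_len(nrow(ev)))
    expect_lte(after[ev$p1[i]], ev$frame[i])
  ## empty ROI errors
  expect_error(applyPhotoconversion(sc, ROI(c(1L, 1L), 0.4), 0),
               "no filament")
})

test_that("noise-free renders obey the forward model exactly", {
  empty <- new("SceneGraph", filaments = list(), tubules = list(),
               puncta = data.frame(role = character(), filament = integer(),
                                   arc = numeric(), x = numeric(),
                                   y = numeric(), from = integer(),
                                   to = integer()),
               events = MitoNodeQuant:::.emptyEvents(), fovUm = c(5, 5),
               durationS = 10, nFrames = 2L,
               params = list(frameIntervalS = 5, photoconvert = FALSE),
               seed = 1L)
  mv <- renderMovie(empty, opticsModel(background = 100), channels = "mito",
                    noise = FALSE)
  expect_true(all(mv@pixels == 100))
  ## single filament: the centerline carries the maximum
  sc <- buildScene(sceneParams(nMito = 1, nErTubules = 0, fovUm = c(8, 8),
                               durationS = 10), seed = 3)
  m2 <- renderMovie(sc, channels = "mito", noise = FALSE)
  plane <- getPlane(m2, "mito")
  peak <- which(plane == max(plane), arr.ind = TRUE)[1, ]
  ctl <- MitoNodeQuant:::.resamplePolyline(sc@filaments[[1]]$points, 0.05)
  d <- min(sqrt((ctl$x - (peak[2] - 0.5) * 0.1)^2 +
                (ctl$y - (peak[1] - 0.5) * 0.1)^2))
  expect_lt(d, 0.15)
  expect_gt(max(plane), 300)     # well above the background of 100
})

test_that("Poisson shot noise has variance equal to the mean per pixel", {
  sc <- buildScene(sceneParams(nMito = 1, nErTubules = 0, fovUm = c(4, 4),
                               durationS = 10), seed = 2)
  op <- opticsModel(readNoiseSd = 0)
  stacks <- vapply(1:400, function(k)
    getPlane(renderMovie(sc, op, seed = k, channels = "mito"), "mito"),
    matrix(0, 40, 40))
  mu <- apply(stacks, c(1, 2), mean)
  vv <- apply(stacks, c(1, 2), var)
  bright <- mu > 200
  expect_lt(abs(mean(vv[bright] / mu[bright]) - 1), 0.1)
})

test_that("programmed constrictions render as at least their nominal dip", {
  p <- sceneParams(nMito = 1, nErTubules = 2, crossingConstrictionProb = 1,
                   fovUm = c(10, 10), durationS = 10)
  found <- 0
  for (s in 1:12) {
    sc <- buildScene(p, seed = s)
    cr <- sc@params$crossings
    if (is.null(cr) || nrow(cr) == 0 || !any(cr$constricted)) next
    found <- found + 1
    ## analytic line integral of emitter density: per-arc amplitude is the
    ## squared constriction factor, so the programmed dip is 1 - f^2
    f <- sc@filaments[[1]]
    rs <- MitoNodeQuant:::.resamplePolyline(f$points, 0.05,
                                            attr = f$constriction)
    dens <- rs$attr^2
    progDip <- 1 - min(cr$minFactor[cr$constricted])^2
    expect_gte(1 - min(dens) / max(dens), progDip - 0.01)
    if (found >= 3) break
  }
  expect_gte(found, 1)
})

test_that("ground-truth export is consistent with the scene", {
  p <- sceneParams(nMito = 5, nErTubules = 0, fovUm = c(17, 17),
                   durationS = 300, fusionRatePerMitoMin = 0.2,
                   fissionRatePerMitoMin = 0.1, photoconvert = TRUE)
  sc <- buildScene(p, seed = 4)
  gt <- exportGroundTruth(sc)
  ev <- sc@events[sc@events$realized, ]
  expect_equal(nrow(gt$events), nrow(ev))
  durMin <- sc@durationS / 60
  expect_equal(gt$rates$rate[gt$rates$class == "total" &
                               gt$rates$kind == "fusion"],
               sum(ev$kind == "fusion") / (5 * durMin))
  ## class rates sum to the fusion total
  r <- gt$rates
  expect_equal(r$rate[r$class == "tip_to_middle"] +
                 r$rate[r$class == "tip_to_tip"],
               r$rate[r$kind == "fusion" & r$class == "total"])
  ## no events scheduled -> zero rates
  gt0 <- exportGroundTruth(buildScene(sceneParams(nMito = 3,
                                                  nErTubules = 0), seed = 1))
  expect_true(all(gt0$rates$rate == 0))
})
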