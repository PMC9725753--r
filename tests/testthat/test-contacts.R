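test_that("a perpendicular ER tubule yields one crossing at the intersection", {
  ## horizontal mitochondrion, vertical ER band
  skel <- skeletonizeMask(BinaryMask(barMask()))
  er <- matrix(FALSE, 60, 60)
  er[10:50, 29:31] <- TRUE
  cs <- detectCrossings(skel, BinaryMask(er))
  cr <- crossings(cs)
  expect_equal(nrow(cr), 1L)
  expect_true(cr$resolvable[1])
  expect_lt(abs(cr$col[1] - 30), 1.5)
  expect_lt(abs(cr$row[1] - 31), 1.5)
  ## empty ER mask: no crossings
  none <- detectCrossings(skel, BinaryMask(matrix(FALSE, 60, 60)))
  expect_equal(nrow(crossings(none)), 0L)
})

test_that("long parallel overlap runs are flagged unresolvable", {
  skel <- skeletonizeMask(BinaryMask(barMask()))
  er <- matrix(FALSE, 60, 60)
  er[28:34, 10:45] <- TRUE          # runs along the mitochondrion for 3.5 um
  cs <- detectCrossings(skel, BinaryMask(er), maxParallelRunUm = 1.0)
  cr <- crossings(cs)
  expect_gte(nrow(cr), 1L)
  expect_false(any(cr$resolvable))
})

test_that("line profiles sample one value per path pixel", {
  img <- matrix(7, 30, 30)
  path <- cbind(15, 5:25)
  prof <- extractLineProfile(img, path)
  expect_length(prof$intensity, nrow(path))
  expect_true(all(prof$intensity == 7))
  expect_equal(max(prof$arcUm), (nrow(path) - 1) * 0.1)
  expect_error(extractLineProfile(img, cbind(40, 1:5)), "outside")
})

test_that("the 40% dip rule calls exactly the qualifying minima", {
  p1 <- list(arcUm = c(0, 0.1, 0.2), intensity = c(100, 55, 100))
  calls <- callConstrictions(p1, smoothWindow = 1)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$dipFraction, 0.45)
  p2 <- list(arcUm = c(0, 0.1, 0.2), intensity = c(100, 70, 100))
  expect_equal(nrow(callConstrictions(p2, smoothWindow = 1)), 0L)
  expect_error(callConstrictions(list(arcUm = 0, intensity = c(1, 2))),
               "3 samples")
})

test_that("constriction calls equal a brute-force scan on random profiles", {
  set.seed(23)
  for (i in 1:200) {
    y <- randomSmoothProfile(50)
    arc <- (seq_along(y) - 1) * 0.1
    got <- callConstrictions(list(arcUm = arc, intensity = y),
                             smoothWindow = 1)
    want <- bruteConstrictions(y, arc)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$positionUm, want$positionUm)
      expect_equal(got$dipFraction, want$dipFraction)
    }
  }
})

test_that("constriction calling is invariant to intensity scaling", {
  set.seed(5)
  y <- randomSmoothProfile(60)
  arc <- (seq_along(y) - 1) * 0.1
  a <- callConstrictions(list(arcUm = arc, intensity = y))
  b <- callConstrictions(list(arcUm = arc, intensity = y * 37.5))
  expect_equal(a, b)
})

test_that("multi-slice calls require support in several z-planes", {
  base <- c(100, 100, 100, 40, 100, 100, 100)
  arc <- (0:6) * 0.1
  flat <- rep(100, 7)
  two <- rbind(base, base, flat)
  calls <- callConstrictions(list(arcUm = arc, intensity = two),
                             minZSupport = 2, smoothWindow = 1)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$zSupport, 2L)
  one <- rbind(base, flat, flat)
  expect_equal(nrow(callConstrictions(list(arcUm = arc, intensity = one),
                                      minZSupport = 2, smoothWindow = 1)), 0L)
})

test_that("crossing-constriction fraction follows its definition", {
  cr <- data.frame(row = 1, col = 1, xUm = c(1, 2, 3, 4), yUm = 0,
                   runUm = 0.2, resolvable = TRUE, edge = 1L,
                   arcUm = c(1, 2, 3, 4))
  cs <- new("CrossingSet", crossings = cr, calibration = Calibration())
  calls <- data.frame(edge = 1L, positionUm = c(1.1, 3.2),
                      dipFraction = 0.5, zSupport = 2L)
  expect_equal(fractionCrossingsConstricted(cs, calls), 0.5)
  expect_equal(fractionCrossingsConstricted(cs, calls[0, ]), 0)
  cs0 <- new("CrossingSet", crossings = cr[0, ], calibration = Calibration())
  expect_error(fractionCrossingsConstricted(cs0, calls), "resolvable")
})

test_that("overlap fraction satisfies the Mander's identities", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  expect_equal(overlapFraction(BinaryMask(a), BinaryMask(a)), 1.0)
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(overlapFraction(BinaryMask(a), BinaryMask(b)), 0.0)
  half <- matrix(FALSE, 10, 10); half[2:3, 2:5] <- TRUE   # half of a
  expect_equal(overlapFraction(BinaryMask(half), BinaryMask(a)), 0.5)
  expect_error(overlapFraction(BinaryMask(a),
                               BinaryMask(matrix(FALSE, 10, 10))), "empty")
  expect_error(overlapFraction(BinaryMask(a),
                               BinaryMask(matrix(TRUE, 5, 5))), "shape")
})

test_that("overlap fraction grows monotonically as mask A dilates", {
  set.seed(3)
  b <- matrix(runif(400) < 0.4, 20, 20)
  a <- matrix(FALSE, 20, 20); a[8:12, 8:12] <- TRUE
  prev <- overlapFraction(BinaryMask(a), BinaryMask(b))
  for (i in 1:4) {
    a <- MitoNodeQuant:::.maxfilt3(a * 1) > 0
    cur <- overlapFraction(BinaryMask(a), BinaryMask(b))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("rendered constriction dips are found near the programmed site", {
  p <- sceneParams(nMito = 1, nErTubules = 2, crossingConstrictionProb = 1,
                   constrictionMinFactor = c(0.4, 0.5), fovUm = c(10, 10),
                   durationS = 10)
  checked <- 0
  for (s in 1:15) {
    sc <- buildScene(p, seed = s)
    cr <- sc@params$crossings
    if (is.null(cr) || !any(cr$constricted)) next
    zs <- renderZStack(sc, seed = s, noise = FALSE)
    out <- scoreConstrictions(zs)
    calls <- out$calls
    expect_gte(nrow(calls), sum(cr$constricted))
    ## programmed sites carry a call nearby (adjacent dips can merge into
    ## one broad minimum between them, hence the 0.6 um allowance)
    hits <- vapply(which(cr$constricted), function(j)
      min(sqrt((calls$xUm - cr$x[j])^2 + (calls$yUm - cr$y[j])^2)),
      numeric(1))
    expect_gte(mean(hits <= 0.35), 0.7)
    expect_true(all(hits <= 0.65))
    checked <- checked + 1
    if (checked >= 3) break
  }
  expect_gte(checked, 1)
})
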