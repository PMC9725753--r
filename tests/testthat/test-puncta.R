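## render one Gaussian spot (peak-normalized amplitude) on a background
spotImage <- function(centers, amp = 500, bg = 100, sigmaPx = 2, n = 60) {
  img <- matrix(bg, n, n)
  for (k in seq_len(nrow(centers))) {
    for (r in 1:n) for (cl in 1:n) {
      d2 <- (r - centers[k, 1])^2 + (cl - centers[k, 2])^2
      img[r, cl] <- img[r, cl] + amp * exp(-d2 / (2 * sigmaPx^2))
    }
  }
  img
}

test_that("a single rendered spot yields one sub-pixel detection", {
  img <- spotImage(cbind(30.3, 25.6))
  det <- detectPunctaFrame(img)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$row - 30.3), 1)
  expect_lt(abs(det$col - 25.6), 1)
  ## blank image gives nothing
  expect_equal(nrow(detectPunctaFrame(matrix(100, 40, 40))), 0L)
})

test_that("two spots a micrometre apart are resolved as two", {
  img <- spotImage(rbind(c(25, 25), c(25, 35)))   # 10 px = 1 um apart
  det <- detectPunctaFrame(img)
  expect_equal(nrow(det), 2L)
})

test_that("persistence linking keeps full-length tracks and drops transients", {
  full <- data.frame(row = 20, col = 20, xUm = 1.95, yUm = 1.95,
                     sigmaUm = 0.15, intensity = 500, response = 10)
  trans <- data.frame(row = 5, col = 5, xUm = 0.45, yUm = 0.45,
                      sigmaUm = 0.15, intensity = 500, response = 10)
  frames <- lapply(1:24, function(t)
    if (t == 3) rbind(full, trans) else full)
  ps <- linkPersistentPuncta(frames)
  expect_equal(nrow(puncta(ps)), 1L)
  expect_equal(puncta(ps)$persistence, 1)
  ## a punctum present in 1 of 24 frames is rejected
  frames2 <- lapply(1:24, function(t) if (t == 3) trans else full[0, ])
  expect_equal(nrow(puncta(linkPersistentPuncta(frames2))), 0L)
  ## detection dropouts below the tolerance are forgiven
  frames3 <- lapply(1:24, function(t) if (t %in% c(7, 15)) full[0, ] else full)
  ps3 <- linkPersistentPuncta(frames3)
  expect_equal(nrow(puncta(ps3)), 1L)
  expect_equal(puncta(ps3)$persistence, 22 / 24)
})

test_that("raising the persistence requirement never adds puncta", {
  set.seed(9)
  frames <- lapply(1:24, function(t) {
    n <- rpois(1, 3)
    data.frame(row = runif(n, 5, 55), col = runif(n, 5, 55),
               xUm = 0, yUm = 0, sigmaUm = 0.15, intensity = 1,
               response = 1)
  })
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(mp)
    nrow(puncta(linkPersistentPuncta(frames, minPersistence = mp))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("puncta density divides assigned counts by skeleton length", {
  sk <- skeletonizeMask(BinaryMask(barMask()))     # ~4.9 um horizontal bar
  L <- totalLength(sk)
  on <- punctaAt(x = c(1.0, 2.0, 4.0), y = rep(3.05, 3))
  expect_equal(punctaDensity(on, skeleton = sk), 3 / L)
  ## far-away puncta are not assigned
  off <- punctaAt(x = c(1.0, 2.0), y = c(3.05, 5.5))
  expect_equal(punctaDensity(off, skeleton = sk), 1 / L)
  ## plain arithmetic form
  expect_equal(punctaDensity(on, mitoLengthUm = 10), 0.3)
  expect_equal(punctaDensity(punctaAt(numeric(0), numeric(0)),
                             mitoLengthUm = 10), 0)
  expect_error(punctaDensity(on, mitoLengthUm = 0), "positive")
})

test_that("crossing occupancy fraction follows its definition", {
  cr <- data.frame(row = 1, col = 1, xUm = seq(1, 10), yUm = 1,
                   runUm = 0.2, resolvable = TRUE, edge = 1L, arcUm = 1)
  cs <- new("CrossingSet", crossings = cr, calibration = Calibration())
  pu <- punctaAt(x = c(1.05, 3.1, 6.9, 9.0), y = rep(1, 4))
  expect_equal(fractionCrossingsWithPuncta(cs, pu), 0.4)
  expect_equal(fractionCrossingsWithPuncta(
    cs, punctaAt(numeric(0), numeric(0))), 0)
})

test_that("node matching is one-to-one, nearest-first, and symmetric", {
  a <- punctaAt(x = c(1, 2, 3, 4, 5), y = rep(0, 5))
  b <- punctaAt(x = c(1, 2, 3, 4, 5) + 0.05, y = rep(0, 5))
  expect_equal(nodeDensity(a, b, mitoLengthUm = 10), 0.5)
  ## far-separated sets give zero
  c2 <- punctaAt(x = c(20, 30), y = rep(0, 2))
  expect_equal(nodeDensity(a, c2, mitoLengthUm = 10), 0)
  ## one B punctum cannot validate two A puncta
  a2 <- punctaAt(x = c(1.0, 1.2), y = c(0, 0))
  b2 <- punctaAt(x = 1.1, y = 0)
  expect_equal(countNodes(a2, b2), 1L)
  ## symmetry under one-to-one matching
  set.seed(2)
  ra <- punctaAt(runif(8, 0, 5), runif(8, 0, 5))
  rb <- punctaAt(runif(6, 0, 5), runif(6, 0, 5))
  expect_equal(countNodes(ra, rb), countNodes(rb, ra))
})

test_that("densities are invariant to rigid scene motion", {
  sk <- skeletonizeMask(BinaryMask(barMask()))
  pu <- punctaAt(x = c(1.0, 2.5, 4.0), y = rep(3.05, 3))
  d0 <- punctaDensity(pu, skeleton = sk)
  ## translate everything by the same offset
  m2 <- matrix(FALSE, 60, 60); m2[35:37, 8:57] <- TRUE
  sk2 <- skeletonizeMask(BinaryMask(m2))
  pu2 <- punctaAt(x = c(1.0, 2.5, 4.0) + 0.3, y = rep(3.55, 3))
  expect_equal(punctaDensity(pu2, skeleton = sk2), d0, tolerance = 0.05)
  ## 90-degree rotation of the scene
  m3 <- t(barMask())[, 60:1]
  sk3 <- skeletonizeMask(BinaryMask(m3))
  expect_equal(totalLength(sk3), totalLength(sk), tolerance = 0.1)
})
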