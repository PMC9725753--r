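test_that("Otsu separates a bimodal image and rejects a flat one", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  m <- otsuMask(img)
  expect_identical(m@pixels, img > 100)
  expect_error(otsuMask(matrix(7, 5, 5)), "contrast")
})

test_that("Otsu mask is invariant to affine intensity rescaling", {
  set.seed(41)
  img <- matrix(sample(c(rpois(150, 20), rpois(106, 200))), 16, 16)
  m1 <- otsuMask(img)
  m2 <- otsuMask(img * 3.7 + 55)
  expect_identical(m1@pixels, m2@pixels)
})

test_that("component labeling matches a flood-fill oracle on random masks", {
  set.seed(7)
  for (i in 1:12) {
    mask <- matrix(runif(144) < 0.35, 12, 12)
    for (conn in c(4, 8)) {
      lo <- labelComponents(BinaryMask(mask), conn)
      oracle <- floodLabel(mask, conn)
      expect_equal(max(lo@labels), max(oracle))
      ## same partition (labels may be permuted)
      if (max(oracle) > 0)
        expect_equal(length(unique(paste(lo@labels[mask], oracle[mask]))),
                     max(oracle))
      ## conservation: per-object areas sum to total foreground
      expect_equal(sum(objectSizes(lo)), sum(mask))
    }
  }
})

test_that("two disjoint squares label as two objects of nine pixels", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE; m[8:10, 8:10] <- TRUE
  lo <- labelComponents(BinaryMask(m))
  expect_identical(sort(objectSizes(lo)), c(9L, 9L))
  expect_equal(max(labelImage(lo)), 2L)
  expect_length(objectSizes(labelComponents(BinaryMask(matrix(FALSE, 5, 5)))),
                0L)
})

test_that("mean area per mitochondrion follows the ROI arithmetic", {
  m <- matrix(FALSE, 120, 120)
  m[10:19, 10:19] <- TRUE                       # 100 px = 1 um^2
  res <- meanAreaPerMitochondrion(BinaryMask(m))
  expect_equal(res$totalAreaUm2, 1.0)
  expect_equal(res$count, 1L)
  expect_equal(res$meanAreaUm2, 1.0)
  m[40:49, 10:39] <- TRUE                       # + 300 px object
  res2 <- meanAreaPerMitochondrion(BinaryMask(m))
  expect_equal(res2$meanAreaUm2, 2.0)           # (1.0 + 3.0) / 2
  expect_error(meanAreaPerMitochondrion(BinaryMask(matrix(FALSE, 60, 60)),
                                        ROI(c(1L, 1L), 5)), "no mitochondria")
})

test_that("skeleton of a bar is one edge of the bar's length", {
  sk <- skeletonizeMask(BinaryMask(barMask()))
  expect_equal(nrow(skeletonEdges(sk)), 1L)
  expect_lt(abs(totalLength(sk) - 4.9), 0.2)
  empty <- skeletonizeMask(BinaryMask(matrix(FALSE, 10, 10)))
  expect_equal(totalLength(empty), 0)
  expect_equal(nrow(skeletonNodes(empty)), 0L)
})

test_that("a Y-shaped mask gives one junction and three endpoints", {
  sk <- skeletonizeMask(BinaryMask(yMask()))
  types <- table(skeletonNodes(sk)$type)
  expect_equal(unname(types["junction"]), 1L)
  expect_equal(unname(types["endpoint"]), 3L)
  ## neighbour-count oracle on the thinned image: exactly one pixel with
  ## three or more skeleton neighbours
  skimg <- matrix(FALSE, 80, 80)
  for (p in sk@paths) skimg[p] <- TRUE
  cnt <- MitoNodeQuant:::.neighborCount(skimg)
  expect_gte(sum(skimg & cnt >= 3), 1L)
})

test_that("skeleton length is stable under 90-degree rotation", {
  m <- yMask()
  l0 <- totalLength(skeletonizeMask(BinaryMask(m)))
  l90 <- totalLength(skeletonizeMask(BinaryMask(t(m[nrow(m):1, ]))))
  expect_lt(abs(l90 - l0) / l0, 0.1)
})

test_that("segmentation of noisy rendered blobs matches the clean mask", {
  ## disks on background, Poisson noise at moderate signal level
  img0 <- matrix(50, 80, 80)
  for (ctr in list(c(20, 25), c(55, 50))) {
    for (r in 1:80) for (cl in 1:80)
      if ((r - ctr[1])^2 + (cl - ctr[2])^2 <= 100) img0[r, cl] <- 500
  }
  truth <- img0 > 100
  set.seed(11)
  noisy <- matrix(rpois(length(img0), img0), 80, 80)
  m <- otsuMask(noisy)
  iou <- sum(m@pixels & truth) / sum(m@pixels | truth)
  expect_gte(iou, 0.8)
})
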