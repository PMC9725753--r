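## labeled-object movie from a list of logical masks
maskMovie <- function(masks, cal = Calibration()) {
  lapply(masks, function(m) labelComponents(BinaryMask(m, cal)))
}

blockMask <- function(rows, cols, n = 40) {
  m <- matrix(FALSE, n, n); m[rows, cols] <- TRUE; m
}

test_that("a static object yields one track spanning the movie", {
  mv <- maskMovie(rep(list(blockMask(10:14, 10:20)), 20))
  tr <- trackComponents(mv)
  expect_equal(nrow(tr$tracks), 1L)
  expect_equal(tr$tracks$birth, 1L)
  expect_equal(tr$tracks$death, 20L)
  expect_equal(nrow(tr$links), 0L)
})

test_that("splits and merges are recorded with their participants", {
  one <- blockMask(10:12, 5:30)
  two <- blockMask(10:12, 5:15) | blockMask(10:12, 20:30)
  mvS <- maskMovie(c(rep(list(one), 9), rep(list(two), 11)))
  trS <- trackComponents(mvS)
  expect_equal(sum(trS$links$type == "split"), 1L)
  expect_equal(trS$links$frame[trS$links$type == "split"], 10L)
  mvM <- maskMovie(c(rep(list(two), 9), rep(list(one), 11)))
  trM <- trackComponents(mvM)
  mg <- trM$links[trM$links$type == "merge", ]
  expect_equal(nrow(mg), 1L)
  expect_equal(mg$frame, 10L)
  expect_length(strsplit(mg$parents, ",")[[1]], 2L)
})

test_that("fission requires persistent separation; re-merge cancels it", {
  one <- blockMask(10:12, 5:30)
  two <- blockMask(10:12, 5:15) | blockMask(10:12, 20:30)
  ## split at frame 10, children persist to movie end: one fission
  mv1 <- maskMovie(c(rep(list(one), 9), rep(list(two), 11)))
  tr1 <- trackComponents(mv1)
  f1 <- detectFissionEvents(tr1, mv1)
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$kind, "fission")
  expect_equal(f1$class, "none")
  ## split followed by immediate re-merge of the same pair: no fission
  mv2 <- maskMovie(c(rep(list(one), 9), list(two), rep(list(one), 10)))
  tr2 <- trackComponents(mv2)
  expect_equal(nrow(detectFissionEvents(tr2, mv2)), 0L)
})

test_that("fusion needs converted-label mixing; kiss-and-run is rejected", {
  cal <- Calibration()
  sep <- blockMask(10:12, 3:14) | blockMask(10:12, 18:30)
  joined <- blockMask(10:12, 3:30)
  nF <- 20L
  masksL <- c(rep(list(sep), 7), rep(list(joined), 13))
  mv <- maskMovie(masksL, cal)
  mkConv <- function(mixFrom) lapply(seq_len(nF), function(t) {
    img <- matrix(10, 40, 40)
    img[10:12, 3:14] <- 400                  # converted donor
    if (t >= mixFrom) img[10:12, 15:30] <- 400
    img
  })
  tr <- trackComponents(mv)
  ## label transfer at the merge: one fusion at the mixing frame
  fus <- detectFusionEvents(tr, mv, mkConv(9), cal)
  expect_equal(nrow(fus), 1L)
  expect_equal(fus$kind, "fusion")
  expect_lte(abs(fus$frame - 9L), 1L)
  ## contact without transfer, then separation: nothing
  masksKR <- c(rep(list(sep), 7), rep(list(joined), 2), rep(list(sep), 11))
  mvKR <- maskMovie(masksKR, cal)
  trKR <- trackComponents(mvKR)
  fusKR <- detectFusionEvents(trKR, mvKR, mkConv(Inf), cal)
  expect_equal(nrow(fusKR), 0L)
  ## and the transient contact is not scored as fission either
  expect_equal(nrow(detectFissionEvents(trKR, mvKR, cal)), 0L)
})

test_that("a movie without a converted object raises an error", {
  mv <- maskMovie(rep(list(blockMask(10:12, 5:30)), 5))
  flat <- lapply(1:5, function(t) matrix(10, 40, 40))
  tr <- trackComponents(mv)
  expect_error(detectFusionEvents(tr, mv, flat), "photoconverted")
})

test_that("tip-geometry classification follows the endpoint rule", {
  ## donor bar ending at the acceptor's endpoint: tip-to-tip
  donor <- skeletonizeMask(BinaryMask(blockMask(10:12, 5:24, 60)))
  acceptor <- skeletonizeMask(BinaryMask(blockMask(10:12, 28:50, 60)))
  touch <- c(2.6, 1.05)      # between the two tips, in um
  cls <- classifyFusionEvent(touch, donor, acceptor)
  expect_equal(cls$class, "tip_to_tip")
  expect_false(cls$atypical)
  ## donor tip against the acceptor mid-body: tip-to-middle
  acceptorV <- skeletonizeMask(BinaryMask(blockMask(3:55, 28:30, 60)))
  midTouch <- c(2.75, 2.9)
  cls2 <- classifyFusionEvent(midTouch, donor, acceptorV)
  expect_equal(cls2$class, "tip_to_middle")
  ## degenerate skeleton: explicit error
  empty <- skeletonizeMask(BinaryMask(matrix(FALSE, 20, 20)))
  expect_error(classifyFusionEvent(touch, donor, empty), "degenerate")
})

test_that("event rates follow count / (mitochondria x minutes) exactly", {
  ev <- data.frame(kind = c(rep("fusion", 5), "fission"),
                   class = c(rep("tip_to_middle", 3), rep("tip_to_tip", 2),
                             "none"))
  r <- computeEventRates(ev, nMitochondria = 4, durationMin = 5)
  expect_equal(r$rate[r$class == "total" & r$kind == "fusion"], 0.25)
  expect_equal(r$rate[r$class == "tip_to_middle"], 0.15)
  expect_equal(r$rate[r$class == "tip_to_tip"], 0.10)
  expect_equal(r$rate[r$kind == "fission"], 0.05)
  ## class rates sum exactly to the fusion total
  expect_identical(r$rate[r$class == "tip_to_middle"] +
                     r$rate[r$class == "tip_to_tip"] +
                     r$rate[r$class == "unclassified"],
                   r$rate[r$class == "total" & r$kind == "fusion"])
  r0 <- computeEventRates(ev[0, ], 4, 5)
  expect_true(all(r0$rate == 0))
  expect_error(computeEventRates(ev, 0, 5), "mitochondrion")
  expect_error(computeEventRates(ev, 4, 0), "duration")
})

test_that("scheduled fission events in a clean render are all detected", {
  p <- sceneParams(nMito = 4, nErTubules = 0, fovUm = c(16, 16),
                   durationS = 300, fissionRatePerMitoMin = 0.12,
                   photoconvert = TRUE)
  checked <- 0
  for (s in 1:8) {
    sc <- buildScene(p, seed = s)
    k <- sum(sc@events$realized & sc@events$kind == "fission" &
               sc@events$frame <= 48)     # leave room to separate on film
    if (k == 0) next
    mv <- renderMovie(sc, seed = s + 40, channels = c("native", "converted"),
                      noise = FALSE)
    res <- scoreDynamics(mv)
    expect_gte(sum(res$events$kind == "fission"), k)
    checked <- checked + 1
    if (checked >= 3) break
  }
  expect_gte(checked, 1)
})
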