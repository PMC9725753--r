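test_that("identical groups give F = 0 and p = 1", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anovaTukey(g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_true(all(res$pairwise$p.adj == 1))
  expect_equal(res$stars, "ns")
})

test_that("for two groups the ANOVA F equals the squared pooled t", {
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(6, 10, 2); b <- rnorm(8, 12, 2)
    f <- anovaTukey(list(a = a, b = b))
    t2 <- tTestTwoTailed(a, b)$statistic^2
    expect_equal(f$statistic, t2, tolerance = 1e-10)
    expect_equal(f$p.value, tTestTwoTailed(a, b)$p.value, tolerance = 1e-10)
  }
})

test_that("a fixed 3x5 table matches the hand-computed ANOVA decomposition", {
  g <- list(ctrl = c(4, 6, 5, 7, 8),
            kd = c(2, 3, 2, 4, 4),
            rescue = c(5, 6, 7, 6, 6))
  ## sum-of-squares arithmetic done long-hand:
  ## means: 6, 3, 6; grand mean 5
  ## SSB = 5*((6-5)^2 + (3-5)^2 + (6-5)^2) = 5*6 = 30, dfB = 2
  ## SSW = (4,6,5,7,8 about 6 -> 4+0+1+1+4 = 10)
  ##     + (2,3,2,4,4 about 3 -> 1+0+1+1+1 = 4)
  ##     + (5,6,7,6,6 about 6 -> 1+0+1+0+0 = 2)  = 16, dfW = 12
  ## F = (30/2) / (16/12) = 15 / (4/3) = 11.25
  res <- anovaTukey(g)
  expect_equal(res$statistic, 11.25, tolerance = 1e-6)
  expect_equal(res$df, c(2, 12))
  expect_equal(res$p.value, pf(11.25, 2, 12, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p.adj >= 0 & res$pairwise$p.adj <= 1))
})

test_that("two-sample t follows the closed-form pooled formula", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  ## pooled: means 2 and 3, s2p = (2 + 2) / 4 = 1,
  ## t = (2 - 3) / sqrt(1 * (1/3 + 1/3)) = -sqrt(3/2)
  res <- tTestTwoTailed(a, b)
  expect_equal(res$statistic, -sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(res$df, 4)
  ## antisymmetry and the trivial identity case
  expect_equal(tTestTwoTailed(b, a)$statistic, -res$statistic)
  same <- tTestTwoTailed(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(tTestTwoTailed(1, c(1, 2)), "at least 2")
})

test_that("group summaries match the sort-based percentile oracle", {
  s <- summarizeGroups(list(a = c(1, 2, 3, 4, 5)))
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  single <- summarizeGroups(list(b = 7))
  expect_true(all(c(single$median, single$q1, single$q3) == 7))
  set.seed(12)
  for (i in 1:10) {
    v <- runif(sample(3:20, 1), 0, 100)
    s2 <- summarizeGroups(list(g = v))
    srt <- sort(v)
    oracle <- function(p) {
      h <- (length(srt) - 1) * p + 1
      lo <- floor(h)
      srt[lo] + (h - lo) * (srt[min(lo + 1, length(srt))] - srt[lo])
    }
    expect_equal(s2$median, oracle(0.5))
    expect_equal(s2$q1, oracle(0.25))
    expect_equal(s2$q3, oracle(0.75))
  }
})

test_that("significance stars follow the reporting thresholds", {
  expect_identical(significanceStars(c(0.5, 0.02, 0.005, 5e-4, 5e-5)),
                   c("ns", "ns", "**", "***", "****"))
  expect_error(significanceStars(1.5))
})

test_that("LFQ enrichment averages replicates and ranks by ratio", {
  tab <- data.frame(protein = c("A", "B", "C"),
                    wt1 = c(10, 6, 8), wt2 = c(14, 6, 8),
                    mut1 = c(6, 6, 16), mut2 = c(6, 6, 16))
  e <- lfqEnrichment(tab, c("wt1", "wt2"), c("mut1", "mut2"))
  a <- e[e$protein == "A", ]
  expect_equal(a$meanWT, 12); expect_equal(a$meanMUT, 6)
  expect_equal(a$ratio, 2); expect_equal(a$rank, 1L)
  expect_equal(e$ratio[e$protein == "B"], 1)        # diagonal
  expect_equal(e$rank[e$protein == "C"], 3L)
  ## one-sided proteins are floor-imputed and flagged
  tab2 <- data.frame(protein = c("D", "E"), wt1 = c(8, 4), wt2 = c(8, 4),
                     mut1 = c(0, 4), mut2 = c(NA, 4))
  e2 <- lfqEnrichment(tab2, c("wt1", "wt2"), c("mut1", "mut2"))
  d <- e2[e2$protein == "D", ]
  expect_true(d$oneSided)
  expect_equal(d$meanMUT, 2)               # floor = min positive / 2 = 2
  expect_equal(d$ratio, 4)
  ## ranking is invariant to uniform rescaling
  e3 <- lfqEnrichment(transform(tab, wt1 = wt1 * 10, wt2 = wt2 * 10,
                                mut1 = mut1 * 10, mut2 = mut2 * 10),
                      c("wt1", "wt2"), c("mut1", "mut2"))
  expect_identical(e3$protein, e$protein)
})
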