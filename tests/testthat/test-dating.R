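test_that("pairwise SNP counts match a brute-force site loop", {
  m <- hapFix(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 0L)),
              labels = c("x_1", "x_2"))
  out <- pairwiseSnpCounts(m, data.frame(a = "x_1", b = "x_2"))
  expect_equal(out$pairs$count, 2L)
  # identical haplotypes differ at zero sites
  m0 <- hapFix(matrix(1L, 5, 2), labels = c("x_1", "x_2"))
  expect_equal(pairwiseSnpCounts(m0, data.frame(a = "x_1", b = "x_2"))$pairs$count, 0L)
  expect_error(pairwiseSnpCounts(m, data.frame(a = character(0), b = character(0))),
               "empty")

  # random fixtures vs brute-force oracle, with missing data
  set.seed(71)
  for (rep in 1:5) {
    a <- matrix(rbinom(200 * 6, 1, 0.3), 200, 6)
    a[sample.int(1200, 60)] <- NA
    m <- hapFix(a)
    labs <- haplotypeNames(m)
    pr <- withinPairs(labs[1:4])
    out <- pairwiseSnpCounts(m, pr)
    for (i in seq_len(nrow(pr))) {
      expect_equal(out$pairs$count[i],
                   bruteDiff(a[, match(pr$a[i], labs)], a[, match(pr$b[i], labs)]))
    }
  }
})

test_that("group summaries are the mean and SD over listed pairs", {
  # counts {2, 4, 6} by construction
  a <- matrix(0L, 10, 4)
  a[1:2, 2] <- 1L; a[3:6, 3] <- 1L; a[c(1:2, 3:6), 4] <- 1L
  m <- hapFix(a, labels = c("p_1", "p_2", "q_1", "q_2"))
  out <- pairwiseSnpCounts(m, data.frame(a = c("p_1", "p_1", "p_1"),
                                         b = c("p_2", "q_1", "q_2")))
  expect_equal(sort(out$pairs$count), c(2L, 4L, 6L))
  expect_equal(out$mean, 4)
  expect_equal(out$sd, 2)
})

test_that("variant-list differences follow the set-difference rule", {
  A <- data.frame(pos = c(10, 20, 30), alt = c("A", "C", "G"))
  expect_equal(variantListPairwiseDiffs(A, A), 0L)
  B <- data.frame(pos = c(10, 20, 40), alt = c("A", "C", "T"))
  # A-only {30}, B-only {40}, shared same alt -> 2
  expect_equal(variantListPairwiseDiffs(A, B), 2L)
  # shared position with a different alternate allele counts once
  C <- data.frame(pos = c(10, 20, 30), alt = c("A", "T", "G"))
  expect_equal(variantListPairwiseDiffs(A, C), 1L)
  expect_error(variantListPairwiseDiffs(A, data.frame(pos = c(1, 1), alt = c("A", "C"))),
               "malformed")
})

test_that("coalescent dating reproduces the published worked values", {
  # 26 SNPs over the 102,909 bp minimal haplotype: ~89 thousand years
  expect_equal(coalescentTime(26, 1.42e-9, 102909) / 1000, 89, tolerance = 0.005)
  # the +/- 8 SNPs give the +/- 27 KY
  expect_equal(coalescentTime(8, 1.42e-9, 102909) / 1000, 27.4, tolerance = 0.005)
  # de novo assembly comparison: 11 SNPs over 92,199 bp -> 42 KY
  expect_equal(coalescentTime(11, 1.42e-9, 92199) / 1000, 42, tolerance = 0.005)
  expect_equal(coalescentTime(0, 1.42e-9, 102909), 0)
  expect_error(coalescentTime(5, 0, 100), "positive")

  expect_equal(expectedSnps(4e6, 1.42e-9, 102909), 1169.05, tolerance = 1e-4)
  expect_equal(expectedSnps(5e6, 1.42e-9, 102909), 1461.31, tolerance = 1e-4)
  expect_equal(expectedSnps(0, 1.42e-9, 102909), 0)
  expect_error(expectedSnps(-1, 1.42e-9, 102909), "negative")
})

test_that("forward and inverse dating round-trip exactly", {
  for (T in c(0, 857, 1e5, 4.5e6)) {
    expect_equal(coalescentTime(expectedSnps(T, 1.42e-9, 102909),
                                1.42e-9, 102909), T, tolerance = 1e-9)
  }
})

test_that("similarity percent reproduces the checker-checker value", {
  expect_equal(similarityPercent(26, 4261), 99.39, tolerance = 0.005)
  expect_equal(similarityPercent(0, 4261), 100)
  expect_equal(similarityPercent(4261, 4261), 0)
  expect_error(similarityPercent(10, 0), "positive")
  expect_error(similarityPercent(11, 10), "0 <= S <= K")
})

test_that("divergence-vs-expectation t-test matches the closed form", {
  r <- divergenceVsExpectationTest(c(380, 384, 388), 1169.05)
  tHand <- (384 - 1169.05) / (4 / sqrt(3))
  expect_equal(r$t, tHand)
  expect_lt(r$p, 0.001)
  # cross-check against stats::t.test on a non-degenerate sample
  x <- c(350, 420, 391, 377)
  tt <- t.test(x, mu = 1169.05)
  r2 <- divergenceVsExpectationTest(x, 1169.05)
  expect_equal(r2$t, unname(tt$statistic))
  expect_equal(r2$p, tt$p.value)
  # degenerate zero-variance sample equal to expectation
  r0 <- divergenceVsExpectationTest(c(5, 5, 5), 5)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_error(divergenceVsExpectationTest(380, 1169.05), "two")
})

test_that("cytochrome-b divergence dating brackets the 4-5 MY species split", {
  t <- cytbDivergenceTime(8.0, 1.96)
  expect_equal(t, 8.0 / 1.96)
  expect_gt(t, 4); expect_lt(t, 5)
  expect_equal(cytbDivergenceTime(0, 1.96), 0)
  expect_error(cytbDivergenceTime(8, 0), "positive")
})

test_that("generations convert to years at one or two generations per year", {
  expect_equal(generationsToYears(857, 1), 857)
  expect_equal(generationsToYears(857, 2), 428.5)
  expect_equal(generationsToYears(1000, 2), 500)
  expect_equal(generationsToYears(0, 1), 0)
  expect_error(generationsToYears(100, 0), "invalid")
})
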