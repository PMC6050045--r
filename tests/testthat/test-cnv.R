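cnvR <- genomicRegion("sc", 8001, 10000)
refR <- genomicRegion("sc", 1, 8000)

test_that("copy number is twice the normalized depth ratio, tie rounds down", {
  mkTrack <- function(refDepth, cnvDepth)
    DepthTrack("sc", seq(1, 10000, by = 100),
               c(rep(refDepth, 80), rep(cnvDepth, 20)), binWidth = 100L)
  cc <- estimateCopyNumber(mkTrack(15, 15), cnvR, refR)
  expect_equal(copyEstimate(cc), 2)
  expect_equal(copyCall(cc), 2L)
  cc2 <- estimateCopyNumber(mkTrack(15, 30), cnvR, refR)
  expect_equal(copyEstimate(cc2), 4)
  expect_equal(copyCall(cc2), 4L)
  # estimate 7 ties between 6 and 8: call 6
  cc3 <- estimateCopyNumber(mkTrack(10, 35), cnvR, refR)
  expect_equal(copyEstimate(cc3), 7)
  expect_equal(copyCall(cc3), 6L)
  expect_error(estimateCopyNumber(mkTrack(0, 10), cnvR, refR), "zero mean")
  expect_error(estimateCopyNumber(DepthTrack("sc", 1:10, rep(1, 10)),
                                  cnvR, refR), "cover")
})

test_that("copy-number estimation is scale invariant", {
  set.seed(91)
  tr <- simulateDepth(c(1, 4), coverage = 20, cnvRegion = cnvR,
                      referenceRegion = refR, seed = 1)
  base <- copyEstimate(estimateCopyNumber(tr, cnvR, refR))
  for (k in c(0.01, 0.5, 3, 1000)) {
    scaled <- DepthTrack("sc", depthPositions(tr), k * depthValues(tr),
                         binWidth = 100L)
    expect_equal(copyEstimate(estimateCopyNumber(scaled, cnvR, refR)), base)
  }
})

test_that("depth simulation recovers the configured copy totals", {
  est <- function(cp, s)
    copyEstimate(estimateCopyNumber(simulateDepth(cp, 20, seed = s)))
  expect_equal(est(c(1, 1), 1), 2, tolerance = 0.1)
  expect_equal(est(c(4, 4), 2), 8, tolerance = 0.05)
  expect_equal(est(c(1, 2), 3), 3, tolerance = 0.1)
  expect_error(simulateDepth(c(1, 3), 20), "1, 2, 4")
  expect_error(simulateDepth(c(1, 1), 0), "coverage")
})

test_that("pairwise Wilcoxon p-values match exact enumeration", {
  # {1,2,3} vs {10,11,12}: most extreme of C(6,3) = 20 arrangements,
  # two-sided exact p = 2/20 = 0.1
  combos <- combn(6, 3)
  vals <- c(1, 2, 3, 10, 11, 12)
  obs <- sum(rank(vals)[1:3])
  sums <- apply(combos, 2, function(ix) sum(rank(vals)[ix]))
  pEnum <- 2 * min(mean(sums <= obs), mean(sums >= obs))
  expect_equal(pEnum, 0.1)
  pExact <- wilcox.test(c(1, 2, 3), c(10, 11, 12), exact = TRUE)$p.value
  expect_equal(pExact, pEnum)
  out <- copyPhenotypeTest(c(1, 2, 3, 10, 11, 12),
                           rep(c("bar", "checker"), each = 3))
  expect_equal(out$p, pExact, tolerance = 0.35)  # normal approx vs exact
  expect_equal(out$pAdj, out$p)                  # single pair: BH is identity

  # identical groups: adjusted p = 1
  same <- copyPhenotypeTest(rep(c(2, 4, 4, 6), 2), rep(c("a", "b"), each = 4))
  expect_equal(same$pAdj, 1)
  expect_error(copyPhenotypeTest(1:3, rep("a", 3)), "two")

  # three groups: BH adjustment across the three pairs
  three <- copyPhenotypeTest(c(2, 2, 2, 4, 4, 5, 8, 8, 7),
                             rep(c("bar", "checker", "tcheck"), each = 3))
  expect_equal(nrow(three), 3)
  expect_equal(three$pAdj, p.adjust(three$p, "BH"))
})

test_that("pigment regression r-squared matches a closed-form linear fit", {
  x <- c(2, 4, 6, 8); y <- c(12, 30, 35, 50)
  fit <- pigmentCopyRegression(y, x, model = "linear")
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2Hand <- 1 - sum((y - (a + b * x))^2) / sum((y - mean(y))^2)
  expect_equal(fit$rSquared, r2Hand)

  # exact curve: r-squared 1 (logistic nls on noiseless logistic data)
  exact <- simulatePigmentPanel(rep(c(2, 3, 4, 5, 6, 8), 4), noiseSd = 0,
                                seed = 1)
  fitL <- pigmentCopyRegression(exact$percentArea, exact$copies)
  expect_equal(fitL$rSquared, 1, tolerance = 1e-6)

  # constant response: r-squared 0
  expect_equal(pigmentCopyRegression(rep(40, 6), c(2, 3, 4, 5, 6, 8))$rSquared, 0)
  expect_error(pigmentCopyRegression(c(1, 2, 3), c(4, 4, 4)), "vary")
  expect_error(simulatePigmentPanel(c(2, 7)), "attainable")
})

test_that("qPCR relative expression is 2^-deltaCt of replicate means", {
  expect_equal(qpcrRelativeExpression(c(20, 20), c(20, 20)), 1)
  expect_equal(qpcrRelativeExpression(c(21, 21), c(20, 20)), 0.5)
  expect_equal(qpcrRelativeExpression(c(18, 18), c(20, 20)), 4)
  # replicate means first: mean(19,21)=20
  expect_equal(qpcrRelativeExpression(c(19, 21), c(20, 20)), 1)
  # delta-delta-Ct against a calibrator
  expect_equal(qpcrRelativeExpression(21, 20, 23, 20), 4)
  expect_error(qpcrRelativeExpression(numeric(0), 20), "empty")
})
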