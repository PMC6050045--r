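test_that("site-pattern weights follow the frequency formula", {
  expect_equal(sitePatterns(0, 1, 1, 0), data.frame(abba = 1, baba = 0))
  expect_equal(sitePatterns(1, 0, 1, 0), data.frame(abba = 0, baba = 1))
  expect_equal(sitePatterns(0.5, 0.5, 1, 0),
               data.frame(abba = 0.25, baba = 0.25))
  expect_error(sitePatterns(1.2, 0, 0, 0), "frequencies")
})

test_that("D is the normalized pattern-sum difference, undefined at zero sums", {
  expect_equal(dStatistic(2, 2), 0)
  expect_equal(dStatistic(5, 0), 1)
  expect_equal(dStatistic(3, 1), 0.5)
  expect_true(is.na(dStatistic(0, 0)))
  expect_error(dStatistic(-1, 0), "nonnegative")
})

# four diploid samples, one per role
dPanel <- PopulationPanel(list(bar = "b", chk = "c", gui = "g", pal = "o"),
                          roles = c(P1 = "bar", P2 = "chk", P3 = "gui",
                                    O = "pal"))
dLabels <- sampleHaplotypes(c("b", "c", "g", "o"))

test_that("windowed D equals global D over one window and flags empty windows", {
  set.seed(21)
  a <- matrix(rbinom(50 * 8, 1, 0.4), 50, 8)
  a[, 7:8] <- 0L   # outgroup ancestral
  m <- hapFix(a, pos = 1:50 * 10, labels = dLabels)
  g <- globalD(m, dPanel)
  w <- windowedD(m, dPanel, makeWindows(genomicRegion("s", 1, 500), 500))
  expect_equal(mcols(w)$D, g$D)

  # ABBA-only sites in the left half: left D = 1, right window missing
  a2 <- matrix(0L, 10, 8)
  a2[1:5, 3:6] <- 1L  # p2 = p3 = 1, p1 = pO = 0 at sites 1..5
  m2 <- hapFix(a2, pos = 1:10 * 10, labels = dLabels)
  w2 <- windowedD(m2, dPanel, makeWindows(genomicRegion("s", 1, 100), 50))
  expect_equal(mcols(w2)$D[1], 1)
  expect_true(is.na(mcols(w2)$D[2]))
})

test_that("swapping P1 and P2 negates D; site order is irrelevant", {
  swapped <- PopulationPanel(list(bar = "b", chk = "c", gui = "g", pal = "o"),
                             roles = c(P1 = "chk", P2 = "bar", P3 = "gui",
                                       O = "pal"))
  set.seed(31)
  for (rep in 1:5) {
    a <- matrix(rbinom(40 * 8, 1, runif(1, 0.2, 0.6)), 40, 8)
    m <- hapFix(a, labels = dLabels)
    d1 <- globalD(m, dPanel)$D
    d2 <- globalD(m, swapped)$D
    if (!is.na(d1)) expect_equal(d1, -d2)
    # window order is irrelevant: per-window values permute along
    win <- makeWindows(genomicRegion("s", 1, 400), 100)
    wd <- windowedD(m, dPanel, win)
    perm <- sample.int(length(win))
    wdP <- windowedD(m, dPanel, win[perm])
    expect_equal(mcols(wdP)$D, mcols(wd)$D[perm])
  }
})

test_that("frequency-weighted D matches brute-force pattern counting on haploid data", {
  set.seed(41)
  for (rep in 1:5) {
    a <- matrix(rbinom(200 * 8, 1, 0.5), 200, 8)
    a[, seq(2, 8, 2)] <- a[, seq(1, 7, 2)]  # make samples homozygous
    m <- hapFix(a, labels = dLabels)
    cnt <- bruteDCount(a[, 1], a[, 3], a[, 5], a[, 7])
    g <- globalD(m, dPanel)
    expect_equal(g$sumAbba, unname(cnt["abba"]))
    expect_equal(g$sumBaba, unname(cnt["baba"]))
  }
})

test_that("combination averaging reduces to simple means", {
  set.seed(51)
  a <- matrix(rbinom(60 * 12, 1, 0.4), 60, 12)
  a[, 11:12] <- 0L
  labs <- sampleHaplotypes(c("b1", "b2", "c1", "c2", "g", "o"))
  m <- hapFix(a, pos = 1:60 * 10, labels = labs)
  panel <- PopulationPanel(list(bar = c("b1", "b2"), chk = c("c1", "c2"),
                                gui = "g", pal = "o"),
                           roles = c(P1 = "bar", P2 = "chk", P3 = "gui",
                                     O = "pal"))
  win <- makeWindows(genomicRegion("s", 1, 600), 300)
  cm <- comboMeanD(m, panel, win)
  expect_equal(nrow(cm$perCombo), 4)
  expect_equal(cm$grandMean, mean(cm$perCombo$meanD))
  # identical data in every combo: grand mean equals the per-combo mean
  one <- comboMeanD(m, panel, win, p1Samples = "b1", p2Samples = "c1")
  expect_equal(one$grandMean, one$perCombo$meanD[1])
})

test_that("block bootstrap CI is deterministic and matches enumeration on tiny n", {
  expect_equal(unname(blockBootstrapCi(rep(0.3, 5), seed = 1)), c(0.3, 0.3))
  ci1 <- blockBootstrapCi(c(0, 0.5, 1, 0.2), replicates = 500, seed = 9)
  ci2 <- blockBootstrapCi(c(0, 0.5, 1, 0.2), replicates = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_error(blockBootstrapCi(c(1, NA)), "two")

  # exhaustive enumeration oracle: all 4^4 equally likely resamples
  v <- c(0, 0, 1, 1)
  grid <- expand.grid(1:4, 1:4, 1:4, 1:4)
  meansAll <- rowMeans(matrix(v[as.matrix(grid)], ncol = 4))
  exact <- quantile(meansAll, c(0.025, 0.975), names = FALSE)
  boot <- blockBootstrapCi(v, replicates = 20000, seed = 3)
  expect_equal(unname(boot), exact, tolerance = 0.05)
})
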