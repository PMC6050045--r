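test_that("EHH counts identical extended-haplotype pairs", {
  # 4 carriers, identical over the whole span
  m <- hapFix(matrix(0L, 9, 4), pos = 10 * (1:9))
  carriers <- haplotypeNames(m)
  cv <- ehhCurve(m, focal = 50, carriers, side = "right")
  expect_equal(cv@ehh, rep(1, 5))  # focal + 4 sites right
  expect_equal(cv@positions[1], 50)

  # beyond position 60 the carriers split into two identical pairs:
  # EHH = 2 / C(4,2) = 1/3
  a <- matrix(0L, 9, 4)
  a[7:9, c(2, 4)] <- 1L
  m2 <- hapFix(a, pos = 10 * (1:9))
  cv2 <- ehhCurve(m2, 50, carriers, side = "right")
  expect_equal(cv2@ehh, c(1, 1, 1/3, 1/3, 1/3))

  # all carriers distinct at the first flanking site: EHH = 0 there
  a3 <- matrix(0L, 3, 4)
  a3[3, ] <- c(0L, 1L, 0L, 1L)
  a3[2, ] <- c(0L, 0L, 1L, 1L)
  m3 <- hapFix(a3, pos = c(10, 20, 30))
  cv3 <- ehhCurve(m3, 10, carriers, side = "right")
  expect_equal(cv3@ehh, c(1, 1/3, 0))

  expect_error(ehhCurve(m, 50, carriers[1]), "two")
  # discordant core allele at the focal site
  a4 <- matrix(0L, 3, 4); a4[2, 1] <- 1L
  m4 <- hapFix(a4, pos = c(10, 20, 30))
  expect_error(ehhCurve(m4, 20, carriers, side = "right"), "core allele")
})

test_that("EHH matches the brute-force pair-counting oracle and is monotone", {
  set.seed(81)
  for (rep in 1:5) {
    a <- matrix(rbinom(200 * 8, 1, 0.3), 200, 8)
    a[100, ] <- 0L  # shared core allele
    m <- hapFix(a, pos = 1:200 * 5)
    carriers <- haplotypeNames(m)
    cv <- ehhCurve(m, focal = 500, carriers, side = "right")
    expect_true(all(cv@ehh >= 0 & cv@ehh <= 1))
    expect_equal(cv@ehh[1], 1)
    expect_true(all(diff(cv@ehh) <= 1e-12))  # non-increasing, complete data
    for (k in c(2, 5, 20)) {
      spanRows <- 101:(99 + k)
      expect_equal(cv@ehh[k], bruteEhh(a, spanRows))
    }
  }
})

test_that("span homozygosity averages the two boundary EHH values", {
  mkCurve <- function(side, ehh, pos) {
    new("EHHCurve", side = side, focal = 0, positions = pos, ehh = ehh,
        n = 22L)
  }
  left <- mkCurve("left", c(1, 0.5, 0.18), -c(0, 1000, 2000))
  right <- mkCurve("right", c(1, 0.6, 0.228), c(0, 1500, 2500))
  sp <- spanHomozygosity(left, right, threshold = 0.25, rate = 2)
  expect_equal(sp$p, 0.204)  # (0.18 + 0.228) / 2
  expect_equal(sp$rLeftCm, 2000 * 2 / 1e6)
  expect_equal(sp$rRightCm, 2500 * 2 / 1e6)

  # degenerate threshold 1: boundary at the first flanking site
  sp1 <- spanHomozygosity(left, right, threshold = 1, rate = 2)
  expect_equal(sp1$boundaryLeft, -1000)
  expect_equal(sp1$p, (0.5 + 0.6) / 2)

  never <- mkCurve("left", c(1, 0.9, 0.8), -c(0, 1000, 2000))
  expect_error(spanHomozygosity(never, right, threshold = 0.25, rate = 2),
               "never drops")

  # genetic-map interpolation replaces the uniform rate
  map <- data.frame(pos = c(-3000, 0, 3000), cM = c(-0.3, 0, 0.3))
  spm <- spanHomozygosity(left, right, threshold = 0.25, map = map)
  expect_equal(spm$rLeftCm, 0.2)
})

test_that("age point estimate inverts the homozygosity-decay model", {
  expect_equal(agePoint(0.1, 1), 0)
  # algebraic round trip
  for (g0 in c(100, 857, 5000)) {
    r <- 0.0809
    pr <- exp(-2 * (r / 100) * g0)
    expect_equal(agePoint(r, pr), g0, tolerance = 1e-12)
  }
  # the published boundary (r = 0.0809 cM at Pr = 0.25) dates to ~857
  expect_equal(agePoint(0.0809, 0.25), 857, tolerance = 0.001)
  expect_error(agePoint(0, 0.5), "positive")
  expect_error(agePoint(0.1, 0), "0, 1")
  # strictly decreasing in pr and in r
  expect_gt(agePoint(0.08, 0.2), agePoint(0.08, 0.3))
  expect_gt(agePoint(0.05, 0.25), agePoint(0.1, 0.25))
})

test_that("binomial age CI matches exhaustive CDF summation", {
  n <- 22; p <- 0.204
  cdf <- cumsum(dbinom(0:n, n, p))
  NLoOracle <- min(which(cdf >= 0.025)) - 1  # smallest N with CDF >= 2.5%
  NHiOracle <- min(which(cdf >= 0.975)) - 1
  ci <- ageCi(n, p, rCm = 0.0809)
  expect_equal(ci$NLo, NLoOracle)
  expect_equal(ci$NHi, NHiOracle)
  expect_false(ci$unboundedUpper)
  # interval brackets the point estimate computed from the same p
  g <- agePoint(0.0809, p)
  expect_true(ci$ci["lo"] <= g && g <= ci$ci["hi"])

  # p near 1: no recombination observable, age interval collapses to zero
  ci1 <- ageCi(22, 1 - 1e-12, rCm = 0.0809)
  expect_equal(unname(ci1$ci), c(0, 0))
  # tiny p: lower quantile 0 leaves the upper age unbounded
  ci0 <- ageCi(10, 0.01, rCm = 0.0809)
  expect_true(ci0$unboundedUpper)
  expect_equal(unname(ci0$ci["hi"]), Inf)
  expect_error(ageCi(22, 1.2, 0.08), "strictly")

  # interval widens as the carrier count drops at fixed p
  wide <- ageCi(8, 0.204, 0.0809)$ci
  narrow <- ageCi(80, 0.204, 0.0809)$ci
  expect_lt(diff(range(narrow)), diff(range(wide)))
})

test_that("the full age wrapper assembles point, CI and year conversions", {
  mkCurve <- function(side, ehh, pos)
    new("EHHCurve", side = side, focal = 0, positions = pos, ehh = ehh,
        n = 22L)
  left <- mkCurve("left", c(1, 0.18), -c(0, 49030))
  right <- mkCurve("right", c(1, 0.228), c(0, 49030))
  age <- estimateHaplotypeAge(left, right, rate = 1.65, n = 22)
  expect_s4_class(age, "AgeEstimate")
  rCm <- 49030 * 1.65 / 1e6
  expect_equal(ageGenerations(age), agePoint(rCm, 0.204))
  expect_equal(age@yearsTwoGen, ageGenerations(age) / 2)
  expect_true(ageInterval(age)[1] < ageGenerations(age))
})
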