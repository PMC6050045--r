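#' Extended haplotype homozygosity from a focal site
#'
#' At each site outward from the focal position, EHH is the probability
#' that two randomly drawn carrier haplotypes are identical over the
#' whole span from the focal site to that site:
#' sum over distinct extended haplotypes of C(n_h, 2) / C(n, 2).
#' Haplotypes with missing data anywhere in the current span are excluded
#' from both numerator and denominator; the curve is truncated if fewer
#' than two haplotypes remain.
#'
#' @param h a phased [HaplotypeMatrix-class].
#' @param focal focal position (bp).
#' @param carriers haplotype labels carrying the core allele; they must
#'   agree at the focal site.
#' @param side "left" or "right".
#' @param scaffold scaffold of the focal site (optional when the matrix
#'   holds a single scaffold).
#' @return An [EHHCurve-class]; the first point is the focal position
#'   with EHH = 1.
#' @export
ehhCurve <- function(h, focal, carriers, side = c("right", "left"),
                     scaffold = NULL) {
  side <- match.arg(side)
  if (!isPhased(h)) stop("EHH requires phased haplotypes")
  if (length(carriers) < 2) stop("need at least two carrier haplotypes")
  scs <- as.character(seqnames(siteRanges(h)))
  if (is.null(scaffold)) {
    u <- unique(scs)
    if (length(u) != 1L)
      stop("matrix spans several scaffolds; supply 'scaffold'")
    scaffold <- u
  }
  on <- scs == scaffold
  pos <- sitePositions(h)[on]
  a <- alleleMatrix(h)[on, carriers, drop = FALSE]
  atFocal <- which(pos == focal)
  if (length(atFocal) == 1L) {
    core <- a[atFocal, ]
    if (length(unique(core[!is.na(core)])) > 1L)
      stop("carriers do not share the core allele at the focal site")
  }
  idx <- if (side == "right") which(pos > focal) else rev(which(pos < focal))
  n0 <- length(carriers)
  grp <- rep(1L, n0)            # extended-haplotype class per carrier
  alive <- rep(TRUE, n0)        # FALSE once missing data entered the span
  outPos <- c(focal, rep(NA_real_, length(idx)))
  outEhh <- c(1, rep(NA_real_, length(idx)))
  k <- 1L
  for (i in idx) {
    al <- a[i, ]
    alive <- alive & !is.na(al)
    n <- sum(alive)
    if (n < 2) break
    key <- paste(grp[alive], al[alive])
    grp[alive] <- match(key, unique(key))
    sizes <- tabulate(grp[alive])
    ehh <- sum(sizes * (sizes - 1) / 2) / (n * (n - 1) / 2)
    k <- k + 1L
    outPos[k] <- pos[i]
    outEhh[k] <- ehh
    if (ehh == 0 && !anyNA(a[idx, ])) {
      # all survivors distinct and no further exclusions possible:
      # EHH stays 0 for the rest of the side
      rest <- idx[match(i, idx) + seq_len(length(idx) - match(i, idx))]
      nr <- length(rest)
      if (nr > 0) {
        outPos[k + seq_len(nr)] <- pos[rest]
        outEhh[k + seq_len(nr)] <- 0
        k <- k + nr
      }
      break
    }
  }
  new("EHHCurve", side = side, focal = as.numeric(focal),
      positions = as.numeric(outPos[seq_len(k)]), ehh = outEhh[seq_len(k)],
      n = as.integer(n0))
}

setMethod("show", "EHHCurve", function(object) {
  cat(sprintf("EHHCurve (%s of %s): %d points, n = %d, min EHH = %.3f\n",
              object@side, format(object@focal, big.mark = ","),
              length(object@positions), object@n, min(object@ehh)))
})

#' Haplotype span and non-recombination probability from EHH decay
#'
#' On each side, the haplotype end is the first site at which EHH drops
#' below \code{threshold}; the non-recombination probability is the mean
#' of the two sides' EHH values at those boundary sites,
#' p = (Pr[homoz | left] + Pr[homoz | right]) / 2. Genetic distances
#' focal-to-boundary are converted with a uniform rate (cM/Mb) or a
#' two-column genetic map (pos, cM; linear interpolation).
#'
#' @param left,right [EHHCurve-class]s for the two sides.
#' @param threshold EHH cutoff (default 0.25).
#' @param rate uniform recombination rate in cM/Mb (ignored when
#'   \code{map} is given).
#' @param map optional data.frame(pos, cM).
#' @return list(p, rLeftCm, rRightCm, boundaryLeft, boundaryRight,
#'   ehhLeft, ehhRight).
#' @export
spanHomozygosity <- function(left, right, threshold = 0.25, rate = NULL,
                             map = NULL) {
  pick <- function(curve) {
    i <- which(curve@ehh < threshold)
    if (!length(i))
      stop("EHH never drops below ", threshold, " on the ", curve@side,
           " side; extend the analyzed span")
    i[1]
  }
  iL <- pick(left); iR <- pick(right)
  bL <- left@positions[iL]; bR <- right@positions[iR]
  cmAt <- function(bp) {
    if (!is.null(map)) {
      stats::approx(map$pos, map$cM, xout = bp, rule = 2)$y
    } else {
      if (is.null(rate)) stop("supply either 'rate' (cM/Mb) or 'map'")
      bp * rate / 1e6
    }
  }
  list(p = (left@ehh[iL] + right@ehh[iR]) / 2,
       rLeftCm = abs(cmAt(bL) - cmAt(left@focal)),
       rRightCm = abs(cmAt(bR) - cmAt(right@focal)),
       boundaryLeft = bL, boundaryRight = bR,
       ehhLeft = left@ehh[iL], ehhRight = right@ehh[iR])
}

#' Haplotype age from homozygosity decay
#'
#' Under a star genealogy the probability that a random carrier pair is
#' homozygous out to genetic distance r Morgans after g generations is
#' Pr[homoz] = exp(-2 r g), hence
#' g = -100 * log(Pr[homoz]) / (2 * r_cM)  (natural log; the factor 100
#' converts centiMorgans to Morgans).
#'
#' @param rCm genetic distance focal-to-boundary in cM (> 0).
#' @param pr homozygosity probability in (0, 1].
#' @return Age in generations.
#' @examples
#' agePoint(0.0809, 0.25)  # ~857 generations
#' @export
agePoint <- function(rCm, pr) {
  if (any(rCm <= 0)) stop("genetic distance must be positive")
  if (any(pr <= 0 | pr > 1)) stop("Pr[homoz] must lie in (0, 1]")
  -100 * log(pr) / (2 * rCm)
}

#' Binomial confidence interval for the haplotype age
#'
#' The number N of carrier haplotypes unrecombined at the boundary is
#' modelled as Binomial(n, p); exact CDF quantiles of N at the interval
#' tails give homozygosity bounds N/n, which invert through [agePoint()]
#' to age bounds. A zero lower quantile leaves the upper age unbounded
#' (Inf, flagged).
#'
#' @param n carrier haplotype count (>= 2).
#' @param p non-recombination probability in (0, 1) (e.g. the boundary
#'   homozygosity from [spanHomozygosity()]).
#' @param rCm genetic distance in cM.
#' @param level confidence level (default 0.95).
#' @return list(ci = c(lo, hi) generations, NLo, NHi,
#'   unboundedUpper flag).
#' @export
ageCi <- function(n, p, rCm, level = 0.95) {
  if (p <= 0 || p >= 1) stop("p must lie strictly between 0 and 1")
  if (n < 2) stop("need n >= 2 carrier haplotypes")
  aL <- (1 - level) / 2
  NLo <- qbinom(aL, n, p)        # smallest N with CDF >= alpha/2
  NHi <- qbinom(1 - aL, n, p)
  gLo <- agePoint(rCm, NHi / n)
  unb <- NLo == 0
  gHi <- if (unb) Inf else agePoint(rCm, NLo / n)
  list(ci = c(lo = gLo, hi = gHi), NLo = NLo, NHi = NHi,
       unboundedUpper = unb)
}

#' Full LD-decay age estimate from two EHH curves
#'
#' Convenience wrapper: boundary detection and homozygosity via
#' [spanHomozygosity()], point age via [agePoint()] at the mean of the
#' two sides' genetic distances, binomial CI via [ageCi()], year
#' conversions at one and two generations per year.
#'
#' @inheritParams spanHomozygosity
#' @param n carrier haplotype count for the binomial CI (default: the
#'   carrier count of \code{left}).
#' @param level CI level.
#' @return An [AgeEstimate-class].
#' @export
estimateHaplotypeAge <- function(left, right, threshold = 0.25,
                                 rate = NULL, map = NULL, n = NULL,
                                 level = 0.95) {
  span <- spanHomozygosity(left, right, threshold = threshold,
                           rate = rate, map = map)
  if (is.null(n)) n <- left@n
  rCm <- (span$rLeftCm + span$rRightCm) / 2
  g <- agePoint(rCm, span$p)
  ci <- ageCi(n, span$p, rCm, level = level)
  new("AgeEstimate", g = g, ci = unname(ci$ci),
      yearsOneGen = generationsToYears(g, 1),
      yearsTwoGen = generationsToYears(g, 2),
      inputs = list(rCm = rCm, prHomoz = span$p, n = n, level = level,
                    boundaries = c(span$boundaryLeft, span$boundaryRight),
                    unboundedUpper = ci$unboundedUpper))
}

#' @describeIn estimateHaplotypeAge point age in generations.
#' @param x an \code{AgeEstimate}.
#' @export
ageGenerations <- function(x) x@g

#' @describeIn estimateHaplotypeAge CI in generations.
#' @export
ageInterval <- function(x) x@ci

setMethod("show", "AgeEstimate", function(object) {
  cat(sprintf(
    "AgeEstimate: %.0f generations (%.0f-%.0f), %.0f y at 1 gen/y, %.0f y at 2 gen/y\n",
    object@g, object@ci[1], object@ci[2],
    object@yearsOneGen, object@yearsTwoGen))
  cat(sprintf("  r = %.4f cM, Pr[homoz] = %.3f, n = %d\n",
              object@inputs$rCm, object@inputs$prHomoz, object@inputs$n))
})
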