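#' Per-site allele-frequency differentiation test
#'
#' A 1-df likelihood-ratio test on allele counts under binomial
#' likelihoods: the statistic is 2 * [l(p1.hat, p2.hat) - l(p.pooled)],
#' with the p-value from a chi-square with one degree of freedom. This is
#' a simple allele-count analogue of probabilistic differentiation scans
#' such as pFst.
#'
#' @param k1,k2 alternate-allele counts in the two groups (vectorized).
#' @param n1,n2 allele totals (> 0).
#' @return data.frame(stat, p), one row per site.
#' @examples
#' siteLrt(20, 20, 0, 20)  # stat = 80 * log(2), p ~ 1e-13
#' @export
siteLrt <- function(k1, n1, k2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("allele totals must be positive in both groups")
  if (any(k1 < 0 | k1 > n1) || any(k2 < 0 | k2 > n2))
    stop("allele counts must satisfy 0 <= k <= n")
  ll <- function(k, n, p) {
    out <- numeric(length(k))
    i <- k > 0
    out[i] <- out[i] + k[i] * log(p[i])
    i <- k < n
    out[i] <- out[i] + (n - k)[i] * log(1 - p[i])
    out
  }
  p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
  stat <- 2 * (ll(k1, n1, p1) + ll(k2, n2, p2) -
               ll(k1, n1, pp) - ll(k2, n2, pp))
  stat <- pmax(stat, 0)
  stat[abs(stat) < 1e-10] <- 0  # equal sample frequencies: exactly 0
  data.frame(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Genome-wide differentiation scan with Bonferroni threshold
#'
#' Applies [siteLrt()] at every site with non-missing alleles in both
#' contrast groups, sets the genome-wide threshold to
#' \code{alpha / number of sites tested}, and merges significant sites
#' separated by at most \code{mergeGap} bp (per scaffold) into candidate
#' regions.
#'
#' @param h a [HaplotypeMatrix-class].
#' @param panel a [PopulationPanel-class].
#' @param contrast length-2 character: the two group names to compare
#'   (default the P2 and P1 role groups, i.e. checker vs bar).
#' @param alpha family-wise error rate (default 0.05).
#' @param mergeGap bp gap tolerated inside a merged region (default 10 kb).
#' @return A [ScanResult-class].
#' @export
genomeScan <- function(h, panel, contrast = NULL, alpha = 0.05,
                       mergeGap = 10000) {
  if (is.null(contrast))
    contrast <- c(panel@roles[["P2"]], panel@roles[["P1"]])
  cols1 <- sampleHaplotypes(groupSamples(panel, contrast[1]))
  cols2 <- sampleHaplotypes(groupSamples(panel, contrast[2]))
  a <- alleleMatrix(h)
  k1 <- rowSums(a[, cols1, drop = FALSE] == 1L, na.rm = TRUE)
  n1 <- rowSums(!is.na(a[, cols1, drop = FALSE]))
  k2 <- rowSums(a[, cols2, drop = FALSE] == 1L, na.rm = TRUE)
  n2 <- rowSums(!is.na(a[, cols2, drop = FALSE]))
  test <- n1 > 0 & n2 > 0
  if (!any(test)) stop("no testable site (a group is all-missing everywhere)")
  res <- siteLrt(k1[test], n1[test], k2[test], n2[test])
  stats <- siteRanges(h)[test]
  mcols(stats) <- S4Vectors::DataFrame(stat = res$stat, p = res$p)
  nTested <- sum(test)
  threshold <- alpha / nTested
  sig <- stats[res$p < threshold]
  regions <- if (length(sig))
    reduce(sig, min.gapwidth = mergeGap + 1) else GRanges()
  mcols(regions) <- NULL
  new("ScanResult", stats = stats, threshold = threshold,
      nTested = as.integer(nTested), regions = regions)
}

#' @describeIn genomeScan per-site statistics accessor (\code{GRanges}
#'   with \code{stat} and \code{p}).
#' @param x a \code{ScanResult}.
#' @export
scanStats <- function(x) x@stats

#' @describeIn genomeScan genome-wide threshold accessor.
#' @export
scanThreshold <- function(x) x@threshold

#' @describeIn genomeScan merged significant regions accessor.
#' @export
scanRegions <- function(x) x@regions

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult:", object@nTested, "sites tested; threshold",
      format(object@threshold, digits = 3), "\n",
      length(object@regions), "merged significant region(s)\n")
})

#' Minimal shared haplotype around a focal position
#'
#' The maximal interval containing the focal position over which all
#' carrier haplotypes are mutually identical. Missing alleles are
#' wildcards: a site is discordant only when both 0 and 1 are observed
#' among carriers. Bounds are set at the nearest discordant site on each
#' side, exclusive (the returned region starts at the first concordant
#' site beyond it); with no discordant site the region runs to the edge
#' of the matrix extent on that scaffold.
#'
#' @param h a [HaplotypeMatrix-class].
#' @param carriers haplotype labels sharing the focal core allele.
#' @param focal focal position (bp), inside the matrix extent.
#' @param scaffold scaffold of the focal position; may be omitted when
#'   the matrix holds a single scaffold.
#' @return Length-1 \code{GRanges}.
#' @export
minimalSharedHaplotype <- function(h, carriers, focal, scaffold = NULL) {
  if (!length(carriers)) stop("carrier set is empty")
  scs <- as.character(seqnames(siteRanges(h)))
  if (is.null(scaffold)) {
    u <- unique(scs)
    if (length(u) != 1L)
      stop("matrix spans several scaffolds; supply 'scaffold'")
    scaffold <- u
  }
  on <- scs == scaffold
  pos <- sitePositions(h)[on]
  if (!length(pos) || focal < min(pos) || focal > max(pos))
    stop("focal position lies outside the matrix extent")
  a <- alleleMatrix(h)[on, carriers, drop = FALSE]
  has1 <- rowSums(a == 1L, na.rm = TRUE) > 0L
  has0 <- rowSums(a == 0L, na.rm = TRUE) > 0L
  discordant <- has0 & has1
  atFocal <- which(pos == focal)
  if (length(atFocal) && discordant[atFocal])
    stop("carriers are discordant at the focal position itself")
  dleft <- which(discordant & pos < focal)
  dright <- which(discordant & pos > focal)
  lo <- if (length(dleft)) pos[max(dleft) + 1L] else min(pos)
  hi <- if (length(dright)) pos[min(dright) - 1L] else max(pos)
  genomicRegion(scaffold, lo, hi)
}
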