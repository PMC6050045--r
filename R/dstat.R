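#' ABBA / BABA site-pattern weights from derived-allele frequencies
#'
#' For the four-taxon arrangement (P1, P2, P3, O) the frequency-weighted
#' pattern weights are
#' \code{abba = (1 - p1) * p2 * p3 * (1 - pO)} and
#' \code{baba = p1 * (1 - p2) * p3 * (1 - pO)}. Sites where the outgroup
#' carries the derived allele are retained with weight \code{1 - pO}
#' rather than dropped.
#'
#' @param p1,p2,p3,pO derived-allele frequencies in [0, 1] (vectorized).
#' @return data.frame(abba, baba).
#' @examples
#' sitePatterns(0, 1, 1, 0)        # canonical ABBA
#' sitePatterns(0.5, 0.5, 1, 0)    # (0.25, 0.25)
#' @export
sitePatterns <- function(p1, p2, p3, pO) {
  f <- c(p1, p2, p3, pO)
  if (any(f < 0 | f > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  data.frame(abba = (1 - p1) * p2 * p3 * (1 - pO),
             baba = p1 * (1 - p2) * p3 * (1 - pO))
}

#' Patterson's D from pattern sums
#'
#' \code{D = (sum(abba) - sum(baba)) / (sum(abba) + sum(baba))}. When
#' both sums are zero the statistic is undefined and \code{NA} is
#' returned (flagged missing, never coerced to 0).
#'
#' @param sumAbba,sumBaba nonnegative pattern-weight sums.
#' @return D in [-1, 1], or NA.
#' @export
dStatistic <- function(sumAbba, sumBaba) {
  if (sumAbba < 0 || sumBaba < 0) stop("pattern sums must be nonnegative")
  tot <- sumAbba + sumBaba
  if (tot == 0) return(NA_real_)
  (sumAbba - sumBaba) / tot
}

# Derived-allele frequency per site for a set of haplotype columns
# (pairwise deletion of missing alleles; NaN where all missing).
.groupFreq <- function(h, cols) {
  rowMeans(alleleMatrix(h)[, cols, drop = FALSE], na.rm = TRUE)
}

#' Per-site ABBA/BABA weights for a quartet panel
#'
#' @param h a polarized (derived-coded) [HaplotypeMatrix-class].
#' @param panel a [PopulationPanel-class] with all four roles assigned.
#' @param p1Samples,p2Samples optional sample-id overrides for the P1/P2
#'   roles (used for individual-combination averaging).
#' @param hapMode "frequency" (default) uses diploid derived-allele
#'   frequencies; "haplotype" uses only the first haplotype of each
#'   sample, matching one-sequence-per-role pattern counting.
#' @return data.frame(abba, baba), one row per site (NA where a role is
#'   entirely missing at the site).
#' @export
quartetPatterns <- function(h, panel, p1Samples = NULL, p2Samples = NULL,
                            hapMode = c("frequency", "haplotype")) {
  hapMode <- match.arg(hapMode)
  .checkQuartet(panel)
  cols <- function(samples) {
    labs <- sampleHaplotypes(samples)
    if (hapMode == "haplotype") labs <- labs[seq(1, length(labs), by = 2)]
    labs
  }
  p1 <- .groupFreq(h, cols(if (is.null(p1Samples)) roleSamples(panel, "P1") else p1Samples))
  p2 <- .groupFreq(h, cols(if (is.null(p2Samples)) roleSamples(panel, "P2") else p2Samples))
  p3 <- .groupFreq(h, cols(roleSamples(panel, "P3")))
  pO <- .groupFreq(h, cols(roleSamples(panel, "O")))
  ok <- is.finite(p1) & is.finite(p2) & is.finite(p3) & is.finite(pO)
  out <- data.frame(abba = rep(NA_real_, nSites(h)),
                    baba = rep(NA_real_, nSites(h)))
  out[ok, ] <- sitePatterns(p1[ok], p2[ok], p3[ok], pO[ok])
  out
}

#' Global and windowed D-statistics
#'
#' \code{globalD()} returns the pattern-sum ratio over all sites;
#' \code{windowedD()} computes one D per window from within-window
#' pattern sums (windows with zero informative pattern weight are
#' flagged missing, not zero).
#'
#' @param h a polarized [HaplotypeMatrix-class].
#' @param panel a [PopulationPanel-class] with quartet roles.
#' @param windows \code{GRanges} of windows (see [makeWindows()]).
#' @param ... passed to [quartetPatterns()].
#' @return \code{globalD()}: a list with \code{D}, \code{sumAbba},
#'   \code{sumBaba}, \code{sitesUsed}. \code{windowedD()}: the
#'   \code{windows} \code{GRanges} with \code{D}, \code{abba},
#'   \code{baba} and \code{nSites} metadata columns.
#' @export
globalD <- function(h, panel, ...) {
  w <- quartetPatterns(h, panel, ...)
  used <- !is.na(w$abba)
  sa <- sum(w$abba[used]); sb <- sum(w$baba[used])
  list(D = dStatistic(sa, sb), sumAbba = sa, sumBaba = sb,
       sitesUsed = sum(used & (w$abba + w$baba) > 0))
}

#' @rdname globalD
#' @export
windowedD <- function(h, panel, windows, ...) {
  w <- quartetPatterns(h, panel, ...)
  hit <- findOverlaps(siteRanges(h), windows)
  sa <- sb <- numeric(length(windows))
  ns <- integer(length(windows))
  qh <- queryHits(hit); sh <- subjectHits(hit)
  ok <- !is.na(w$abba[qh])
  sa <- as.numeric(tapply(w$abba[qh][ok], factor(sh[ok], levels = seq_along(windows)), sum))
  sb <- as.numeric(tapply(w$baba[qh][ok], factor(sh[ok], levels = seq_along(windows)), sum))
  sa[is.na(sa)] <- 0; sb[is.na(sb)] <- 0
  ns <- as.integer(table(factor(sh[ok], levels = seq_along(windows))))
  D <- ifelse(sa + sb > 0, (sa - sb) / (sa + sb), NA_real_)
  out <- windows
  mcols(out)$D <- D
  mcols(out)$abba <- sa
  mcols(out)$baba <- sb
  mcols(out)$nSites <- ns
  out
}

#' Average D over many P1 x P2 individual combinations
#'
#' Mirrors the many-combination design: each combination pairs one P1
#' individual with one P2 individual (donor and outgroup groups are used
#' in full), D is computed per window, averaged over windows within the
#' combination, and the per-combination means are averaged into a grand
#' mean.
#'
#' @param h a polarized [HaplotypeMatrix-class].
#' @param panel a [PopulationPanel-class].
#' @param windows \code{GRanges} of windows.
#' @param p1Samples,p2Samples sample ids to combine (defaults: all P1 and
#'   all P2 samples).
#' @param hapMode see [quartetPatterns()].
#' @return list(perCombo = data.frame(p1, p2, meanD), grandMean).
#' @export
comboMeanD <- function(h, panel, windows, p1Samples = NULL,
                       p2Samples = NULL, hapMode = "frequency") {
  if (is.null(p1Samples)) p1Samples <- roleSamples(panel, "P1")
  if (is.null(p2Samples)) p2Samples <- roleSamples(panel, "P2")
  if (!length(p1Samples) || !length(p2Samples))
    stop("need at least one combination")
  grid <- expand.grid(p1 = p1Samples, p2 = p2Samples,
                      stringsAsFactors = FALSE)
  grid$meanD <- NA_real_
  for (i in seq_len(nrow(grid))) {
    wd <- windowedD(h, panel, windows, p1Samples = grid$p1[i],
                    p2Samples = grid$p2[i], hapMode = hapMode)
    d <- mcols(wd)$D
    if (all(is.na(d))) next
    grid$meanD[i] <- mean(d, na.rm = TRUE)
  }
  if (anyNA(grid$meanD)) {
    warning(sum(is.na(grid$meanD)),
            " combination(s) with all-missing windows excluded")
    grid <- grid[!is.na(grid$meanD), , drop = FALSE]
  }
  list(perCombo = grid, grandMean = mean(grid$meanD))
}

#' Moving-blocks bootstrap percentile CI for a windowed statistic
#'
#' Blocks are the windows themselves: each replicate resamples n window
#' values with replacement (n = number of non-missing windows) and
#' records their mean; the percentile interval of the replicate means is
#' returned. Deterministic for a fixed seed.
#'
#' @param windowValues numeric window statistics (NAs dropped).
#' @param replicates bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional RNG seed.
#' @return Named numeric c(lo, hi).
#' @export
blockBootstrapCi <- function(windowValues, replicates = 1000,
                             level = 0.95, seed = NULL) {
  v <- windowValues[!is.na(windowValues)]
  if (length(v) < 2) stop("need at least two non-missing windows")
  if (!is.null(seed)) set.seed(seed)
  n <- length(v)
  means <- vapply(seq_len(replicates),
                  function(i) mean(v[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  ci <- quantile(means, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  c(lo = ci[1], hi = ci[2])
}
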