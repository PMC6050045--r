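#' Simulate a read-depth track over a CNV and a reference region
#'
#' Per-bin depth is Poisson: mean \code{coverage * (c1 + c2) / 2} inside
#' the CNV region (c1, c2 copies per chromosome) and \code{coverage}
#' elsewhere, averaged over \code{bin} base pairs.
#'
#' @param copies length-2 vector of per-chromosome copy numbers, each in
#'   \{1, 2, 4\}.
#' @param coverage mean haploid-pair read depth (> 0).
#' @param cnvRegion,referenceRegion \code{GRanges}; defaults are the
#'   tandem-CNV segment (Scaffold68 1,790,000-1,805,600) and the non-CNV
#'   normalization region (800,000-1,400,000).
#' @param bin bin width in bp (default 100; use 1 for per-base).
#' @param seed optional RNG seed.
#' @return A [DepthTrack-class] covering both regions.
#' @export
simulateDepth <- function(copies, coverage,
                          cnvRegion = genomicRegion("Scaffold68", 1790000, 1805600),
                          referenceRegion = genomicRegion("Scaffold68", 800000, 1400000),
                          bin = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(copies) != 2L || !all(copies %in% c(1, 2, 4)))
    stop("copies must be a pair of per-chromosome counts in {1, 2, 4}")
  if (!is.numeric(coverage) || coverage <= 0) stop("coverage must be > 0")
  if (as.character(seqnames(cnvRegion)) != as.character(seqnames(referenceRegion)))
    stop("CNV and reference regions must be on the same scaffold")
  binStarts <- function(r) seq(start(r), end(r), by = bin)
  posRef <- binStarts(referenceRegion)
  posCnv <- binStarts(cnvRegion)
  lam <- function(p, r, mean) {
    w <- pmin(p + bin - 1, end(r)) - p + 1  # last bin may be short
    rpois(length(p), mean * w) / w
  }
  dRef <- lam(posRef, referenceRegion, coverage)
  dCnv <- lam(posCnv, cnvRegion, coverage * sum(copies) / 2)
  DepthTrack(as.character(seqnames(cnvRegion)),
             c(posRef, posCnv), c(dRef, dCnv), binWidth = as.integer(bin))
}

#' Simulate a copy-number / wing-pigmentation panel
#'
#' Percent dark wing-shield area follows a saturating logistic in diploid
#' copy number plus Gaussian noise, truncated to [0, 100]. With the
#' default curve and noise, a mixed panel gives a fit comparable to real
#' panels (r-squared about one half).
#'
#' @param copyTotals diploid copy totals, each in \{2,3,4,5,6,8\}.
#' @param curve named numeric: \code{ymin}, \code{ymax} (percent),
#'   \code{k} (steepness per copy), \code{c0} (inflection, copies).
#' @param noiseSd Gaussian noise SD in percent (default 20).
#' @param seed optional RNG seed.
#' @return data.frame(bird, copies, percentArea).
#' @export
simulatePigmentPanel <- function(copyTotals,
                                 curve = c(ymin = 10, ymax = 80, k = 0.8, c0 = 4),
                                 noiseSd = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(copyTotals %in% c(2, 3, 4, 5, 6, 8)))
    stop("copy totals must be attainable diploid totals {2,3,4,5,6,8}")
  mu <- curve[["ymin"]] +
    (curve[["ymax"]] - curve[["ymin"]]) /
      (1 + exp(-curve[["k"]] * (copyTotals - curve[["c0"]])))
  area <- pmin(100, pmax(0, mu + rnorm(length(copyTotals), 0, noiseSd)))
  data.frame(bird = sprintf("bird%03d", seq_along(copyTotals)),
             copies = copyTotals, percentArea = area)
}

#' Simulate paired gDNA/cDNA allele-ratio (ASE) panels
#'
#' Each heterozygous bird gets a gDNA checker:bar signal ratio near 1
#' (amplification bias noise) and a cDNA ratio equal to the gDNA ratio
#' times the class fold-change plus noise, emulating pyrosequencing
#' assays normalized to gDNA.
#'
#' @param copyClasses per-bird checker-chromosome CNV copy class, each in
#'   \{1, 2, 4\}; default mirrors a 12-bird panel (5, 1, 6 birds).
#' @param foldChange named numeric fold-change per class (> 0).
#' @param noiseSd Gaussian noise SD on both ratios (default 0.15).
#' @param seed optional RNG seed.
#' @return data.frame(bird, copyClass, gdnaRatio, cdnaRatio).
#' @export
simulateAse <- function(copyClasses = rep(c(1, 2, 4), c(5, 1, 6)),
                        foldChange = c(`1` = 1.4, `2` = 1.7, `4` = 2.2),
                        noiseSd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(copyClasses %in% c(1, 2, 4)))
    stop("copy classes must be in {1, 2, 4}")
  if (any(foldChange <= 0)) stop("fold changes must be positive")
  if (!all(as.character(unique(copyClasses)) %in% names(foldChange)))
    stop("foldChange must name every class present")
  n <- length(copyClasses)
  g <- pmax(0.05, 1 + rnorm(n, 0, noiseSd))
  cd <- pmax(0.01, g * foldChange[as.character(copyClasses)] +
                   rnorm(n, 0, noiseSd))
  data.frame(bird = sprintf("bird%03d", seq_len(n)),
             copyClass = copyClasses, gdnaRatio = g,
             cdnaRatio = as.numeric(cd))
}
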