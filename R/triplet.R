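#' Sliding-window triplet sequence similarity over informative sites
#'
#' For three haplotypes A, B, C the scan restricts to triplet-informative
#' sites (not all three alleles identical, none missing), slides a window
#' of \code{windowSites} informative sites in steps of \code{stepSites}
#' sites, and reports percent identity (100 x matches / window) for each
#' pair, aligned to the bp coordinate of the window-center site. In an
#' introgressed segment the donor-derived pair rises toward 100 while the
#' within-species pair drops - the similarity "reversal" diagnostic.
#'
#' @param h a [HaplotypeMatrix-class].
#' @param sequences exactly three haplotype labels (A, B, C).
#' @param windowSites window size in informative sites (default 100).
#' @param stepSites step in informative sites (default 1).
#' @return data.frame(center, simAB, simAC, simBC), center in bp.
#' @export
tripletSimilarityScan <- function(h, sequences, windowSites = 100,
                                  stepSites = 1) {
  if (length(sequences) != 3L) stop("supply exactly three haplotypes")
  mask <- informativeSites(h, sequences)
  nInf <- sum(mask)
  if (nInf < windowSites)
    stop("only ", nInf, " informative sites for this triplet; ",
         "reduce windowSites (currently ", windowSites, ") or widen the region")
  a <- alleleMatrix(h)[mask, sequences, drop = FALSE]
  pos <- sitePositions(h)[mask]
  rollPct <- function(match) {
    cs <- c(0, cumsum(match))
    starts <- seq(1L, nInf - windowSites + 1L, by = stepSites)
    100 * (cs[starts + windowSites] - cs[starts]) / windowSites
  }
  starts <- seq(1L, nInf - windowSites + 1L, by = stepSites)
  centers <- pos[starts + windowSites %/% 2L]
  data.frame(center = centers,
             simAB = rollPct(a[, 1] == a[, 2]),
             simAC = rollPct(a[, 1] == a[, 3]),
             simBC = rollPct(a[, 2] == a[, 3]))
}
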