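#' Phased haplotype matrix with its site table
#'
#' Sites-by-haplotypes matrix of biallelic allele codes (0 = reference or
#' ancestral, 1 = alternate or derived, NA = missing), together with a
#' site table held as a \code{GRanges} (one 1-bp range per SNP, with
#' \code{ref} and \code{alt} metadata columns). Haplotype columns are
#' named \code{<sample>_1}/\code{<sample>_2} (sample-major, phase-minor),
#' so a diploid sample contributes two adjacent columns.
#'
#' @slot alleles integer matrix, sites x haplotypes, codes in \{0, 1, NA\}.
#' @slot sites \code{GRanges} of SNP positions (1-based), strictly
#'   increasing within each scaffold, with \code{ref}/\code{alt} columns.
#' @slot phased logical flag; haplotype-level operations require TRUE.
#'
#' @seealso [HaplotypeMatrix()] for the constructor,
#'   [readPhasedVcf()] to build one from a VCF.
#' @export
setClass("HaplotypeMatrix",
  representation(alleles = "matrix", sites = "GRanges", phased = "logical"),
  prototype(alleles = matrix(integer(0), 0, 0), phased = TRUE)
)

setValidity("HaplotypeMatrix", function(object) {
  msg <- NULL
  a <- object@alleles
  if (!is.integer(a) && length(a) > 0L)
    msg <- c(msg, "allele codes must be stored as integers")
  bad <- a[!is.na(a)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    msg <- c(msg, "allele codes must be 0, 1 or NA")
  if (nrow(a) != length(object@sites))
    msg <- c(msg, "number of matrix rows must equal number of sites")
  if (length(object@sites)) {
    bySc <- split(start(object@sites), as.character(seqnames(object@sites)))
    if (!all(vapply(bySc, function(p) all(diff(p) > 0), logical(1))))
      msg <- c(msg, "site positions must be strictly increasing per scaffold")
  }
  if (length(object@phased) != 1L)
    msg <- c(msg, "'phased' must be a single logical")
  if (is.null(msg)) TRUE else msg
})

#' Named sample groups with four-taxon quartet roles
#'
#' Maps sample ids to named groups and groups to the quartet roles used by
#' the ABBA-BABA test: P1 = recipient ancestral (bar), P2 = recipient
#' derived (checker), P3 = donor species (*C. guinea*), O = outgroup
#' (*C. palumbus*). Roles must point at disjoint groups.
#'
#' @slot samples data.frame with columns \code{sample} and \code{group}.
#' @slot roles named character vector mapping role names (any of
#'   "P1","P2","P3","O") to group names.
#' @export
setClass("PopulationPanel",
  representation(samples = "data.frame", roles = "character")
)

setValidity("PopulationPanel", function(object) {
  msg <- NULL
  df <- object@samples
  if (!all(c("sample", "group") %in% names(df)))
    msg <- c(msg, "samples must have 'sample' and 'group' columns")
  else {
    if (anyDuplicated(df$sample))
      msg <- c(msg, "duplicated sample ids")
    r <- object@roles
    if (length(r)) {
      if (!all(names(r) %in% c("P1", "P2", "P3", "O")))
        msg <- c(msg, "role names must be among P1, P2, P3, O")
      if (!all(r %in% df$group))
        msg <- c(msg, "every role must name an existing group")
      if (anyDuplicated(r))
        msg <- c(msg, "quartet roles must map to disjoint groups")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Read-depth track along a scaffold
#'
#' Per-position (or per-bin) read depth, the "gdepth" dialect: one depth
#' value per coordinate. \code{binWidth} records the bin size in bp
#' (1 for per-base tracks); \code{pos} is the 1-based start of each bin.
#'
#' @slot scaffold single scaffold identifier.
#' @slot pos integer vector of sorted 1-based bin starts.
#' @slot depth numeric vector of nonnegative mean depths per bin.
#' @slot binWidth single integer bin size in bp.
#' @export
setClass("DepthTrack",
  representation(scaffold = "character", pos = "integer",
                 depth = "numeric", binWidth = "integer")
)

setValidity("DepthTrack", function(object) {
  msg <- NULL
  if (length(object@scaffold) != 1L) msg <- c(msg, "one scaffold per track")
  if (length(object@pos) != length(object@depth))
    msg <- c(msg, "pos and depth lengths differ")
  if (is.unsorted(object@pos, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  if (any(object@depth < 0, na.rm = TRUE))
    msg <- c(msg, "depth must be nonnegative")
  if (length(object@binWidth) != 1L || object@binWidth < 1L)
    msg <- c(msg, "binWidth must be a single positive integer")
  if (is.null(msg)) TRUE else msg
})

#' Differentiation scan result
#'
#' @slot stats \code{GRanges} of tested sites with \code{stat} and \code{p}
#'   metadata columns.
#' @slot threshold genome-wide significance threshold (Bonferroni
#'   alpha / number of sites tested).
#' @slot nTested number of sites tested.
#' @slot regions \code{GRanges} of merged significant regions.
#' @export
setClass("ScanResult",
  representation(stats = "GRanges", threshold = "numeric",
                 nTested = "integer", regions = "GRanges")
)

#' One-sided extended haplotype homozygosity curve
#'
#' EHH from a focal site outward along one side: the probability that two
#' randomly drawn carrier haplotypes are identical over the span from the
#' focal site to each position. Equals 1 at the focal site and lies in
#' [0, 1] throughout.
#'
#' @slot side "left" or "right".
#' @slot focal focal position (bp).
#' @slot positions site positions, ordered outward from the focal site.
#' @slot ehh EHH value at each position.
#' @slot n number of carrier haplotypes used (after missing-data
#'   exclusions).
#' @export
setClass("EHHCurve",
  representation(side = "character", focal = "numeric",
                 positions = "numeric", ehh = "numeric", n = "integer")
)

setValidity("EHHCurve", function(object) {
  msg <- NULL
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(object@positions) != length(object@ehh))
    msg <- c(msg, "positions and ehh lengths differ")
  if (any(object@ehh < 0 | object@ehh > 1, na.rm = TRUE))
    msg <- c(msg, "EHH values must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Haplotype age estimate from LD decay
#'
#' Point age in generations with a binomial-quantile confidence interval,
#' plus conversions to years at one and two generations per year. The
#' upper bound is \code{Inf} (flagged) when the lower binomial quantile
#' is zero.
#'
#' @slot g point estimate, generations.
#' @slot ci length-2 numeric, generations (lower, upper; upper may be Inf).
#' @slot yearsOneGen,yearsTwoGen point age in years at 1 and 2
#'   generations/year.
#' @slot inputs list echoing r_cM, pr_homoz, n and p used.
#' @export
setClass("AgeEstimate",
  representation(g = "numeric", ci = "numeric",
                 yearsOneGen = "numeric", yearsTwoGen = "numeric",
                 inputs = "list")
)

#' Diploid copy-number estimate and call
#'
#' @slot estimate continuous diploid copy-number estimate (2 x normalized
#'   depth ratio).
#' @slot call nearest attainable diploid total in \{2,3,4,5,6,8\}
#'   (per-chromosome copies 1, 2 or 4); ties round down.
#' @slot cnvRegion,referenceRegion the regions the ratio was computed over.
#' @export
setClass("CopyCall",
  representation(estimate = "numeric", call = "integer",
                 cnvRegion = "GRanges", referenceRegion = "GRanges")
)
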