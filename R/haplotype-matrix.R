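#' Build a HaplotypeMatrix
#'
#' @param alleles sites x haplotypes matrix of 0/1/NA codes. Column names
#'   are haplotype labels (\code{<sample>_1}, \code{<sample>_2}).
#' @param sites \code{GRanges} of SNP positions with \code{ref}/\code{alt}
#'   metadata columns (defaults are filled in if absent).
#' @param phased logical; whether columns are true phased haplotypes.
#' @return A [HaplotypeMatrix-class] object.
#' @examples
#' m <- HaplotypeMatrix(
#'   matrix(c(0L, 1L, 1L, 0L), 2, 2, dimnames = list(NULL, c("a_1", "a_2"))),
#'   GenomicRanges::GRanges("s", IRanges::IRanges(c(10, 20), width = 1)))
#' nSites(m)
#' @export
HaplotypeMatrix <- function(alleles, sites, phased = TRUE) {
  storage.mode(alleles) <- "integer"
  if (is.null(mcols(sites)$ref)) mcols(sites)$ref <- "A"
  if (is.null(mcols(sites)$alt)) mcols(sites)$alt <- "T"
  new("HaplotypeMatrix", alleles = alleles, sites = sites,
      phased = phased)
}

#' @describeIn HaplotypeMatrix allele-code matrix accessor.
#' @param x a \code{HaplotypeMatrix}.
#' @export
alleleMatrix <- function(x) x@alleles

#' @describeIn HaplotypeMatrix site table accessor (\code{GRanges}).
#' @export
siteRanges <- function(x) x@sites

#' @describeIn HaplotypeMatrix number of SNP sites.
#' @export
nSites <- function(x) nrow(x@alleles)

#' @describeIn HaplotypeMatrix number of haplotype columns.
#' @export
nHaplotypes <- function(x) ncol(x@alleles)

#' @describeIn HaplotypeMatrix haplotype column labels.
#' @export
haplotypeNames <- function(x) colnames(x@alleles)

#' @describeIn HaplotypeMatrix site positions (bp) in matrix order.
#' @export
sitePositions <- function(x) start(x@sites)

#' @describeIn HaplotypeMatrix whether genotypes are phased.
#' @export
isPhased <- function(x) x@phased

setMethod("show", "HaplotypeMatrix", function(object) {
  cat("HaplotypeMatrix:", nSites(object), "sites x",
      nHaplotypes(object), "haplotypes",
      if (object@phased) "(phased)\n" else "(unphased)\n")
  sc <- unique(as.character(seqnames(object@sites)))
  if (length(sc))
    cat("  scaffolds:", paste(head(sc, 5), collapse = ", "),
        if (length(sc) > 5) "...\n" else "\n")
})

#' Subset a HaplotypeMatrix by region and/or haplotypes
#'
#' @param x a \code{HaplotypeMatrix}.
#' @param region optional \code{GRanges}; keep sites overlapping it.
#' @param haplotypes optional character vector of haplotype labels (or
#'   a logical/integer column index).
#' @return A \code{HaplotypeMatrix}.
#' @export
subsetHaplotypes <- function(x, region = NULL, haplotypes = NULL) {
  keep <- rep(TRUE, nSites(x))
  if (!is.null(region))
    keep <- overlapsAny(x@sites, region)
  cols <- seq_len(nHaplotypes(x))
  if (!is.null(haplotypes)) {
    if (is.character(haplotypes)) {
      miss <- setdiff(haplotypes, haplotypeNames(x))
      if (length(miss))
        stop("unknown haplotype id(s): ", paste(miss, collapse = ", "))
      cols <- match(haplotypes, haplotypeNames(x))
    } else cols <- haplotypes
  }
  HaplotypeMatrix(x@alleles[keep, cols, drop = FALSE],
                  x@sites[keep], phased = x@phased)
}

#' Haplotype labels for a set of samples
#'
#' Expands sample ids to their phased haplotype column labels
#' (sample-major, phase-minor).
#'
#' @param samples character vector of sample ids.
#' @return Character vector \code{<sample>_1, <sample>_2, ...}.
#' @export
sampleHaplotypes <- function(samples) {
  as.vector(t(outer(samples, 1:2, function(s, p) paste0(s, "_", p))))
}

#' Recode alleles so 1 means "derived", using an outgroup
#'
#' The allele absent (or minor) in the outgroup at each site is taken as
#' derived. Sites where the outgroup is polymorphic, or entirely missing,
#' carry no ancestral information and are dropped (and listed).
#'
#' @param h a \code{HaplotypeMatrix}.
#' @param outgroup character vector of outgroup haplotype labels.
#' @return A list with elements \code{matrix} (derived-coded
#'   \code{HaplotypeMatrix} restricted to polarizable sites) and
#'   \code{dropped} (\code{GRanges} of removed sites).
#' @export
polarizeByOutgroup <- function(h, outgroup) {
  if (length(outgroup) == 0L) stop("outgroup haplotype set is empty")
  miss <- setdiff(outgroup, haplotypeNames(h))
  if (length(miss))
    stop("outgroup haplotypes not in matrix: ", paste(miss, collapse = ", "))
  og <- h@alleles[, outgroup, drop = FALSE]
  n1 <- rowSums(og == 1L, na.rm = TRUE)
  n0 <- rowSums(og == 0L, na.rm = TRUE)
  keep <- (n0 == 0L) != (n1 == 0L)   # outgroup fixed for one allele
  flip <- keep & n0 == 0L            # outgroup fixed alt: alt is ancestral
  a <- h@alleles
  a[flip, ] <- 1L - a[flip, ]
  list(matrix = HaplotypeMatrix(a[keep, , drop = FALSE], h@sites[keep],
                                phased = h@phased),
       dropped = h@sites[!keep])
}

#' Mask of triplet-informative sites
#'
#' A site is informative for a three-sequence comparison when the three
#' alleles are not all identical and none is missing.
#'
#' @param h a \code{HaplotypeMatrix}.
#' @param sequences exactly three haplotype labels.
#' @return Logical vector over sites.
#' @export
informativeSites <- function(h, sequences) {
  if (length(sequences) != 3L)
    stop("informativeSites() needs exactly three sequences")
  a <- h@alleles[, sequences, drop = FALSE]
  ok <- !rowSums(is.na(a))
  ok & !(rowSums(a, na.rm = TRUE) %in% c(0L, 3L))
}
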