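#' Read phased biallelic SNPs from a VCF
#'
#' Retains biallelic SNP records only (indels and multiallelic records are
#' dropped with a message). Genotypes must carry GT; when
#' \code{requirePhased} (the default) any "/"-separated genotype among the
#' retained records is an error naming the offending record.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional \code{GRanges}; keep only overlapping records.
#' @param samples optional character vector of sample ids to keep (error
#'   if any is absent from the file).
#' @param requirePhased logical; set FALSE to accept unphased genotypes
#'   (the matrix is then flagged unphased and haplotype-level analyses
#'   will refuse it).
#' @return A list with \code{matrix} (a [HaplotypeMatrix-class]; columns
#'   sample-major, phase-minor) and \code{sites} (its \code{GRanges} site
#'   table, also available via [siteRanges()]).
#' @export
readPhasedVcf <- function(path, region = NULL, samples = NULL,
                          requirePhased = TRUE) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  nIn <- nrow(vcf)
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  if (any(!snv))
    message("dropped ", sum(!snv), " non-biallelic-SNP record(s)")
  vcf <- vcf[snv, ]
  if (!is.null(region))
    vcf <- vcf[overlapsAny(SummarizedExperiment::rowRanges(vcf), region), ]
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(vcf))
    if (length(miss))
      stop("sample id(s) not in VCF: ", paste(miss, collapse = ", "))
    vcf <- vcf[, samples]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- GRanges(seqnames(rr), ranges(rr))
  mcols(sites)$ref <- as.character(VariantAnnotation::ref(vcf))
  mcols(sites)$alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  names(sites) <- NULL

  ok <- grepl("^[0-9.]+([|/][0-9.]+)?$", gt)
  if (any(!ok))
    stop("malformed GT at record ",
         rownames(gt)[(which(!ok)[1] - 1L) %% nrow(gt) + 1L])
  unph <- grepl("/", gt, fixed = TRUE)
  phased <- !any(unph)
  if (requirePhased && any(unph)) {
    i <- which(unph)[1]
    stop("unphased genotype ", gt[i], " at record ",
         rownames(gt)[(i - 1) %% nrow(gt) + 1],
         " for sample ", colnames(gt)[(i - 1) %/% nrow(gt) + 1],
         "; phased GT (\"|\") required")
  }
  a1 <- sub("[|/].*$", "", gt)
  a2 <- sub("^[0-9.]+[|/]", "", gt)
  code <- function(v) {
    out <- suppressWarnings(as.integer(v))
    out[v == "."] <- NA_integer_
    if (any(!is.na(out) & !out %in% c(0L, 1L)))
      stop("allele codes other than 0/1 in retained biallelic records")
    out
  }
  m1 <- matrix(code(a1), nrow = nrow(gt))
  m2 <- matrix(code(a2), nrow = nrow(gt))
  alleles <- matrix(NA_integer_, nrow(gt), 2L * ncol(gt))
  alleles[, seq(1L, 2L * ncol(gt), by = 2L)] <- m1
  alleles[, seq(2L, 2L * ncol(gt), by = 2L)] <- m2
  colnames(alleles) <- sampleHaplotypes(colnames(gt))
  m <- HaplotypeMatrix(alleles, sites, phased = phased)
  list(matrix = m, sites = sites)
}

#' Write a HaplotypeMatrix as a phased VCF
#'
#' Columns are re-paired into diploid samples (sample-major, phase-minor
#' labels \code{<sample>_1}/\code{<sample>_2}), so the matrix must have an
#' even column count with matching pair labels. Codes round-trip exactly
#' through [readPhasedVcf()].
#'
#' @param h a phased [HaplotypeMatrix-class].
#' @param path output VCF path.
#' @return \code{path}, invisibly.
#' @export
writePhasedVcf <- function(h, path) {
  if (!isPhased(h)) stop("matrix is not phased")
  labs <- haplotypeNames(h)
  if (length(labs) %% 2L)
    stop("odd haplotype count; cannot pair into diploid samples")
  samp <- unique(sub("_[12]$", "", labs))
  if (!identical(labs, sampleHaplotypes(samp)))
    stop("haplotype labels are not sample-major/phase-minor pairs")
  a <- h@alleles
  ch <- matrix(as.character(a), nrow(a), ncol(a))
  ch[is.na(a)] <- "."
  i1 <- seq(1L, ncol(a), by = 2L)
  gt <- matrix(paste(ch[, i1], ch[, i1 + 1L], sep = "|"),
               nrow = nrow(a), dimnames = list(NULL, samp))
  sites <- h@sites
  ids <- paste0(as.character(seqnames(sites)), ":", start(sites))
  rr <- GRanges(seqnames(sites), ranges(sites))
  names(rr) <- ids
  rownames(gt) <- ids
  vcfObj <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_along(samp),
                                   row.names = samp),
    fixed = S4Vectors::DataFrame(
      REF = DNAStringSet(mcols(sites)$ref),
      ALT = do.call(DNAStringSetList, as.list(mcols(sites)$alt)),
      QUAL = NA_real_, FILTER = "PASS"),
    geno = S4Vectors::SimpleList(GT = gt), collapsed = TRUE)
  hdr <- VariantAnnotation::VCFHeader(samples = samp)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  VariantAnnotation::header(vcfObj) <- hdr
  VariantAnnotation::writeVcf(vcfObj, path)
  invisible(path)
}

#' Construct / read / write read-depth tracks
#'
#' The on-disk format is the per-position "gdepth" dialect: a
#' tab-separated table with header \code{scaffold, pos, depth}.
#'
#' @param scaffold scaffold identifier.
#' @param pos 1-based positions (bin starts).
#' @param depth mean read depth per bin.
#' @param binWidth bin size in bp (1 = per-base).
#' @return A [DepthTrack-class].
#' @export
DepthTrack <- function(scaffold, pos, depth, binWidth = 1L) {
  o <- order(pos)
  new("DepthTrack", scaffold = scaffold, pos = as.integer(pos)[o],
      depth = as.numeric(depth)[o], binWidth = as.integer(binWidth))
}

#' @rdname DepthTrack
#' @param path depth TSV file.
#' @export
readDepthTrack <- function(path, binWidth = 1L) {
  df <- read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("scaffold", "pos", "depth") %in% names(df)))
  sc <- unique(df$scaffold)
  if (length(sc) != 1L) stop("one scaffold per depth track")
  DepthTrack(sc, df$pos, df$depth, binWidth = binWidth)
}

#' @rdname DepthTrack
#' @param track a \code{DepthTrack}.
#' @export
writeDepthTrack <- function(track, path) {
  write.table(
    data.frame(scaffold = track@scaffold, pos = track@pos,
               depth = track@depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn DepthTrack depth values.
#' @export
depthValues <- function(track) track@depth

#' @describeIn DepthTrack bin start positions.
#' @export
depthPositions <- function(track) track@pos

setMethod("show", "DepthTrack", function(object) {
  cat("DepthTrack on", object@scaffold, ":", length(object@pos),
      "bins of", object@binWidth, "bp; mean depth",
      round(mean(object@depth), 2), "\n")
})
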