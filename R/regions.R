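#' Construct a genomic region
#'
#' Regions are plain \code{GRanges} with 1-based inclusive coordinates
#' (VCF convention). \code{regionLength()} is inclusive arithmetic:
#' end - start + 1.
#'
#' @param scaffold scaffold identifier.
#' @param start,end 1-based inclusive bounds, start <= end.
#' @return A length-1 \code{GRanges}.
#' @examples
#' r <- genomicRegion("Scaffold68", 1702691, 1805600)
#' regionLength(r)  # 102910 by inclusive arithmetic
#' @export
genomicRegion <- function(scaffold, start, end) {
  if (length(scaffold) != 1L || length(start) != 1L || length(end) != 1L)
    stop("genomicRegion() builds a single region")
  if (!is.finite(start) || !is.finite(end) || start > end)
    stop("region start must be <= end")
  if (start < 1) stop("coordinates are 1-based; start must be >= 1")
  GRanges(scaffold, IRanges(start = as.numeric(start), end = as.numeric(end)))
}

#' @rdname genomicRegion
#' @param region a \code{GRanges}.
#' @export
regionLength <- function(region) {
  stopifnot(is(region, "GRanges"))
  width(region)
}

#' Tile a region into (possibly overlapping) windows
#'
#' Windows are produced on a half-open internal grid and reported 1-based
#' inclusive; the last window is truncated at the region end and flagged
#' \code{partial} when shorter than \code{size}.
#'
#' @param region length-1 \code{GRanges}.
#' @param size window size in bp (> 0).
#' @param step step between window starts in bp (> 0); equal to
#'   \code{size} for non-overlapping tiling.
#' @return \code{GRanges} of windows with a logical \code{partial} column.
#' @examples
#' w <- makeWindows(genomicRegion("s", 1, 200000), size = 100000, step = 50000)
#' length(w)  # 3 overlapping windows
#' @export
makeWindows <- function(region, size, step = size) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  if (!is.finite(size) || size <= 0) stop("window size must be > 0")
  if (!is.finite(step) || step <= 0) stop("window step must be > 0")
  w <- slidingWindows(region, width = as.integer(size),
                      step = as.integer(step))[[1]]
  mcols(w)$partial <- width(w) < size
  w
}

#' Export regions as BED text
#'
#' Converts 1-based inclusive regions to BED's 0-based half-open
#' convention.
#'
#' @param regions \code{GRanges}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  stopifnot(is(regions, "GRanges"))
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
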