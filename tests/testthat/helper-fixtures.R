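suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# Small haplotype matrix from a plain 0/1/NA matrix and positions.
hapFix <- function(m, pos = seq_len(nrow(m)) * 10, scaffold = "s",
                   labels = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (is.null(labels))
    labels <- sampleHaplotypes(sprintf("s%02d", seq_len(ncol(m) / 2)))
  colnames(m) <- labels
  HaplotypeMatrix(m, GRanges(scaffold, IRanges(pos, width = 1)))
}

# Write a minimal VCF text file; gts is a sites x samples character matrix.
writeVcfFixture <- function(path, pos, ref, alt, gts, scaffold = "Scaffold68") {
  samples <- colnames(gts)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  posChr <- format(pos, scientific = FALSE, trim = TRUE)
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(scaffold, posChr[i], ".", ref[i], alt[i], ".",
                              "PASS", ".", "GT", gts[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Brute-force pairwise difference count (site loop, pairwise deletion).
bruteDiff <- function(a, b) {
  n <- 0L
  for (i in seq_along(a)) {
    if (!is.na(a[i]) && !is.na(b[i]) && a[i] != b[i]) n <- n + 1L
  }
  n
}

# Brute-force EHH: probability a random carrier pair is identical over
# the span from focal out to each site (complete-data matrices).
bruteEhh <- function(mat, spanRows) {
  n <- ncol(mat)
  same <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (all(mat[spanRows, i] == mat[spanRows, j])) same <- same + 1L
  }
  same / (n * (n - 1) / 2)
}

# Brute-force single-haplotype ABBA/BABA counting over a matrix with
# one column per role (values 0/1).
bruteDCount <- function(p1, p2, p3, pO) {
  abba <- sum(p1 == 0 & p2 == 1 & p3 == 1 & pO == 0)
  baba <- sum(p1 == 1 & p2 == 0 & p3 == 1 & pO == 0)
  c(abba = abba, baba = baba)
}

# Standard quartet panel for simulator outputs.
simPanelOutgroup <- function(sim)
  sampleHaplotypes(roleSamples(sim$panel, "O"))
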