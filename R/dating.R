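#' Pairwise SNP difference counts between haplotypes
#'
#' Counts sites with unequal non-missing alleles for each listed pair
#' (site-wise pairwise deletion), summarized as group mean and SD, plus
#' the total number of segregating sites K in the region across all
#' haplotypes involved. Similarity is reported two ways: the mean of
#' per-pair similarities 100 * (1 - S_i / K) and the similarity of the
#' mean count 100 * (1 - mean(S) / K); the two differ in the second
#' decimal for real panels.
#'
#' @param h a [HaplotypeMatrix-class].
#' @param pairs two-column matrix or data.frame of haplotype labels.
#' @param region optional \code{GRanges} restriction.
#' @return list(pairs = data.frame(a, b, count), mean, sd, K,
#'   meanPairSimilarity, similarityOfMean).
#' @seealso [crossPairs()] and [withinPairs()] to enumerate pairs,
#'   [similarityPercent()].
#' @export
pairwiseSnpCounts <- function(h, pairs, region = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!nrow(pairs)) stop("empty pair list")
  names(pairs)[1:2] <- c("a", "b")
  hh <- if (is.null(region)) h else subsetHaplotypes(h, region = region)
  labs <- unique(c(pairs$a, pairs$b))
  a <- alleleMatrix(hh)[, labs, drop = FALSE]
  seg <- rowSums(a == 1L, na.rm = TRUE) > 0 &
         rowSums(a == 0L, na.rm = TRUE) > 0
  K <- sum(seg)
  cnt <- mapply(function(x, y) {
    ok <- !is.na(a[, x]) & !is.na(a[, y])
    sum(a[ok, x] != a[ok, y])
  }, pairs$a, pairs$b)
  pairs$count <- as.integer(cnt)
  m <- mean(pairs$count)
  list(pairs = pairs, mean = m, sd = sd(pairs$count), K = K,
       meanPairSimilarity = if (K > 0) mean(100 * (1 - pairs$count / K)) else NA_real_,
       similarityOfMean = if (K > 0) 100 * (1 - m / K) else NA_real_)
}

#' @rdname pairwiseSnpCounts
#' @param labelsA,labelsB haplotype label sets; \code{crossPairs} forms
#'   all between-set pairs, \code{withinPairs} all unordered within-set
#'   pairs.
#' @export
crossPairs <- function(labelsA, labelsB)
  expand.grid(a = labelsA, b = labelsB, stringsAsFactors = FALSE)

#' @rdname pairwiseSnpCounts
#' @param labels haplotype labels.
#' @export
withinPairs <- function(labels) {
  if (length(labels) < 2) stop("need at least two haplotypes")
  idx <- utils::combn(length(labels), 2)
  data.frame(a = labels[idx[1, ]], b = labels[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Pairwise differences between two variant lists
#'
#' For two per-individual variant lists (position -> alternate allele,
#' e.g. from de novo assemblies compared against a common reference) the
#' difference count is |A-only positions| + |B-only positions| + shared
#' positions whose alternate alleles differ; shared positions with the
#' same alternate allele do not differ between the two individuals.
#'
#' @param listA,listB data.frames with columns \code{pos} and \code{alt}
#'   (or named character vectors, names = positions).
#' @return Integer difference count.
#' @export
variantListPairwiseDiffs <- function(listA, listB) {
  norm <- function(v) {
    if (is.character(v) && !is.null(names(v)))
      v <- data.frame(pos = as.numeric(names(v)), alt = unname(v))
    v <- as.data.frame(v)
    if (!all(c("pos", "alt") %in% names(v)))
      stop("variant lists need 'pos' and 'alt'")
    if (anyNA(v$pos) || anyNA(v$alt) || anyDuplicated(v$pos))
      stop("malformed variant entry (NA or duplicated position)")
    v
  }
  A <- norm(listA); B <- norm(listB)
  aOnly <- sum(!A$pos %in% B$pos)
  bOnly <- sum(!B$pos %in% A$pos)
  shared <- intersect(A$pos, B$pos)
  diffAlt <- sum(A$alt[match(shared, A$pos)] != B$alt[match(shared, B$pos)])
  as.integer(aOnly + bOnly + diffAlt)
}

#' Coalescent SNP-count dating
#'
#' \code{coalescentTime()} inverts the expectation of pairwise
#' differences: T = S / (2 * mu * L) generations.
#' \code{expectedSnps()} is the forward direction: 2 * mu * L * T.
#'
#' @param S observed SNP differences (>= 0).
#' @param mu mutation rate per site per generation (> 0).
#' @param L region length in bp (> 0); supply the published region-size
#'   constant explicitly (e.g. 102909 for the minimal checker haplotype).
#' @return Generations (coalescentTime) or expected count (expectedSnps).
#' @examples
#' coalescentTime(26, 1.42e-9, 102909)   # ~88963 generations (~89 KY)
#' expectedSnps(4e6, 1.42e-9, 102909)    # 1169.05
#' @export
coalescentTime <- function(S, mu, L) {
  if (mu <= 0 || L <= 0) stop("mu and L must be positive")
  if (any(S < 0)) stop("SNP count must be nonnegative")
  S / (2 * mu * L)
}

#' @rdname coalescentTime
#' @param T divergence time in generations (>= 0).
#' @export
expectedSnps <- function(T, mu, L) {
  if (mu <= 0 || L <= 0) stop("mu and L must be positive")
  if (any(T < 0)) stop("negative divergence time")
  2 * mu * L * T
}

#' Percent sequence similarity at segregating sites
#'
#' @param S pairwise difference count (0 <= S <= K).
#' @param K total segregating sites in the region (> 0).
#' @return 100 * (1 - S / K).
#' @examples
#' similarityPercent(26, 4261)  # 99.39
#' @export
similarityPercent <- function(S, K) {
  if (K <= 0) stop("K must be positive")
  if (any(S < 0 | S > K)) stop("S must satisfy 0 <= S <= K")
  100 * (1 - S / K)
}

#' Test observed pairwise counts against an expected constant
#'
#' One-sample t of the observed per-pair difference counts against the
#' coalescent expectation (a constant, hence no second-sample variance).
#' Degenerate zero-variance samples are handled explicitly: t = 0 and
#' p = 1 when every observation equals the expectation.
#'
#' @param observed numeric vector of per-pair counts (length >= 2).
#' @param expected expected count (scalar).
#' @return list(t, df, p).
#' @export
divergenceVsExpectationTest <- function(observed, expected) {
  n <- length(observed)
  if (n < 2) stop("need at least two observed counts")
  s <- sd(observed)
  m <- mean(observed)
  if (s == 0) {
    t <- if (m == expected) 0 else sign(m - expected) * Inf
  } else {
    t <- (m - expected) / (s / sqrt(n))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1, p = p)
}

#' Mitochondrial divergence-rate dating
#'
#' @param d percent sequence divergence between two species.
#' @param rate divergence rate in percent per million years (> 0), e.g.
#'   1.96 for columbid cytochrome b.
#' @return Divergence time in million years.
#' @examples
#' cytbDivergenceTime(8.0, 1.96)  # ~4.08 MY
#' @export
cytbDivergenceTime <- function(d, rate) {
  if (rate <= 0) stop("rate must be positive")
  if (any(d < 0)) stop("divergence must be nonnegative")
  d / rate
}

#' Generations to years
#'
#' @param g age in generations (>= 0).
#' @param generationsPerYear generations per year (> 0; pigeons breed at
#'   one to two generations per year).
#' @return Years.
#' @examples
#' generationsToYears(857, 2)  # 428.5, i.e. ~429 years
#' @export
generationsToYears <- function(g, generationsPerYear) {
  if (!is.numeric(generationsPerYear) || generationsPerYear <= 0)
    stop("invalid generations-per-year rate")
  if (any(g < 0)) stop("age must be nonnegative")
  g / generationsPerYear
}
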