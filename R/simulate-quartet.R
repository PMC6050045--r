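#' Configuration for the quartet introgression simulator
#'
#' Defines the study system the generator emulates: a recipient pigeon
#' population in which a derived subgroup (P2, "checker") carries a
#' haplotype introgressed from a donor species (P3) that diverged several
#' million generations ago, with a deeper outgroup (O). The pulse is
#' recent (\code{TIntro} generations ago) and affects only the target
#' region; all other loci are neutral background.
#'
#' @param mu mutation rate per site per generation (default 1.42e-9, the
#'   pigeon rate used throughout the dating analyses).
#' @param rho recombination rate per site per generation (default
#'   1.65e-8, about 1.65 cM/Mb).
#' @param region target region \code{GRanges} (default Scaffold68
#'   1,702,691-1,805,600, the minimal checker haplotype).
#' @param focal focal position for haplotype decay (default 1,751,072).
#' @param flank bp of simulated flank on each side of the region
#'   (needed for EHH decay; default 0).
#' @param TIntro generations since the introgression pulse (default 857).
#' @param fIntro probability that a P2 haplotype carries the introgressed
#'   segment (0..1; default 1).
#' @param TSplitDonor recipient-donor split, generations (default 4.5e6,
#'   i.e. the 4-5 MY interspecies divergence at one generation/year).
#' @param TOut outgroup split, generations (> TSplitDonor; default 7e6).
#' @param Ne named effective sizes (haploid-pair units) for
#'   \code{recipient}, \code{donor}, \code{outgroup}, \code{ancestral}.
#' @param nBar,nChecker,nDonor,nOut haplotype counts per group (even, so
#'   haplotypes pair into diploid samples).
#' @param nBackgroundLoci,backgroundLocusBp number and size of unlinked
#'   neutral background loci (the "genome-wide" windows).
#' @param chunkBp size of independently simulated chunks along the focal
#'   scaffold (free recombination between chunks, none within).
#' @param seed RNG seed (base R Mersenne-Twister via \code{set.seed}).
#' @return A validated list of class \code{QuartetSimConfig}.
#' @export
quartetSimConfig <- function(mu = 1.42e-9, rho = 1.65e-8,
                             region = genomicRegion("Scaffold68", 1702691, 1805600),
                             focal = 1751072, flank = 0,
                             TIntro = 857, fIntro = 1,
                             TSplitDonor = 4.5e6, TOut = 7e6,
                             Ne = c(recipient = 2e6, donor = 6.5e5,
                                    outgroup = 1e6, ancestral = 2e6),
                             nBar = 20, nChecker = 22, nDonor = 2, nOut = 2,
                             nBackgroundLoci = 20, backgroundLocusBp = 50000,
                             chunkBp = 20000, seed = NULL) {
  if (fIntro < 0 || fIntro > 1) stop("fIntro must lie in [0, 1]")
  if (!(TIntro < TSplitDonor && TSplitDonor < TOut))
    stop("event times must satisfy TIntro < TSplitDonor < TOut")
  if (mu < 0 || rho < 0) stop("rates must be nonnegative")
  if (any(Ne <= 0)) stop("effective sizes must be positive")
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  if (focal < start(region) || focal > end(region))
    stop("focal position must lie inside the target region")
  counts <- c(nBar = nBar, nChecker = nChecker, nDonor = nDonor, nOut = nOut)
  if (any(counts < 2) || any(counts %% 2 != 0))
    stop("haplotype counts must be even and >= 2")
  cfg <- list(mu = mu, rho = rho, region = region, focal = focal,
              flank = flank, TIntro = TIntro, fIntro = fIntro,
              TSplitDonor = TSplitDonor, TOut = TOut, Ne = Ne,
              nBar = nBar, nChecker = nChecker, nDonor = nDonor,
              nOut = nOut, nBackgroundLoci = nBackgroundLoci,
              backgroundLocusBp = backgroundLocusBp,
              chunkBp = chunkBp, seed = seed)
  class(cfg) <- "QuartetSimConfig"
  cfg
}

# Structured coalescent for one non-recombining locus.
#
# Tips enter demes R (recipient), D (donor), O (outgroup) at time 0;
# an optional founder tip enters D at TIntro (the ancestral copy of the
# introgressed haplotype, sampled at the pulse). Demography: D merges
# into R at TSplitDonor, O at TOut; the merged deme uses the ancestral
# Ne. Returns derived-allele matrix rows sorted by position (1..L).
.simQuartetLocus <- function(nR, nD, nO, founder, L, cfg) {
  nTips <- nR + nD + nO + as.integer(founder)
  deme <- c(rep("R", nR), rep("D", nD), rep("O", nO))
  leafset <- as.list(seq_len(nR + nD + nO))
  birth <- rep(0, nR + nD + nO)
  pendingFounder <- founder
  founderTip <- if (founder) nTips else NA_integer_

  NeOf <- function(d, t) {
    if (t >= cfg$TSplitDonor) return(cfg$Ne[["ancestral"]])
    switch(d, R = cfg$Ne[["recipient"]], D = cfg$Ne[["donor"]],
           O = cfg$Ne[["outgroup"]])
  }
  events <- sort(unique(c(if (founder) cfg$TIntro, cfg$TSplitDonor, cfg$TOut)))
  edgeLeaves <- vector("list", 2L * nTips)
  edgeLen <- numeric(2L * nTips)
  nEdge <- 0L
  t <- 0
  repeat {
    if (length(leafset) <= 1L && !pendingFounder) break
    demes <- unique(deme)
    rate <- vapply(demes, function(d) {
      k <- sum(deme == d)
      k * (k - 1) / 2 / (2 * NeOf(d, t))
    }, numeric(1))
    total <- sum(rate)
    dt <- if (total > 0) rexp(1L, total) else Inf
    nextEv <- events[events > t][1]
    if (!is.na(nextEv) && t + dt >= nextEv) {
      t <- nextEv
      if (pendingFounder && t == cfg$TIntro) {
        leafset <- c(leafset, list(founderTip))
        deme <- c(deme, "D")
        birth <- c(birth, cfg$TIntro)
        pendingFounder <- FALSE
      }
      if (t == cfg$TSplitDonor) deme[deme == "D"] <- "R"
      if (t == cfg$TOut) deme[deme == "O"] <- "R"
      next
    }
    t <- t + dt
    d <- sample(demes, 1L, prob = rate)
    idx <- which(deme == d)
    pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
    for (i in pair) {
      nEdge <- nEdge + 1L
      if (nEdge > length(edgeLen)) {  # grow storage
        edgeLeaves <- c(edgeLeaves, vector("list", length(edgeLeaves)))
        edgeLen <- c(edgeLen, numeric(length(edgeLen)))
      }
      edgeLeaves[[nEdge]] <- leafset[[i]]
      edgeLen[nEdge] <- t - birth[i]
    }
    merged <- sort(c(leafset[[pair[1]]], leafset[[pair[2]]]))
    leafset[[pair[1]]] <- merged
    birth[pair[1]] <- t
    leafset <- leafset[-pair[2]]
    deme <- deme[-pair[2]]
    birth <- birth[-pair[2]]
  }
  edgeLeaves <- edgeLeaves[seq_len(nEdge)]
  edgeLen <- edgeLen[seq_len(nEdge)]
  nMut <- rpois(1L, cfg$mu * L * sum(edgeLen))
  nMut <- min(nMut, L)  # infinite-sites cap
  if (nMut == 0L)
    return(list(pos = integer(0),
                M = matrix(0L, 0L, nTips)))
  br <- sample.int(nEdge, nMut, replace = TRUE, prob = edgeLen)
  pos <- sort(sample.int(L, nMut))
  M <- matrix(0L, nMut, nTips)
  for (b in unique(br)) {          # fill rows branch-wise (vectorized)
    rows <- which(br == b)
    M[rows, edgeLeaves[[b]]] <- 1L
  }
  list(pos = pos, M = M)
}

#' Simulate a quartet dataset with a dated introgression pulse
#'
#' Deep genealogies are drawn from a structured coalescent (recipient,
#' donor, outgroup demes; donor merges at \code{TSplitDonor}, outgroup at
#' \code{TOut}) independently per chunk of the focal scaffold and per
#' background locus. The recent pulse is modelled as a star genealogy:
#' every carrier haplotype in P2 descends from a single donor haplotype
#' sampled \code{TIntro} generations ago, keeps it intact out to
#' exponential recombination breakpoints on each side of the focal site
#' (rate \code{rho * TIntro} per bp), carries Poisson(\code{mu} x span x
#' \code{TIntro}) private new mutations, and reverts to an independent
#' recipient background beyond the breakpoints.
#'
#' @param cfg a [quartetSimConfig()].
#' @return A list with elements \code{haplotypes}
#'   ([HaplotypeMatrix-class], ancestral-coded: 1 = derived),
#'   \code{panel} ([PopulationPanel-class] with roles P1=bar, P2=checker,
#'   P3=guinea, O=palumbus), \code{truth} (introgressed tract
#'   \code{GRanges} per carrier haplotype, their intersection
#'   \code{shared}, carrier labels, \code{TIntro}, \code{focal}), and
#'   \code{config}.
#' @examples
#' sim <- simulateQuartet(quartetSimConfig(
#'   nBackgroundLoci = 2, chunkBp = 50000, seed = 1))
#' sim$haplotypes
#' @export
simulateQuartet <- function(cfg) {
  stopifnot(inherits(cfg, "QuartetSimConfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sampNames <- c(sprintf("bar%02d", seq_len(cfg$nBar / 2)),
                 sprintf("chk%02d", seq_len(cfg$nChecker / 2)),
                 sprintf("gui%02d", seq_len(cfg$nDonor / 2)),
                 sprintf("out%02d", seq_len(cfg$nOut / 2)))
  hapNames <- sampleHaplotypes(sampNames)
  nR <- cfg$nBar + cfg$nChecker
  nTot <- nR + cfg$nDonor + cfg$nOut
  chkCols <- cfg$nBar + seq_len(cfg$nChecker)
  chkLabels <- hapNames[chkCols]

  ext <- genomicRegion(as.character(seqnames(cfg$region)),
                       max(1, start(cfg$region) - cfg$flank),
                       end(cfg$region) + cfg$flank)
  scaffold <- as.character(seqnames(ext))

  # carrier status and recombination breakpoints for the pulse
  carrier <- if (cfg$fIntro > 0)
    runif(cfg$nChecker) < cfg$fIntro else rep(FALSE, cfg$nChecker)
  anyIntro <- any(carrier)
  bl <- br <- rep(NA_real_, cfg$nChecker)
  if (anyIntro) {
    rate <- cfg$rho * cfg$TIntro
    bl[carrier] <- pmax(start(ext),
                        cfg$focal - floor(rexp(sum(carrier), rate)))
    br[carrier] <- pmin(end(ext),
                        cfg$focal + floor(rexp(sum(carrier), rate)))
  }

  # focal scaffold, simulated in independent chunks
  starts <- seq(start(ext), end(ext), by = cfg$chunkBp)
  ends <- pmin(starts + cfg$chunkBp - 1, end(ext))
  posAll <- list(); matAll <- list(); scAll <- list()
  for (ci in seq_along(starts)) {
    L <- ends[ci] - starts[ci] + 1
    loc <- .simQuartetLocus(nR, cfg$nDonor, cfg$nOut,
                            founder = anyIntro, L = L, cfg = cfg)
    if (!nrow(loc$M)) next
    gpos <- starts[ci] + loc$pos - 1
    M <- loc$M[, seq_len(nTot), drop = FALSE]
    if (anyIntro) {
      fA <- loc$M[, nTot + 1L]
      for (j in which(carrier)) {
        inTract <- gpos >= bl[j] & gpos <= br[j]
        M[inTract, chkCols[j]] <- fA[inTract]
      }
    }
    posAll[[length(posAll) + 1L]] <- gpos
    matAll[[length(matAll) + 1L]] <- M
    scAll[[length(scAll) + 1L]] <- rep(scaffold, length(gpos))
  }

  # private mutations on carrier lineages since the pulse (star branches)
  if (anyIntro) {
    for (j in which(carrier)) {
      span <- br[j] - bl[j] + 1
      k <- rpois(1L, cfg$mu * cfg$TIntro * span)
      if (k > 0) {
        p <- bl[j] + sample.int(span, k) - 1
        M <- matrix(0L, k, nTot)
        M[, chkCols[j]] <- 1L
        posAll[[length(posAll) + 1L]] <- p
        matAll[[length(matAll) + 1L]] <- M
        scAll[[length(scAll) + 1L]] <- rep(scaffold, k)
      }
    }
  }

  # unlinked neutral background loci
  for (b in seq_len(cfg$nBackgroundLoci)) {
    loc <- .simQuartetLocus(nR, cfg$nDonor, cfg$nOut, founder = FALSE,
                            L = cfg$backgroundLocusBp, cfg = cfg)
    if (!nrow(loc$M)) next
    posAll[[length(posAll) + 1L]] <- loc$pos
    matAll[[length(matAll) + 1L]] <- loc$M
    scAll[[length(scAll) + 1L]] <- rep(sprintf("bg%02d", b), length(loc$pos))
  }

  pos <- unlist(posAll); sc <- unlist(scAll)
  M <- do.call(rbind, matAll)
  # drop duplicated positions (infinite-sites collisions between the
  # coalescent and the pulse overlay) and monomorphic rows
  key <- paste(sc, pos)
  keep <- !duplicated(key)
  rs <- rowSums(M)
  keep <- keep & rs > 0L & rs < nTot
  pos <- pos[keep]; sc <- sc[keep]; M <- M[keep, , drop = FALSE]
  o <- order(sc, pos)
  pos <- pos[o]; sc <- sc[o]; M <- M[o, , drop = FALSE]
  colnames(M) <- hapNames

  bases <- c("A", "C", "G", "T")
  refIdx <- sample.int(4L, length(pos), replace = TRUE)
  altIdx <- 1L + (refIdx + sample.int(3L, length(pos), replace = TRUE) - 1L) %% 4L
  sites <- GRanges(sc, IRanges(pos, width = 1),
                   ref = bases[refIdx], alt = bases[altIdx])
  h <- HaplotypeMatrix(M, sites, phased = TRUE)

  panel <- PopulationPanel(
    groups = list(bar = grep("^bar", sampNames, value = TRUE),
                  checker = grep("^chk", sampNames, value = TRUE),
                  guinea = grep("^gui", sampNames, value = TRUE),
                  palumbus = grep("^out", sampNames, value = TRUE)),
    roles = c(P1 = "bar", P2 = "checker", P3 = "guinea", O = "palumbus"))

  tracts <- GRanges()
  shared <- NULL
  if (anyIntro) {
    tracts <- GRanges(scaffold, IRanges(bl[carrier], br[carrier]),
                      haplotype = chkLabels[carrier])
    shared <- GRanges(scaffold,
                      IRanges(max(bl[carrier]), min(br[carrier])))
  }
  truth <- list(tracts = tracts, shared = shared,
                carriers = chkLabels[carrier], TIntro = cfg$TIntro,
                fIntro = cfg$fIntro, focal = cfg$focal)
  list(haplotypes = h, panel = panel, truth = truth, config = cfg)
}
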