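#' Diploid copy number from normalized read depth
#'
#' Mean depth over the CNV region divided by mean depth over a non-CNV
#' reference region, times two (diploid normalization). The call is the
#' nearest attainable diploid total in \{2, 3, 4, 5, 6, 8\} (sums of
#' per-chromosome copies 1, 2, 4); exact ties round down. The estimate
#' is invariant to rescaling the whole track.
#'
#' @param track a [DepthTrack-class] covering both regions.
#' @param cnvRegion,referenceRegion \code{GRanges}.
#' @return A [CopyCall-class].
#' @export
estimateCopyNumber <- function(track,
                               cnvRegion = genomicRegion("Scaffold68", 1790000, 1805600),
                               referenceRegion = genomicRegion("Scaffold68", 800000, 1400000)) {
  inRegion <- function(r) {
    if (as.character(seqnames(r)) != track@scaffold)
      return(logical(length(track@pos)))
    track@pos >= start(r) & track@pos <= end(r)
  }
  iC <- inRegion(cnvRegion); iR <- inRegion(referenceRegion)
  if (!any(iC)) stop("depth track does not cover the CNV region")
  if (!any(iR)) stop("depth track does not cover the reference region")
  mRef <- mean(track@depth[iR])
  if (mRef == 0) stop("reference region has zero mean depth")
  est <- 2 * mean(track@depth[iC]) / mRef
  attainable <- c(2L, 3L, 4L, 5L, 6L, 8L)
  d <- abs(est - attainable)
  call <- attainable[which(d == min(d))[1]]  # tie -> round down
  new("CopyCall", estimate = est, call = call,
      cnvRegion = cnvRegion, referenceRegion = referenceRegion)
}

#' @describeIn estimateCopyNumber continuous estimate accessor.
#' @param x a \code{CopyCall}.
#' @export
copyEstimate <- function(x) x@estimate

#' @describeIn estimateCopyNumber integer call accessor.
#' @export
copyCall <- function(x) x@call

setMethod("show", "CopyCall", function(object) {
  cat(sprintf("CopyCall: estimate %.2f diploid copies -> call %d\n",
              object@estimate, object@call))
})

#' Pairwise rank-sum tests of copy number across phenotype categories
#'
#' Wilcoxon rank-sum p-values for every category pair, adjusted across
#' pairs by Benjamini-Hochberg (the "fdr" method).
#'
#' @param copies numeric copy numbers (or any per-bird quantity).
#' @param phenotype parallel factor of phenotype categories (>= 2
#'   nonempty levels).
#' @return data.frame(group1, group2, p, pAdj).
#' @export
copyPhenotypeTest <- function(copies, phenotype) {
  phenotype <- factor(phenotype)
  phenotype <- droplevels(phenotype)
  if (nlevels(phenotype) < 2) stop("need at least two phenotype groups")
  if (any(table(phenotype) == 0)) stop("empty phenotype group")
  lev <- levels(phenotype)
  idx <- utils::combn(length(lev), 2)
  p <- apply(idx, 2, function(ij) {
    suppressWarnings(wilcox.test(copies[phenotype == lev[ij[1]]],
                                 copies[phenotype == lev[ij[2]]],
                                 exact = FALSE))$p.value
  })
  data.frame(group1 = lev[idx[1, ]], group2 = lev[idx[2, ]],
             p = p, pAdj = p.adjust(p, method = "BH"))
}

#' Regression of percent pigmented area on copy number
#'
#' Least-squares fit of a saturating logistic (default) or straight line.
#' r-squared is 1 - SSres / SStot (0 for a constant response).
#'
#' @param area percent dark wing-shield area, in [0, 100].
#' @param copies diploid copy numbers (must vary).
#' @param model "logistic" (nonlinear least squares) or "linear".
#' @return list(model, fit, rSquared, fitted).
#' @export
pigmentCopyRegression <- function(area, copies,
                                  model = c("logistic", "linear")) {
  model <- match.arg(model)
  if (length(area) < 3) stop("need at least three points")
  if (var(copies) == 0) stop("copy numbers do not vary")
  sstot <- sum((area - mean(area))^2)
  if (sstot == 0)
    return(list(model = model, fit = NULL, rSquared = 0,
                fitted = rep(mean(area), length(area))))
  if (model == "linear") {
    fit <- lm(area ~ copies)
    fv <- fitted(fit)
  } else {
    df <- data.frame(area = area, copies = copies)
    fit <- minpack.lm::nlsLM(
      area ~ ymin + (ymax - ymin) / (1 + exp(-k * (copies - c0))),
      data = df,
      start = list(ymin = min(area), ymax = max(area), k = 1,
                   c0 = mean(copies)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    fv <- fitted(fit)
  }
  list(model = model, fit = fit,
       rSquared = 1 - sum((area - fv)^2) / sstot, fitted = as.numeric(fv))
}

#' Relative expression from qPCR Ct values
#'
#' Technical replicates are averaged first; relative expression is
#' 2^-(mean Ct_target - mean Ct_reference) (normalization to a reference
#' gene such as beta-actin). Supplying calibrator Cts switches to the
#' delta-delta-Ct variant 2^-(dCt_sample - dCt_calibrator).
#'
#' @param ctTarget,ctReference replicate Ct values (>= 1 each).
#' @param ctTargetCalibrator,ctReferenceCalibrator optional calibrator
#'   replicate Cts.
#' @return Relative expression (numeric scalar).
#' @export
qpcrRelativeExpression <- function(ctTarget, ctReference,
                                   ctTargetCalibrator = NULL,
                                   ctReferenceCalibrator = NULL) {
  if (!length(ctTarget) || !length(ctReference))
    stop("empty replicate set")
  dct <- mean(ctTarget) - mean(ctReference)
  if (!is.null(ctTargetCalibrator)) {
    if (is.null(ctReferenceCalibrator)) stop("calibrator reference Cts missing")
    dct <- dct - (mean(ctTargetCalibrator) - mean(ctReferenceCalibrator))
  }
  2^(-dct)
}
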