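#' Normalize cDNA allele ratios by their gDNA ratios
#'
#' Dividing the cDNA checker:bar signal ratio by the matched gDNA ratio
#' controls for allele amplification bias; a normalized ratio of 1 means
#' balanced allelic expression.
#'
#' @param cdnaRatio,gdnaRatio positive signal-intensity ratios
#'   (vectorized); alternatively pass a data.frame with
#'   \code{cdnaRatio}/\code{gdnaRatio} columns as the first argument.
#' @return Normalized ratio(s).
#' @export
aseNormalize <- function(cdnaRatio, gdnaRatio = NULL) {
  if (is.data.frame(cdnaRatio)) {
    df <- cdnaRatio
    stopifnot(all(c("cdnaRatio", "gdnaRatio") %in% names(df)))
    cdnaRatio <- df$cdnaRatio; gdnaRatio <- df$gdnaRatio
  }
  if (any(gdnaRatio <= 0)) stop("gDNA ratios must be positive")
  if (any(cdnaRatio <= 0)) stop("cDNA ratios must be positive")
  cdnaRatio / gdnaRatio
}

#' Allele-specific expression tests across CNV copy classes
#'
#' Three analyses of gDNA-normalized allele ratios grouped by the copy
#' class of the checker chromosome: (i) a two-sample t-test between the
#' 1-copy and 4-copy classes, (ii) a regression of normalized ratio on
#' copy count with a slope test (trend), and (iii) per-class one-sample
#' Wilcoxon signed-rank tests against the balanced 1:1 ratio. Classes
#' where every ratio equals 1 exactly retain the null with p = 1.
#'
#' @param normalized gDNA-normalized allele ratios.
#' @param copyClass parallel vector of copy classes (1, 2 or 4).
#' @return list(twoSample = list(t, df, p), trend = list(slope, p, fit),
#'   oneSample = data.frame(class, n, mean, p)).
#' @export
aseTests <- function(normalized, copyClass) {
  if (length(normalized) != length(copyClass))
    stop("ratio and class vectors differ in length")
  cls <- as.numeric(as.character(copyClass))
  if (!all(cls %in% c(1, 2, 4))) stop("copy classes must be 1, 2 or 4")

  x1 <- normalized[cls == 1]; x4 <- normalized[cls == 4]
  if (length(x1) < 2 || length(x4) < 2)
    stop("two-sample test needs >= 2 ratios in each of classes 1 and 4")
  two <- if (sd(c(x1, x4)) == 0) list(t = 0, df = length(c(x1, x4)) - 2, p = 1)
  else {
    tt <- t.test(x1, x4)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  }

  if (length(unique(cls)) < 2)
    stop("trend regression needs at least two copy classes")
  if (var(normalized) == 0) {
    trend <- list(slope = 0, p = 1, fit = NULL)
  } else {
    fit <- lm(normalized ~ cls)
    sm <- summary(fit)$coefficients
    trend <- list(slope = unname(sm["cls", "Estimate"]),
                  p = unname(sm["cls", "Pr(>|t|)"]), fit = fit)
  }

  one <- do.call(rbind, lapply(sort(unique(cls)), function(k) {
    x <- normalized[cls == k]
    p <- if (all(x == 1)) 1 else
      suppressWarnings(wilcox.test(x, mu = 1, exact = FALSE))$p.value
    data.frame(class = k, n = length(x), mean = mean(x), p = p)
  }))
  list(twoSample = two, trend = trend, oneSample = one)
}
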