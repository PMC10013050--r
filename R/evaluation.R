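#' Folded AUROC between two samples
#'
#' Area under the ROC curve as the normalized Mann-Whitney statistic (ties
#' counted half), folded to \code{max(A, 1 - A)} so that 0.5 means full
#' distributional overlap and 1 perfect separation, regardless of which
#' group lies higher. Non-finite values (undefined-metric sentinels) are
#' removed first.
#'
#' @param a,b numeric samples.
#' @return folded AUROC in [0.5, 1], or NaN (with a warning) when a group
#'   is emptied by sentinel removal.
#' @export
auroc <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) {
    warning("a group is empty after removing undefined values; AUROC undefined")
    return(NaN)
  }
  r <- rank(c(a, b))
  A <- (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
    (length(a) * length(b))
  max(A, 1 - A)
}

#' Average pairwise AUROC over three classes
#'
#' The unweighted mean of the three pairwise folded AUROCs of a metric over
#' the three network-type (or state) classes; permutation-invariant in the
#' class labels.
#'
#' @param values numeric vector of metric values.
#' @param classes class label per value; exactly three distinct classes
#'   required.
#' @return mean of the three pairwise folded AUROCs.
#' @export
averagePairwiseAuroc <- function(values, classes) {
  cl <- sort(unique(as.character(classes)))
  if (length(cl) != 3)
    stop(sprintf("need exactly three classes, got %d (%s)", length(cl),
                 paste(cl, collapse = ", ")))
  pr <- utils::combn(cl, 2)
  mean(vapply(seq_len(ncol(pr)), function(q)
    auroc(values[classes == pr[1, q]], values[classes == pr[2, q]]), 0.0))
}

#' One-way ANOVA for equal class means
#'
#' Classic fixed-effects one-way ANOVA of a metric across classes.
#'
#' @param values numeric vector.
#' @param classes class label per value (at least 2 classes of at least 2
#'   finite values each).
#' @return the ANOVA p-value.
#' @export
anovaEqualMeans <- function(values, classes) {
  keep <- is.finite(values)
  values <- values[keep]; classes <- factor(as.character(classes)[keep])
  if (nlevels(classes) < 2 || any(table(classes) < 2))
    stop("need at least 2 classes with at least 2 values each")
  if (all(tapply(values, classes, stats::sd) == 0)) {
    if (length(unique(tapply(values, classes, mean))) == 1) return(1)
    warning("zero within-group variance everywhere; p reported as 0")
    return(0)
  }
  fit <- stats::lm(values ~ classes)
  stats::anova(fit)[["Pr(>F)"]][1]
}

#' Welch t-test between two window groups
#'
#' Two-sided unequal-variance t-test for equal means, e.g. of a metric over
#' the pre-discharge versus discharge windows of an epoch.
#'
#' @param pre,during numeric samples (at least 2 finite values each).
#' @return the p-value, or NaN with a warning for a single-window group.
#' @export
ttestWindows <- function(pre, during) {
  pre <- pre[is.finite(pre)]; during <- during[is.finite(during)]
  if (length(pre) < 2 || length(during) < 2) {
    warning("fewer than two windows in a period; t-test undefined")
    return(NaN)
  }
  if (stats::sd(pre) == 0 && stats::sd(during) == 0)
    return(if (mean(pre) == mean(during)) 1 else 0)
  stats::t.test(pre, during, var.equal = FALSE)$p.value
}

#' Correlation between true and estimated metric values
#'
#' Pearson correlation over paired realizations, quantifying how well an
#' estimated network's metric tracks the true network's metric.
#'
#' @param trueVals,estimated paired numeric vectors (length >= 3 after
#'   removing non-finite pairs).
#' @return Pearson correlation, or NaN for zero variance.
#' @export
trueVsEstimatedCorrelation <- function(trueVals, estimated) {
  keep <- is.finite(trueVals) & is.finite(estimated)
  x <- trueVals[keep]; y <- estimated[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NaN)
  stats::cor(x, y)
}
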