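#' Mixed embedding selected by conditional mutual information
#'
#' Builds the mixed embedding vector for one target channel: among the
#' lagged variables of all channels (lags 1..Lmax), the first term maximizes
#' the mutual information with the target's next value; every subsequent
#' term maximizes the conditional mutual information given the terms already
#' selected. Mutual information is estimated with the
#' Kraskov-Stoegbauer-Grassberger k-nearest-neighbour estimator (maximum
#' norm) on rank-uniformized data. Selection stops when the best
#' candidate's contribution is not statistically significant under a
#' time-shift surrogate randomization test (or, with
#' \code{stopping = "ratio"}, when the relative information gain falls below
#' a threshold), or when \code{maxTerms} terms have been accepted.
#'
#' @param ts \linkS4class{MultiTS} or numeric matrix.
#' @param target column index of the response channel.
#' @param Lmax maximum lag (default 5).
#' @param lags explicit candidate lag set overriding \code{1:Lmax}; a
#'   delay-coupled system sampled coarsely needs candidates near the
#'   coupling delay (in sampling units), e.g. \code{c(1:3, 24:26)} for the
#'   coupled Mackey-Glass convention.
#' @param kNeighbors neighbours of the KSG estimator (default 5).
#' @param nSurrogates time-shift surrogates of the significance test
#'   (19 draws give an exact rank test at level 1/20).
#' @param alpha significance level of the termination test.
#' @param maxTerms cap on the embedding size.
#' @param stopping \code{"surrogate"} (default, the randomization test)
#'   or \code{"ratio"} (fixed relative-gain rule).
#' @param ratioThreshold for ratio stopping: a term is accepted while
#'   I(old) / I(new) stays below this value.
#' @param selectionPoints cap on the number of time points used by the
#'   term-selection scans (systematic thinning). \code{Inf} disables
#'   thinning.
#' @param measurePoints cap on the number of time points used for the
#'   final information ratio (default 512).
#' @param seed RNG seed for the surrogate shifts.
#' @return data.frame of selected terms (columns \code{var}, \code{lag}) in
#'   selection order, with attribute \code{"excluded"} listing constant
#'   channels that were removed from the candidate set.
#' @export
mixedEmbedding <- function(ts, target, Lmax = 5, kNeighbors = 5,
                           nSurrogates = 19, alpha = 0.05, maxTerms = 10,
                           stopping = c("surrogate", "ratio"),
                           ratioThreshold = 0.97, selectionPoints = 256,
                           lags = seq_len(Lmax), seed = NULL) {
  stopping <- match.arg(stopping)
  x <- tsMatrix(ts)
  prep <- embedPrep(x, target, lags)
  withSeed(seed,
    embedSelect(prep, kNeighbors, nSurrogates, alpha, maxTerms,
                stopping, ratioThreshold, selectionPoints))
}

# rank-uniformize to (0, 1); tames heavy tails and spikes before kNN
# estimation
uniformize <- function(x) {
  apply(x, 2, function(col) (rank(col, ties.method = "average") - 0.5) / length(col))
}

embedPrep <- function(x, target, lags) {
  N <- nrow(x); K <- ncol(x)
  Lmax <- max(lags)
  if (N <= Lmax + 20) stop("time series too short for the requested lags")
  const <- apply(x, 2, function(col) stats::sd(col) == 0 || !is.finite(stats::sd(col)))
  if (const[target]) stop("target channel is constant")
  u <- uniformize(x)
  ld <- lagDesign(u, Lmax)
  y <- u[(Lmax + 1):N, target]
  excluded <- which(const)
  if (length(excluded) > 0)
    warning(sprintf("constant channel(s) excluded from candidates: %s",
                    paste(excluded, collapse = ", ")))
  candOk <- !(ld$info$var %in% excluded) & (ld$info$lag %in% lags)
  list(y = y, D = ld$D, info = ld$info, M = ld$M, candOk = candOk,
       target = target, K = K, minShift = max(20L, Lmax + 1L))
}

# Selection loop. The first term must beat a family-wise time-shift
# randomization test: the observed first-step statistic is the maximum MI
# over all candidates, so each surrogate draw is the maximum over the
# identically shifted candidates (an exact level-alpha test under the
# null of an independent target, giving an empty embedding with
# probability ~ 1 - alpha there). With stopping = "surrogate" (default)
# every later step tests the best candidate's CMI against per-candidate
# time-shift surrogates; with stopping = "ratio" a later term is accepted
# while its conditional-information gain exceeds (1/ratioThreshold - 1)
# times the chain-rule accumulated information.
embedSelect <- function(prep, kNeighbors, nSurrogates, alpha, maxTerms,
                        stopping, ratioThreshold, selectionPoints = 256) {
  y <- prep$y; M <- prep$M; D <- prep$D
  if (is.finite(selectionPoints) && M > selectionPoints) {
    stride <- ceiling(M / selectionPoints)
    idx <- seq(1, M, by = stride)
    y <- y[idx]; D <- D[idx, , drop = FALSE]; M <- length(idx)
  }
  sel <- integer(0)
  minShift <- min(prep$minShift, floor(M / 3))
  stopAt <- max(1L, as.integer(floor(alpha * (nSurrogates + 1))))
  iAcc <- 0
  repeat {
    if (length(sel) >= maxTerms) break
    rem <- setdiff(which(prep$candOk), sel)
    if (length(rem) == 0) break
    cond <- D[, sel, drop = FALSE]
    cmis <- scan_cmi_cpp(y, D, rem, cond, kNeighbors)
    bestQ <- which.max(cmis)
    obs <- cmis[bestQ]
    best <- rem[bestQ]
    if (!is.finite(obs) || obs <= 0) break
    if (length(sel) == 0) {
      # first step: the observed statistic is a maximum over candidates, so
      # the surrogate null is the max-statistic over candidates per shift.
      # The whole gate (statistic and null draws) runs on a coarser
      # subsample: the test stays exact at its level, at a fraction of the
      # cost of the full max-null (96 points suffice for the gate's
      # any-dependence decision).
      gi <- seq(1, M, by = ceiling(M / 96))
      Mg <- length(gi)
      gObs <- max(scan_cmi_cpp(y[gi], D[gi, , drop = FALSE], rem,
                               cond[gi, , drop = FALSE], kNeighbors))
      gShift <- min(minShift, floor(Mg / 3))
      shifts <- sample(seq(gShift, Mg - gShift), nSurrogates, replace = TRUE)
      sc <- surrogate_max_count_cpp(y[gi], D[gi, , drop = FALSE], rem,
                                    kNeighbors, shifts, gObs, stopAt)
      significant <- (sc[1] + (nSurrogates - sc[2])) < stopAt
    } else if (stopping == "surrogate") {
      shifts <- sample(seq(minShift, M - minShift), nSurrogates, replace = TRUE)
      sc <- surrogate_count_cpp(y, D[, best], cond, kNeighbors,
                                shifts, obs, stopAt)
      significant <- (sc[1] + (nSurrogates - sc[2])) < stopAt
    } else {
      significant <- obs > (1 / ratioThreshold - 1) * iAcc
    }

    if (!significant) break
    sel <- c(sel, best)
    iAcc <- iAcc + obs
  }
  out <- prep$info[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- which(!prep$candOk[seq_len(prep$K)])
  out
}

#' Partial mutual information from mixed embedding
#'
#' For every ordered channel pair (X, Y): the mixed embedding of the target
#' Y is built once with [mixedEmbedding()]; if it contains no lagged term of
#' X the measure is exactly zero, otherwise
#' \deqn{PMIME_{X \to Y} = \frac{I(y_{t+1}; w^x \mid w^y, w^z)}{I(y_{t+1};
#' \mathbf{w})}}
#' with \eqn{w^x} the selected lags of X, \eqn{w^y} the selected lags of Y
#' itself and \eqn{w^z} the rest. Values are clipped to [0, 1]; a
#' non-positive denominator estimate yields 0 with a warning.
#'
#' @inheritParams mixedEmbedding
#' @param seed master seed; each target channel receives an
#'   order-independent sub-seed.
#' @return a \linkS4class{CausalityMatrix} with measure tag \code{"PMIME"};
#'   entry \code{[i, j]} estimates the driving i -> j.
#' @export
pmime <- function(ts, Lmax = 5, kNeighbors = 5, nSurrogates = 19,
                  alpha = 0.05, maxTerms = 10,
                  stopping = c("surrogate", "ratio"), ratioThreshold = 0.97,
                  selectionPoints = 256, measurePoints = 512,
                  lags = seq_len(Lmax), seed = NULL) {
  stopping <- match.arg(stopping)
  x <- tsMatrix(ts)
  K <- ncol(x)
  vals <- matrix(0, K, K, dimnames = list(colnames(x), colnames(x)))
  for (j in seq_len(K)) {
    prep <- embedPrep(x, j, lags)
    emb <- withSeed(if (is.null(seed)) NULL else subSeed(seed, 101L, j),
      embedSelect(prep, kNeighbors, nSurrogates, alpha, maxTerms,
                  stopping, ratioThreshold, selectionPoints))
    if (nrow(emb) == 0) next
    drivers <- setdiff(unique(emb$var), j)
    if (length(drivers) == 0) next
    colsOf <- function(v) (emb$lag[emb$var %in% v] - 1) * K + emb$var[emb$var %in% v]
    allCols <- (emb$lag - 1) * K + emb$var
    mi <- if (is.finite(measurePoints) && prep$M > measurePoints)
      seq(1, prep$M, by = ceiling(prep$M / measurePoints)) else seq_len(prep$M)
    ymat <- matrix(prep$y[mi], ncol = 1)
    den <- ksg_mi_cpp(prep$D[mi, allCols, drop = FALSE], ymat, kNeighbors)
    for (i in drivers) {
      if (den <= 0) {
        warning(sprintf("non-positive total mutual information for target %d; PMIME set to 0", j))
        break
      }
      wx <- prep$D[mi, colsOf(i), drop = FALSE]
      rest <- prep$D[mi, setdiff(allCols, colsOf(i)), drop = FALSE]
      num <- ksg_cmi_cpp(wx, ymat, rest, kNeighbors)
      vals[i, j] <- min(1, max(0, num / den))
    }
  }
  new("CausalityMatrix", values = vals, measure = "PMIME",
      params = list(Lmax = Lmax, kNeighbors = kNeighbors,
                    nSurrogates = nSurrogates, alpha = alpha,
                    maxTerms = maxTerms, stopping = stopping))
}
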