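tsMatrix <- function(ts) {
  if (is(ts, "MultiTS")) ts@values
  else if (is.matrix(ts)) ts
  else stop("expected a MultiTS or a numeric matrix")
}

# Lagged design matrix shared by all targets: column (v, l) holds x[t - l, v]
# for response rows t = (pmax + 1) .. N. Candidate order is backward in time:
# all variables at lag 1, then lag 2, ... (most recent past first).
lagDesign <- function(x, pmax) {
  N <- nrow(x); K <- ncol(x)
  M <- N - pmax
  D <- matrix(0, M, K * pmax)
  info <- data.frame(var = integer(K * pmax), lag = integer(K * pmax))
  c0 <- 0
  for (l in seq_len(pmax)) {
    D[, c0 + seq_len(K)] <- x[(pmax + 1 - l):(N - l), , drop = FALSE]
    info$var[c0 + seq_len(K)] <- seq_len(K)
    info$lag[c0 + seq_len(K)] <- l
    c0 <- c0 + K
  }
  list(D = D, info = info, M = M)
}

fitRSS <- function(X, y) {
  # residual sum of squares of an OLS fit with intercept; NA when the
  # regressor set is rank deficient
  Z <- cbind(1, X)
  f <- .lm.fit(Z, y)
  if (f$rank < ncol(Z)) return(NA_real_)
  sum(f$residuals^2)
}

#' Modified backward-in-time term selection for a sparse VAR model
#'
#' Greedy forward inclusion over the lagged variables of all channels,
#' ordered backward in time (lag 1 of every channel first, then lag 2, ...).
#' At each round the candidate whose inclusion lowers the Bayesian
#' information criterion of the target's regression the most is added; the
#' search stops when no candidate lowers the BIC. Candidates that make the
#' regression rank deficient are dropped with a warning.
#'
#' @param ts \linkS4class{MultiTS} or numeric matrix (rows are time points).
#' @param target column index of the response channel.
#' @param pmax maximum lag considered.
#' @return data.frame of selected terms with columns \code{var}, \code{lag}
#'   (possibly empty), ordered as selected; attribute \code{"rss"} holds the
#'   residual sum of squares of the selected model and \code{"n"} the number
#'   of regression rows.
#' @export
mbtsSelect <- function(ts, target, pmax = 5) {
  x <- tsMatrix(ts)
  ld <- lagDesign(x, pmax)
  mbtsSelectPre(ld, x, target, pmax)
}

# internal variant reusing a prebuilt lag design across targets
mbtsSelectPre <- function(ld, x, target, pmax) {
  N <- nrow(x)
  y <- x[(pmax + 1):N, target]
  M <- ld$M
  sel <- integer(0)
  rssSel <- sum((y - mean(y))^2)
  bicSel <- M * log(rssSel / M) + log(M)
  dropped <- logical(ncol(ld$D))
  repeat {
    rem <- setdiff(which(!dropped), sel)
    if (length(rem) == 0) break
    bics <- rep(Inf, length(rem))
    rsss <- rep(NA_real_, length(rem))
    for (q in seq_along(rem)) {
      rss <- fitRSS(ld$D[, c(sel, rem[q]), drop = FALSE], y)
      if (is.na(rss)) { dropped[rem[q]] <- TRUE; next }
      rsss[q] <- rss
      bics[q] <- M * log(rss / M) + (length(sel) + 2) * log(M)
    }
    if (any(dropped[rem]))
      warning("rank-deficient candidate term(s) dropped during selection")
    best <- which.min(bics)
    if (!is.finite(bics[best]) || bics[best] >= bicSel) break
    sel <- c(sel, rem[best])
    bicSel <- bics[best]
    rssSel <- rsss[best]
  }
  out <- ld$info[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rss") <- rssSel
  attr(out, "n") <- M
  out
}

#' Restricted conditional Granger causality index
#'
#' For every ordered channel pair (X, Y), fits the sparse VAR model of Y
#' selected by [mbtsSelect()] (the U-model) and the same model with all
#' lagged terms of X removed (the R-model), and reports
#' \deqn{RCGCI_{X \to Y} = \log(s_R^2 / s_U^2)}
#' with \eqn{s^2} the maximum-likelihood residual variances (RSS / n, so the
#' index is non-negative by nesting). When the U-model contains no lagged
#' term of X the index is exactly zero.
#'
#' @param ts \linkS4class{MultiTS} or numeric matrix.
#' @param pmax maximum lag of the candidate set (default 5).
#' @return a \linkS4class{CausalityMatrix} with measure tag \code{"RCGCI"};
#'   entry \code{[i, j]} estimates the driving i -> j.
#' @export
rcgci <- function(ts, pmax = 5) {
  x <- tsMatrix(ts)
  K <- ncol(x)
  N <- nrow(x)
  ld <- lagDesign(x, pmax)
  vals <- matrix(0, K, K, dimnames = list(colnames(x), colnames(x)))
  for (j in seq_len(K)) {
    sel <- mbtsSelectPre(ld, x, j, pmax)
    if (nrow(sel) == 0) next
    rssU <- attr(sel, "rss"); M <- attr(sel, "n")
    sU2 <- rssU / M
    if (sU2 <= 0)
      stop(sprintf("perfect fit for channel %d (zero residual variance); add noise or shorten the model", j))
    y <- x[(pmax + 1):N, j]
    selIdx <- (sel$lag - 1) * K + sel$var
    for (i in setdiff(unique(sel$var), j)) {
      keep <- selIdx[sel$var != i]
      rssR <- if (length(keep) == 0) sum((y - mean(y))^2)
              else fitRSS(ld$D[, keep, drop = FALSE], y)
      vals[i, j] <- max(0, log((rssR / M) / sU2))
    }
  }
  new("CausalityMatrix", values = vals, measure = "RCGCI",
      params = list(pmax = pmax, N = N))
}
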