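#' Simulate coupled Henon maps
#'
#' Iterates the coupled Henon system: each node evolves as
#' \deqn{x_{j,t} = 1.4 - \left[\frac{\sum_i C_{ij} x_{i,t-1}}{\sum_i
#' \Theta(C_{ij})} + \Big(1 - \frac{\sum_i C_{ij}}{\sum_i \Theta(C_{ij})}\Big)
#' x_{j,t-1}\right]^2 + 0.3\, x_{j,t-2}}
#' where the sums run over the drivers of node j and \eqn{\Theta} indicates a
#' non-zero coupling. A node with no drivers reduces to the standard Henon
#' map \eqn{x_t = 1.4 - x_{t-1}^2 + 0.3 x_{t-2}} (the 0/0 coupling ratio is
#' taken as zero by convention).
#'
#' @param net \linkS4class{CouplingMatrix} with strengths set (entry
#'   \code{[i, j]} drives j); C = 0.2 by the study convention.
#' @param N number of retained time points.
#' @param transient leading iterations to discard (after the two seeds).
#' @param init optional 2 x K matrix of the first two states; defaults to
#'   seeded uniform draws in (-0.1, 0.1).
#' @param seed RNG seed for the initial condition.
#' @return a sensor-space \linkS4class{MultiTS} (N x K, unit sampling step).
#' @export
simulateCHM <- function(net, N = 2048, transient = 1000, init = NULL,
                        seed = NULL) {
  stopifnot(is(net, "CouplingMatrix"))
  stopifnotScalar(N, "N");
  if (transient < 0) stop("transient must be non-negative")
  C <- net@values
  K <- ncol(C)
  din <- colSums(C > 0)                      # drivers per response node
  csum <- colSums(C)
  selfCoef <- ifelse(din > 0, 1 - csum / din, 1)
  withSeed(seed, {
    if (is.null(init)) init <- matrix(runif(2 * K, -0.1, 0.1), 2, K)
    if (!all(dim(init) == c(2, K))) stop("init must be a 2 x K matrix")
    total <- N + transient
    X <- matrix(0, total + 2, K)
    X[1:2, ] <- init
    tC <- t(C)
    for (t in 3:(total + 2)) {
      xp <- X[t - 1, ]
      drive <- as.vector(tC %*% xp)
      b <- ifelse(din > 0, drive / din, 0) + selfCoef * xp
      x <- 1.4 - b^2 + 0.3 * X[t - 2, ]
      if (any(abs(x) > 1e6)) {
        bad <- which(abs(x) > 1e6)[1]
        stop(sprintf("coupled Henon system diverged at node %d (iteration %d); reduce coupling or in-degree",
                     bad, t - 2))
      }
      X[t, ] <- x
    }
    out <- X[(transient + 3):(total + 2), , drop = FALSE]
    colnames(out) <- colnames(C)
    new("MultiTS", values = out, samplingInterval = 1, space = "sensor")
  })
}

#' Simulate coupled Mackey-Glass delay systems
#'
#' Integrates the coupled delay system
#' \deqn{\dot x_j(t) = -0.1\, x_j(t) + \sum_i C_{ij}
#' \frac{x_i(t-\Delta)}{1 + x_i(t-\Delta)^{10}}}
#' by fixed-step 4th-order Runge-Kutta with cubic Hermite interpolation of
#' the delayed state (method of steps). Each node additionally carries a
#' self-coupling term with coefficient \code{selfCoupling} (0.2 by default),
#' so that an uncoupled unit is the classic chaotic Mackey-Glass system
#' (delay 100 time units gives high-dimensional chaos). Output is sampled
#' every \code{sampleStep} time units after the transient.
#'
#' @param net \linkS4class{CouplingMatrix} with strengths set (inter-node
#'   coupling C = 0.1 by the study convention).
#' @param N number of retained samples.
#' @param delay delay \eqn{\Delta} in time units (default 100).
#' @param sampleStep sampling interval in time units (default 4).
#' @param h integration step; must divide both \code{sampleStep} and
#'   \code{delay} (default 0.1, i.e. 40 history points per sample).
#' @param transient leading time units to discard.
#' @param selfCoupling self-term production coefficient (set to 0 for a pure
#'   linear decay of uncoupled nodes).
#' @param history initial history: scalar or length-K vector of constant
#'   pre-zero values; defaults to seeded uniform draws in (0.5, 1.5).
#' @param seed RNG seed for the initial history.
#' @return a sensor-space \linkS4class{MultiTS} with sampling interval
#'   \code{sampleStep}.
#' @export
simulateCMG <- function(net, N = 2048, delay = 100, sampleStep = 4, h = 0.1,
                        transient = 1000, selfCoupling = 0.2, history = NULL,
                        seed = NULL) {
  stopifnot(is(net, "CouplingMatrix"))
  stopifnotScalar(delay, "delay"); stopifnotScalar(h, "h")
  if (abs(sampleStep / h - round(sampleStep / h)) > 1e-9)
    stop("h must divide sampleStep")
  if (abs(delay / h - round(delay / h)) > 1e-9)
    stop("h must divide the delay")
  C <- net@values
  K <- ncol(C)
  Cfull <- C
  diag(Cfull) <- diag(Cfull) + selfCoupling
  withSeed(seed, {
    if (is.null(history)) history <- runif(K, 0.5, 1.5)
    if (length(history) == 1) history <- rep(history, K)
    if (length(history) != K) stop("history must have one value per node")
    out <- cmg_integrate(Cfull, as.numeric(history), h,
                         as.integer(round(delay / h)),
                         as.integer(round(sampleStep / h)),
                         as.integer(N),
                         as.integer(round(transient / sampleStep)))
    if (any(!is.finite(out)))
      stop("coupled Mackey-Glass integration produced a non-finite state")
    colnames(out) <- colnames(C)
    new("MultiTS", values = out, samplingInterval = sampleStep,
        space = "sensor")
  })
}

#' Build a stationary VAR(1) process on a coupling network
#'
#' All coefficients supported by the network start at \code{init} (0.9 by
#' convention) and are repeatedly multiplied by
#' \code{shrink} until the spectral radius of the coefficient matrix drops
#' below \code{1 - margin}, guaranteeing stationarity. Note the coefficient
#' matrix is the transpose of the coupling orientation: coupling i -> j
#' puts the coefficient in row j (response), column i (driver).
#'
#' @param net \linkS4class{CouplingMatrix} (binary or weighted; only the
#'   support is used).
#' @param init starting value of non-zero coefficients.
#' @param shrink multiplicative shrink factor per iteration.
#' @param margin stationarity margin on the spectral radius.
#' @return a stationary \linkS4class{VarProcess} with identity noise
#'   covariance.
#' @export
stabilizeVar <- function(net, init = 0.9, shrink = 0.95, margin = 0.05) {
  stopifnot(is(net, "CouplingMatrix"))
  stopifnotScalar(init, "init")
  if (shrink <= 0 || shrink >= 1) stop("shrink must lie in (0, 1)")
  A <- t(net@values > 0) * init
  if (any(A != 0)) {
    while (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1 - margin)
      A <- A * shrink
  }
  K <- nrow(A)
  dimnames(A) <- dimnames(net@values)
  new("VarProcess", A = A, noiseCov = diag(K), order = 1L)
}

spectralRadius <- function(A) {
  if (all(A == 0)) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Simulate a VAR(1) process
#'
#' Exact iteration of \code{x_t = A x_{t-1} + e_t} with seeded Gaussian
#' innovations (zero mean, covariance \code{noiseCov}); the leading
#' \code{transient} states are discarded.
#'
#' @param proc a stationary \linkS4class{VarProcess}.
#' @param N number of retained time points.
#' @param transient burn-in length.
#' @param seed RNG seed for the innovations.
#' @return a sensor-space \linkS4class{MultiTS}.
#' @export
simulateVar <- function(proc, N = 2048, transient = 500, seed = NULL) {
  stopifnot(is(proc, "VarProcess"))
  if (spectralRadius(proc@A) >= 1)
    stop("process is not stationary (spectral radius >= 1)")
  K <- nrow(proc@A)
  R <- chol(proc@noiseCov)
  withSeed(seed, {
    total <- N + transient
    E <- matrix(rnorm(total * K), total, K) %*% R
    X <- matrix(0, total, K)
    x <- numeric(K)
    tA <- t(proc@A)
    for (t in seq_len(total)) {
      x <- as.vector(x %*% tA) + E[t, ]
      X[t, ] <- x
    }
    out <- X[(transient + 1):total, , drop = FALSE]
    colnames(out) <- colnames(proc@A)
    new("MultiTS", values = out, samplingInterval = 1, space = "sensor")
  })
}

#' Linearly transform a VAR(1) process
#'
#' For an invertible mixing matrix H, the transformed state y = H x follows
#' a VAR(1) with coefficient matrix \code{B = H A H^-1} (similar to A, so
#' with identical eigenvalues) and correlated innovation covariance
#' \code{H Sigma Ht}. Choosing H as the inverse eigenvector matrix of a
#' diagonalizable A yields a diagonal B: a mixed system with no lagged
#' cross-connections at all.
#'
#' @param proc a \linkS4class{VarProcess}.
#' @param H invertible K x K matrix.
#' @return list with elements \code{transform} (a
#'   \linkS4class{LinearTransform}) and \code{process} (the
#'   \linkS4class{VarProcess} of y).
#' @export
transformVar <- function(proc, H) {
  stopifnot(is(proc, "VarProcess"))
  if (!is.matrix(H) || !all(dim(H) == dim(proc@A)))
    stop("H must be a K x K matrix")
  Hinv <- tryCatch(solve(H), error = function(e) stop("H is singular"))
  if (max(Mod(H %*% Hinv - diag(nrow(H)))) > 1e-6)
    stop("H is singular or too ill-conditioned to invert")
  B <- H %*% proc@A %*% Hinv
  QA <- eigen(proc@A)$vectors
  newProc <- new("VarProcess", A = B,
                 noiseCov = H %*% proc@noiseCov %*% t(H), order = 1L)
  list(transform = new("LinearTransform", H = H, B = B, QA = QA),
       process = newProc)
}
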