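#' Synthesize a spherical single-shell head model
#'
#' Builds a lead field for the analytic homogeneous conducting sphere:
#' electrodes sit on the unit sphere at synthetic 10-10 coordinates
#' ([tenTenMontage()]), voxels on a regular cubic lattice pruned to a
#' concentric sphere of radius \code{radius}. The gain of each dipole
#' component is the truncated Legendre-series solution of the
#' current-dipole potential in a homogeneous sphere with an insulating
#' boundary. The model is deterministic given its inputs; it is a synthetic
#' stand-in for a realistic volume-conductor model, so source-space results
#' derived from it are directional rather than anatomically exact.
#'
#' @param electrodeLabels channel labels; must be known 10-10 labels.
#' @param nVoxels target voxel count (the realized count is the nearest
#'   lattice pruning, reported by the object).
#' @param radius source-sphere radius (electrodes at radius 1).
#' @param conductivity homogeneous conductivity (scales the gain only).
#' @param nTerms Legendre truncation order.
#' @return a \linkS4class{LeadField}.
#' @export
synthesizeHeadModel <- function(electrodeLabels = simulationElectrodes(),
                                nVoxels = 1000, radius = 0.85,
                                conductivity = 0.33, nTerms = 80) {
  mont <- tenTenMontage()
  unknown <- setdiff(electrodeLabels, mont$label)
  if (length(unknown) > 0)
    stop(sprintf("unknown electrode label(s): %s\nknown labels: %s",
                 paste(unknown, collapse = ", "),
                 paste(mont$label, collapse = ", ")))
  if (length(electrodeLabels) < 4) stop("need at least 4 electrodes")
  if (nVoxels < length(electrodeLabels)) stop("need at least one voxel per electrode")
  epos <- as.matrix(mont[match(electrodeLabels, mont$label), c("x", "y", "z")])
  rownames(epos) <- electrodeLabels

  spacing <- (4 / 3 * pi * radius^3 / nVoxels)^(1 / 3)
  half <- floor(radius / spacing)
  ax <- (-half:half) * spacing
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- sqrt(rowSums(grid^2)) <= radius
  vox <- grid[keep, , drop = FALSE]

  G <- sphericalGain(epos, vox, conductivity, nTerms)
  new("LeadField", gain = G,
      electrodes = data.frame(label = electrodeLabels, x = epos[, 1],
                              y = epos[, 2], z = epos[, 3],
                              stringsAsFactors = FALSE, row.names = NULL),
      voxels = vox, spacing = spacing, radius = radius)
}

# Potential on the surface of a homogeneous conducting sphere (radius 1,
# insulating boundary) from a unit current dipole at radius b < 1:
#   V = 1/(4 pi sigma) sum_n (2n+1)/n * b^(n-1) * [ n q_r P_n(cos g)
#        + q_t P_n^1(cos g) ]
# with q_r the radial and q_t the tangential (towards the electrode) dipole
# components. Gains for the three Cartesian components follow by expressing
# (q_r, q_t) in the voxel's radial/tangential frame.
sphericalGain <- function(epos, vox, conductivity, nTerms) {
  c_ <- nrow(epos); v <- nrow(vox)
  G <- matrix(0, c_, 3 * v)
  b <- sqrt(rowSums(vox^2))
  pref <- 1 / (4 * pi * conductivity)
  for (e in seq_len(c_)) {
    re <- epos[e, ]
    central <- b < 1e-12
    # radial/tangential decomposition per voxel
    rhat <- vox / pmax(b, 1e-12)
    cosg <- pmin(1, pmax(-1, rhat %*% re))        # |re| = 1
    sing <- sqrt(pmax(0, 1 - cosg^2))
    # tangent unit vector in the voxel-electrode plane
    tv <- matrix(re, v, 3, byrow = TRUE) - as.vector(cosg) * rhat
    tn <- sqrt(rowSums(tv^2))
    tv <- tv / pmax(tn, 1e-12)
    aligned <- tn < 1e-12

    # Legendre recurrences, vectorized over voxels
    Pm1 <- rep(1, v); P0 <- as.vector(cosg)       # P_0, P_1
    Q0 <- as.vector(sing)                         # P_1^1 (no phase)
    Qm1 <- rep(0, v)
    radAcc <- numeric(v); tanAcc <- numeric(v)
    bn <- rep(1, v)                               # b^(n-1)
    for (n in seq_len(nTerms)) {
      coef <- (2 * n + 1) / n * bn
      radAcc <- radAcc + coef * n * P0
      tanAcc <- tanAcc + coef * Q0
      # advance P_n -> P_(n+1) and P_n^1 -> P_(n+1)^1
      P1 <- ((2 * n + 1) * cosg * P0 - n * Pm1) / (n + 1)
      Q1 <- ((2 * n + 1) * cosg * Q0 - (n + 1) * Qm1) / n
      Pm1 <- P0; P0 <- as.vector(P1)
      Qm1 <- Q0; Q0 <- as.vector(Q1)
      bn <- bn * b
    }
    gain <- pref * (as.vector(radAcc) * rhat + as.vector(tanAcc) * tv)
    # central voxel: only the n = 1 term survives, direction of re
    if (any(central))
      gain[central, ] <- matrix(pref * 3 * re, sum(central), 3, byrow = TRUE)
    if (any(aligned & !central)) {
      # electrode radially above the voxel: tangential gain vanishes
      idx <- which(aligned & !central)
      gain[idx, ] <- pref * radAcc[idx] * rhat[idx, , drop = FALSE]
    }
    G[e, ] <- as.vector(t(gain))
  }
  G
}

# 6-neighbour lattice smoothing operator: L = I - Adj/6, nonsingular
# (strictly diagonally dominant at boundary voxels, where missing
# neighbours contribute nothing).
latticeOperator <- function(vox, spacing) {
  v <- nrow(vox)
  key <- function(p) paste(round(p[, 1] / spacing), round(p[, 2] / spacing),
                           round(p[, 3] / spacing))
  lookup <- new.env(hash = TRUE, size = v)
  ks <- key(vox)
  for (i in seq_len(v)) assign(ks[i], i, envir = lookup)
  ii <- integer(0); jj <- integer(0)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(6)) {
    nb <- sweep(vox, 2, shifts[s, ] * spacing, "+")
    kn <- key(nb)
    for (i in seq_len(v)) {
      j <- lookup[[kn[i]]]
      if (!is.null(j)) { ii <- c(ii, i); jj <- c(jj, j) }
    }
  }
  Adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(v, v))
  Matrix::Diagonal(v) - Adj / 6
}

#' Build the standardized weighted minimum-norm inverse
#'
#' Solves \code{min_d ||L W d||} subject to \code{m = G d}, with W the
#' diagonal matrix of lead-field column norms (depth weighting) and L a
#' smoothing operator, giving the inverse operator
#' \deqn{T = M^{-1} G' (G M^{-1} G')^{+}, \quad M = W L' L W.}
#' Each voxel's estimate is standardized by the 3 x 3 diagonal block of the
#' model covariance of \code{d* = T m} under the source prior matched to
#' the weighted norm, d ~ N(0, M^-1) (noise-free), so
#' \code{S = T (G M^-1 Gt) Tt}; blocks are ridge-regularized by 1e-12 of
#' their trace before inversion.
#'
#' With the default \code{smoothing = "none"} (L = I) the weighting matrix
#' is diagonal and cancels exactly in the standardized power, which is what
#' gives the method its defining zero-localization-error property for
#' noiseless point sources. \code{smoothing = "laplacian"} uses the
#' 6-neighbour lattice operator \code{I - Adj/6} per dipole component (the
#' smoothness-seeking low-resolution variant); its standardized power is no
#' longer exactly localizing.
#'
#' @param lf a \linkS4class{LeadField}.
#' @param smoothing \code{"none"} (default) or \code{"laplacian"}.
#' @return a \linkS4class{SloretaTransform}.
#' @export
buildTransform <- function(lf, smoothing = c("none", "laplacian")) {
  smoothing <- match.arg(smoothing)
  stopifnot(is(lf, "LeadField"))
  G <- lf@gain
  v <- nrow(lf@voxels)
  W <- sqrt(colSums(G^2))
  if (smoothing == "laplacian") {
    L <- latticeOperator(lf@voxels, lf@spacing)
    L3 <- Matrix::kronecker(L, Matrix::Diagonal(3))
    Dw <- Matrix::Diagonal(x = W)
    M <- Dw %*% Matrix::crossprod(L3) %*% Dw
  } else {
    M <- Matrix::Diagonal(x = W^2)
  }
  X <- as.matrix(Matrix::solve(M, t(G)))
  P <- G %*% X
  sv <- svd(P)
  tol <- max(sv$d) * 1e-10
  pos <- sv$d > tol
  Pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  Tmat <- X %*% Pinv

  # model covariance of m under the prior matched to the weighted norm,
  # d ~ N(0, M^-1): cov(m) = G M^-1 G' = P. Standardizing with this
  # covariance makes the diagonal weighting cancel in the quadratic form,
  # which is what yields exact localization of noiseless point sources.
  TG <- Tmat %*% P                       # 3v x c
  Sinv <- array(0, c(3, 3, v))
  for (i in seq_len(v)) {
    rows <- (3 * i - 3) + 1:3
    S <- TG[rows, , drop = FALSE] %*% t(Tmat[rows, , drop = FALSE])
    S <- S + diag(3) * (1e-12 * sum(diag(S)) + 1e-300)
    Si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Si))
      stop(sprintf("singular standardization block at voxel %d", i))
    Sinv[, , i] <- Si
  }
  new("SloretaTransform", Tmat = Tmat, W = W, Sinv = Sinv,
      electrodeLabels = lf@electrodes$label)
}

#' Standardized source power of one sensor sample
#'
#' Applies the inverse operator to a single measurement vector and returns
#' the standardized power per voxel: the quadratic form
#' \code{di . Sii^-1 . di} of each voxel's 3-component estimate. For a
#' noiseless single-dipole measurement the argmax is the true voxel (zero
#' localization error of the standardized inverse).
#'
#' @param transform a \linkS4class{SloretaTransform}.
#' @param lf the matching \linkS4class{LeadField}.
#' @param m numeric vector of electrode potentials (length c).
#' @return numeric vector of v non-negative standardized powers.
#' @export
localize <- function(transform, lf, m) {
  stopifnot(is(transform, "SloretaTransform"))
  if (length(m) != nrow(lf@gain))
    stop(sprintf("measurement length %d does not match %d electrodes",
                 length(m), nrow(lf@gain)))
  d <- transform@Tmat %*% m
  v <- nrow(lf@voxels)
  D <- matrix(d, nrow = 3)
  vapply(seq_len(v), function(i)
    as.numeric(crossprod(D[, i], transform@Sinv[, , i] %*% D[, i])), 0.0)
}

#' Partition voxels into electrode-nearest ROIs
#'
#' Assigns every voxel to the electrode with minimum Euclidean distance
#' ("all nearest voxels"); ties break towards the lowest electrode index.
#'
#' @param lf a \linkS4class{LeadField}.
#' @return a \linkS4class{RoiPartition} whose levels are the electrode
#'   labels.
#' @export
partitionRois <- function(lf) {
  stopifnot(is(lf, "LeadField"))
  epos <- as.matrix(lf@electrodes[, c("x", "y", "z")])
  d2 <- outer(rowSums(lf@voxels^2), rep(1, nrow(epos))) -
    2 * lf@voxels %*% t(epos) + outer(rep(1, nrow(lf@voxels)), rowSums(epos^2))
  nearest <- apply(d2, 1, which.min)     # which.min takes the first = lowest index
  new("RoiPartition",
      roi = factor(lf@electrodes$label[nearest], levels = lf@electrodes$label))
}

#' Transform sensor-space series to ROI-averaged source space
#'
#' For every time point the inverse operator yields the standardized power
#' of each voxel; ROI values are the means over the partition cells,
#' producing one source channel per electrode with the same number of time
#' points. Powers are non-negative by construction; \code{scale =
#' "amplitude"} returns their square roots.
#'
#' @param transform a \linkS4class{SloretaTransform}.
#' @param lf the matching \linkS4class{LeadField}.
#' @param partition a \linkS4class{RoiPartition} over the lead field's
#'   voxels.
#' @param sensorTs sensor-space \linkS4class{MultiTS} whose channel labels
#'   match the lead-field electrodes.
#' @param scale \code{"power"} (default, the standardized quadratic form)
#'   or \code{"amplitude"} (its square root).
#' @return a source-space \linkS4class{MultiTS} with one channel per ROI.
#' @export
toSourceSpace <- function(transform, lf, partition, sensorTs,
                          scale = c("power", "amplitude")) {
  scale <- match.arg(scale)
  stopifnot(is(sensorTs, "MultiTS"))
  labs <- channelLabels(sensorTs)
  if (is.null(labs) || !identical(labs, transform@electrodeLabels))
    stop("sensor channel labels do not match the lead-field electrodes")
  Xs <- sensorTs@values                  # N x c
  D <- transform@Tmat %*% t(Xs)          # 3v x N
  v <- nrow(lf@voxels); N <- nrow(Xs)
  pow <- matrix(0, v, N)
  for (i in seq_len(v)) {
    rows <- (3 * i - 3) + 1:3
    Di <- D[rows, , drop = FALSE]
    pow[i, ] <- colSums(Di * (transform@Sinv[, , i] %*% Di))
  }
  pow[pow < 0] <- 0                      # numerical guard; quadratic forms are >= 0
  if (scale == "amplitude") pow <- sqrt(pow)
  roi <- partition@roi
  if (length(roi) != v) stop("partition does not match the lead field")
  if (any(table(roi) == 0)) stop("empty ROI in the partition")
  agg <- rowsum(pow, roi, reorder = FALSE)
  agg <- agg / as.vector(table(roi)[rownames(agg)])
  out <- t(agg[match(levels(roi), rownames(agg)), , drop = FALSE])
  colnames(out) <- levels(roi)
  new("MultiTS", values = out, samplingInterval = sensorTs@samplingInterval,
      space = "source")
}
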