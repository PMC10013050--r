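# one small shared head model per test file run (building the inverse is
# the expensive part)
lfSmall <- synthesizeHeadModel(simulationElectrodes(), nVoxels = 220)
trSmall <- buildTransform(lfSmall)

test_that("the synthetic head model is well posed", {
  G <- gainMatrix(lfSmall)
  expect_true(all(is.finite(G)))
  expect_equal(qr(G)$rank, nrow(G))        # full row rank
  expect_true(all(sqrt(colSums(G^2)) > 0)) # every component visible
  # linearity: doubling the dipole moment doubles the potentials
  d <- rnorm(ncol(G))
  expect_equal(G %*% (2 * d), 2 * (G %*% d))
  expect_error(synthesizeHeadModel(c("FC3", "Bogus1")), "unknown electrode")
  expect_silent(synthesizeHeadModel(simulationElectrodes(), nVoxels = 150))
})

test_that("the inverse satisfies the forward constraint on the range of G", {
  G <- gainMatrix(lfSmall)
  set.seed(21)
  for (rep in 1:5) {
    d <- rnorm(ncol(G))
    m <- as.vector(G %*% d)
    dstar <- trSmall@Tmat %*% m
    expect_lt(max(abs(G %*% dstar - m)) / max(abs(m)), 1e-8)
  }
  # deterministic construction
  tr2 <- buildTransform(lfSmall)
  expect_equal(tr2@Tmat, trSmall@Tmat)
  # the Laplacian-weighted variant satisfies the same forward constraint
  trL <- buildTransform(lfSmall, smoothing = "laplacian")
  d <- rnorm(ncol(G)); m <- as.vector(G %*% d)
  expect_lt(max(abs(G %*% (trL@Tmat %*% m) - m)) / max(abs(m)), 1e-8)
})

test_that("the inverse matches a Lagrange-multiplier oracle on a toy problem", {
  # c = 4 electrodes, v = 3 voxels: solve min ||L W d|| s.t. G d = m by the
  # KKT system and compare with the operator
  lf <- synthesizeHeadModel(c("Cz", "C3", "C4", "Fz"), nVoxels = 40)
  lf <- new("LeadField", gain = lf@gain[, 1:9, drop = FALSE],
            electrodes = lf@electrodes, voxels = lf@voxels[1:3, , drop = FALSE],
            spacing = lf@spacing, radius = lf@radius)
  tr <- buildTransform(lf, smoothing = "laplacian")
  G <- lf@gain
  W <- diag(sqrt(colSums(G^2)))
  L <- as.matrix(causalspace:::latticeOperator(lf@voxels, lf@spacing))
  L3 <- kronecker(L, diag(3))
  M <- 2 * W %*% t(L3) %*% L3 %*% W
  set.seed(22)
  m <- rnorm(4)
  KKT <- rbind(cbind(M, t(G)), cbind(G, matrix(0, 4, 4)))
  sol <- solve(KKT, c(rep(0, 9), m))
  expect_equal(as.vector(tr@Tmat %*% m), sol[1:9], tolerance = 1e-6)
})

test_that("standardized power localizes noiseless single dipoles exactly", {
  G <- gainMatrix(lfSmall)
  v <- nrow(voxelPositions(lfSmall))
  set.seed(23)
  hits <- 0
  for (rep in 1:20) {
    vox <- sample(v, 1)
    q <- rnorm(3)
    m <- as.vector(G[, (3 * vox - 3) + 1:3] %*% q)
    pw <- localize(trSmall, lfSmall, m)
    expect_true(all(pw >= -1e-10))
    hits <- hits + (which.max(pw) == vox)
  }
  expect_equal(hits, 20)
  # quadratic form: scaling m by s scales powers by s^2
  m <- as.vector(G %*% rnorm(ncol(G)))
  expect_equal(localize(trSmall, lfSmall, 3 * m),
               9 * localize(trSmall, lfSmall, m))
  expect_equal(localize(trSmall, lfSmall, rep(0, nrow(G))), rep(0, v))
  expect_error(localize(trSmall, lfSmall, rep(0, 3)), "length")
})

test_that("ROI partition is disjoint, exhaustive and geometrically sane", {
  part <- partitionRois(lfSmall)
  roi <- roiLabels(part)
  expect_equal(length(roi), nrow(voxelPositions(lfSmall)))
  expect_false(anyNA(roi))
  expect_true(all(table(roi) > 0))         # every ROI non-empty
  # a voxel straight beneath Cz belongs to Cz
  vox <- voxelPositions(lfSmall)
  below <- which.max(vox[, 3] - abs(vox[, 1]) * 10 - abs(vox[, 2]) * 10)
  d2 <- colSums((t(as.matrix(lfSmall@electrodes[, c("x", "y", "z")])) - vox[below, ])^2)
  expect_equal(as.character(roi[below]),
               lfSmall@electrodes$label[which.min(d2)])
})

test_that("sensor series map to non-negative ROI power series", {
  part <- partitionRois(lfSmall)
  set.seed(24)
  X <- matrix(rnorm(50 * 20), 50, 20)
  colnames(X) <- simulationElectrodes()
  ts <- new("MultiTS", values = X, samplingInterval = 1, space = "sensor")
  src <- toSourceSpace(trSmall, lfSmall, part, ts)
  expect_equal(dim(values(src)), c(50, 20))
  expect_equal(spaceTag(src), "source")
  expect_true(all(values(src) >= 0))
  expect_equal(channelLabels(src), simulationElectrodes())
  # zero input gives zero output; the amplitude scale is the ROI mean of
  # voxel-level square roots, so its square is below the mean power (Jensen)
  Xz <- X * 0; colnames(Xz) <- simulationElectrodes()
  ts0 <- new("MultiTS", values = Xz, samplingInterval = 1, space = "sensor")
  expect_true(all(values(toSourceSpace(trSmall, lfSmall, part, ts0)) == 0))
  amp <- toSourceSpace(trSmall, lfSmall, part, ts, scale = "amplitude")
  expect_true(all(values(amp) >= 0))
  expect_true(all(values(amp)^2 <= values(src) + 1e-12))
  colnames(X) <- c(simulationElectrodes()[-1], "Oz")
  tsBad <- new("MultiTS", values = X, samplingInterval = 1, space = "sensor")
  expect_error(toSourceSpace(trSmall, lfSmall, part, tsBad), "labels")
})
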