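test_that("an uncoupled node follows the standard Henon map exactly", {
  ts <- simulateCHM(emptyNet(2), N = 4, transient = 0, init = matrix(0, 2, 2))
  x <- unname(values(ts))
  # from x0 = x1 = 0: x2 = 1.4, x3 = 1.4 - 1.4^2 = -0.56
  expect_equal(x[1, 1], 1.4)
  expect_equal(x[2, 1], -0.56)
  expect_equal(x[3, 1], 1.4 - 0.56^2 + 0.3 * 1.4)
})

test_that("decoupled Henon nodes with equal initials evolve identically", {
  init <- matrix(rep(c(0.1, 0.2), each = 5), 2, 5, byrow = TRUE)
  ts <- values(simulateCHM(emptyNet(5), N = 100, transient = 100, init = init))
  for (j in 2:5) expect_equal(ts[, j], ts[, 1])
})

test_that("coupled Henon simulation is bit-reproducible under seed", {
  net <- setStrengths(edgeNet(2, list(c(1, 2))), 0.2)
  a <- simulateCHM(net, N = 128, seed = 11)
  b <- simulateCHM(net, N = 128, seed = 11)
  expect_identical(values(a), values(b))
})

test_that("Henon divergence raises an instability error naming the node", {
  net <- setStrengths(edgeNet(2, list(c(1, 2))), 50)
  expect_error(simulateCHM(net, N = 100, seed = 1), "node")
})

test_that("a node with no couplings and no self-term decays as exp(-0.1 t)", {
  ts <- simulateCMG(emptyNet(2), N = 3, sampleStep = 4, transient = 0,
                    selfCoupling = 0, history = 1)
  expect_equal(unname(values(ts)[, 1]), exp(-0.4 * (1:3)), tolerance = 1e-9)
})

test_that("halving the integration step barely changes the trajectory", {
  net <- setStrengths(edgeNet(2, list(c(1, 2))), 0.1)
  a <- values(simulateCMG(net, N = 100, h = 0.1, transient = 200, history = 1.1))
  b <- values(simulateCMG(net, N = 100, h = 0.05, transient = 200, history = 1.1))
  expect_lt(sqrt(mean((a - b)^2)), 1e-4)
})

test_that("the fixed-step integrator matches an adaptive DDE solver", {
  skip_if_not_installed("deSolve")
  # single chaotic Mackey-Glass unit over a short horizon
  f <- function(t, y, parms) {
    ylag <- if (t < 100) 1.1 else deSolve::lagvalue(t - 100)
    list(-0.1 * y + 0.2 * ylag / (1 + ylag^10))
  }
  ref <- deSolve::dede(y = 1.1, times = seq(0, 200, by = 4), func = f,
                       parms = NULL, control = list(mxhist = 1e5))
  mine <- values(simulateCMG(emptyNet(2), N = 50, transient = 0, history = 1.1))[, 1]
  expect_lt(max(abs(mine - ref[-1, 2])), 1e-3)
})

test_that("Mackey-Glass output is bounded chaos at the reference coupling", {
  net <- setStrengths(generateNetwork("RAND", 5, seed = 2), 0.1)
  x <- values(simulateCMG(net, N = 500, seed = 3))
  expect_true(all(is.finite(x)))
  expect_true(all(abs(x) < 3))
  expect_true(all(apply(x, 2, sd) > 0.05))   # not collapsed to a fixed point
  a <- values(simulateCMG(net, N = 50, seed = 9))
  b <- values(simulateCMG(net, N = 50, seed = 9))
  expect_identical(a, b)
})

test_that("stabilizeVar shrinks to the stationary region", {
  expect_equal(stabilizeVar(emptyNet(3))@A, diag(3) * 0,
               ignore_attr = TRUE)
  # a single off-diagonal entry is nilpotent: no shrinking needed
  p1 <- stabilizeVar(edgeNet(3, list(c(1, 2))))
  expect_equal(max(abs(p1@A)), 0.9)
  # dense support requires shrinking but terminates below 1 - margin
  dense <- emptyNet(6)
  v <- matrix(1, 6, 6); diag(v) <- 0
  dense <- initialize(dense, values = v)
  pd <- stabilizeVar(dense)
  expect_lt(max(Mod(eigen(pd@A)$values)), 0.95)
  expect_gt(max(pd@A), 0)
})

test_that("VAR simulation matches white-noise and AR(1) theory", {
  # A = 0: i.i.d. N(0,1)
  p0 <- new("VarProcess", A = matrix(0, 3, 3), noiseCov = diag(3), order = 1L)
  x <- values(simulateVar(p0, N = 2048, seed = 4))
  expect_lt(max(abs(apply(x, 2, var) - 1)), 3 * sqrt(2 / 2048) * 1.5)
  # K = 1, A = 0.5: lag-1 autocorrelation near 0.5
  p1 <- new("VarProcess", A = matrix(0.5, 1, 1), noiseCov = diag(1), order = 1L)
  y <- values(simulateVar(p1, N = 2048, seed = 5))[, 1]
  r1 <- cor(y[-1], y[-length(y)])
  expect_lt(abs(r1 - 0.5), 0.06)
  expect_identical(values(simulateVar(p1, N = 64, seed = 6)),
                   values(simulateVar(p1, N = 64, seed = 6)))
  bad <- new("VarProcess", A = matrix(1.2, 1, 1), noiseCov = diag(1), order = 1L)
  expect_error(simulateVar(bad), "stationary")
})

test_that("similarity transforms preserve eigenvalues and diagonalize", {
  set.seed(8)
  # H = identity leaves the process unchanged
  A0 <- matrix(rnorm(16, sd = 0.2), 4, 4)
  p <- new("VarProcess", A = A0, noiseCov = diag(4), order = 1L)
  tv <- transformVar(p, diag(4))
  expect_equal(tv$transform@B, A0)
  for (rep in 1:20) {
    A <- matrix(rnorm(25, sd = 0.3), 5, 5)   # distinct eigenvalues a.s.
    p <- new("VarProcess", A = A, noiseCov = diag(5), order = 1L)
    H <- matrix(rnorm(25), 5, 5)
    tv <- transformVar(p, H)
    evA <- sort(eigen(A, only.values = TRUE)$values)
    evB <- sort(eigen(tv$transform@B, only.values = TRUE)$values)
    expect_lt(max(Mod(evA - evB)), 1e-8)
    # H = inverse eigenvector matrix makes B diagonal (complex-safe check
    # through the real representation when eigenvalues are complex)
    Q <- eigen(A)$vectors
    Hq <- solve(Q)
    B <- Hq %*% A %*% Q
    offMass <- sum(Mod(B - diag(diag(B)))^2) / sum(Mod(B)^2)
    expect_lt(offMass, 1e-16)
  }
  expect_error(transformVar(p, matrix(0, 5, 5)), "singular")
})

test_that("transformed processes carry the mixed noise covariance", {
  set.seed(9)
  A <- matrix(rnorm(9, sd = 0.2), 3, 3)
  p <- new("VarProcess", A = A, noiseCov = diag(3), order = 1L)
  H <- matrix(rnorm(9), 3, 3)
  tv <- transformVar(p, H)
  expect_equal(tv$process@noiseCov, H %*% t(H))
  expect_equal(tv$process@A, H %*% A %*% solve(H))
})
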