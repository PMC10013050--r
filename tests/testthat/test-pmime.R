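test_that("an independent target yields an empty embedding at the test level", {
  set.seed(40)
  empties <- vapply(1:40, function(i) {
    x <- matrix(rnorm(600 * 3), 600, 3)
    nrow(mixedEmbedding(x, 1, Lmax = 3, seed = i))
  }, 0.0)
  # the first-step gate is an exact level-0.05 randomization test
  expect_lte(mean(empties > 0), 0.15)
})

test_that("a deterministic copy selects its source first", {
  hits <- vapply(1:30, function(i) {
    set.seed(5000 + i)
    x <- matrix(rnorm(600 * 3), 600, 3)
    x[-1, 2] <- x[-600, 1]              # y_{t+1} = x_{1,t}
    emb <- mixedEmbedding(x, 2, Lmax = 3, seed = i)
    nrow(emb) >= 1 && emb$var[1] == 1 && emb$lag[1] == 1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the embedding never exceeds the configured cap", {
  net <- setStrengths(generateNetwork("RAND", 6, seed = 2), 0.2)
  ts <- simulateCHM(net, N = 512, seed = 3)
  emb <- mixedEmbedding(ts, 1, Lmax = 5, maxTerms = 4, seed = 4)
  expect_lte(nrow(emb), 4)
  emb10 <- mixedEmbedding(ts, 1, Lmax = 5, seed = 4)
  expect_lte(nrow(emb10), 10)
})

test_that("constant channels are excluded from the candidate set", {
  set.seed(41)
  x <- matrix(rnorm(400 * 3), 400, 3)
  x[, 3] <- 7
  expect_warning(emb <- mixedEmbedding(x, 1, Lmax = 2), "constant")
  expect_false(any(emb$var == 3))
  x[, 1] <- 0
  expect_error(suppressWarnings(mixedEmbedding(x, 1, Lmax = 2)), "constant")
})

test_that("pmime values are a normalized measure on [0, 1] with zero diagonal", {
  net <- setStrengths(generateNetwork("SW", 8, seed = 5), 0.2)
  ts <- simulateCHM(net, N = 512, seed = 6)
  cm <- pmime(ts, Lmax = 3, seed = 7)
  v <- values(cm)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diag(v) == 0))
  expect_identical(measureTag(cm), "PMIME")
  # zero exactly where the embedding holds no driver lag
  for (j in 1:8) {
    emb <- mixedEmbedding(ts, j, Lmax = 3,
                          seed = causalspace:::subSeed(7, 101L, j))
    absent <- setdiff(1:8, unique(emb$var))
    expect_true(all(v[setdiff(absent, j), j] == 0))
  }
})

test_that("a unidirectional Henon pair is oriented correctly", {
  correct <- vapply(1:25, function(i) {
    net <- setStrengths(edgeNet(2, list(c(1, 2))), 0.2)
    ts <- simulateCHM(net, N = 1024, seed = 6000 + i)
    v <- values(pmime(ts, Lmax = 5, seed = i))
    v[1, 2] > 0 && v[2, 1] == 0
  }, TRUE)
  expect_gte(mean(correct), 0.8)
})

test_that("decoupled channels show (almost) no cross-channel PMIME", {
  set.seed(42)
  ts <- simulateCHM(emptyNet(6), N = 1024,
                    init = matrix(runif(12, -0.3, 0.3), 2, 6))
  v <- values(pmime(ts, Lmax = 5, seed = 43))
  expect_lt(mean(v[row(v) != col(v)] > 0), 0.1)
})
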