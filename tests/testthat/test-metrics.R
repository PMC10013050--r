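test_that("binarize keeps any positive entry and is idempotent", {
  m <- matrix(c(0, 0.001, 0, 0, 0, 5, 0.2, 0, 0), 3, 3)
  b <- binarize(m)
  expect_true(all(b %in% c(0, 1)))
  expect_equal(sum(b), 3)
  expect_identical(binarize(b), b)
  expect_equal(sum(binarize(matrix(0, 3, 3))), 0)
  diag(m) <- 9
  expect_true(all(diag(binarize(m)) == 0))
})

test_that("closed-form graphs give their textbook metric values", {
  # complete graph on 4 nodes
  k4 <- 1 - diag(4)
  mv <- computeMetrics(k4, seed = 1)
  expect_equal(mv[["degMean"]], 3)
  expect_equal(mv[["degSD"]], 0)
  expect_equal(mv[["lambda"]], 1)
  expect_true(is.nan(mv[["r"]]))   # zero degree variance
  # path graph 1-2-3: lambda = (1+1+2)/3
  p3 <- matrix(0, 3, 3); p3[1, 2] <- 1; p3[2, 3] <- 1
  expect_equal(computeMetrics(p3, seed = 1)[["lambda"]], 4 / 3)
  # star on 10 nodes: hubs attach to leaves, so assortativity is negative
  s10 <- matrix(0, 10, 10); s10[1, 2:10] <- 1
  expect_lt(computeMetrics(s10, seed = 1)[["r"]], 0)
  # ring lattice is regular
  ring <- values(generateNetwork("SW", 12,
                                 params = list(ringDegree = 4, rewire = 0),
                                 seed = 1))
  expect_equal(computeMetrics(ring, seed = 1)[["degSD"]], 0)
})

test_that("empty graphs yield undefined metrics, not zeros", {
  mv <- computeMetrics(matrix(0, 5, 5), seed = 1)
  expect_true(all(is.nan(mv)))
  expect_true(attr(mv, "lowConnectivity"))
})

test_that("metrics are invariant under node relabeling", {
  set.seed(20)
  a <- binarize(matrix(rbinom(64, 1, 0.3), 8, 8))
  perm <- sample(8)
  b <- a[perm, perm]
  expect_equal(computeMetrics(a, seed = 5)[c("degMean", "degSD", "lambda", "r")],
               computeMetrics(b, seed = 5)[c("degMean", "degSD", "lambda", "r")])
})

test_that("path length and clustering match brute-force oracles on small graphs", {
  floydLambda <- function(sym) {
    n <- nrow(sym)
    d <- matrix(Inf, n, n); d[sym == 1] <- 1; diag(d) <- 0
    for (k in 1:n) for (i in 1:n) for (j in 1:n)
      if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    off <- d[row(d) != col(d)]
    mean(off[is.finite(off)])
  }
  localClustering <- function(sym) {
    n <- nrow(sym)
    mean(vapply(1:n, function(i) {
      nb <- which(sym[i, ] == 1)
      if (length(nb) < 2) return(0)
      sum(sym[nb, nb]) / (length(nb) * (length(nb) - 1))
    }, 0.0))
  }
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    a <- matrix(rbinom(n * n, 1, runif(1, 0.2, 0.7)), n, n)
    sym <- binarize(a); sym <- 1 * ((sym + t(sym)) > 0)
    if (sum(sym) == 0) next
    mv <- computeMetrics(a, seed = 2)
    expect_equal(mv[["lambda"]], floydLambda(sym), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected")
    expect_equal(igraph::transitivity(g, type = "localaverage", isolates = "zero"),
                 localClustering(sym), tolerance = 1e-12)
  }
})

test_that("class-averaged separations behind the discrimination study hold", {
  swi <- dsd <- list(RAND = c(), SW = c(), SCF = c())
  for (tp in names(swi)) for (i in 1:40) {
    mv <- computeMetrics(generateNetwork(tp, 20, seed = 4000 + i), seed = i)
    swi[[tp]] <- c(swi[[tp]], mv[["SWi"]])
    dsd[[tp]] <- c(dsd[[tp]], mv[["degSD"]])
  }
  expect_gt(mean(swi$SW), mean(swi$RAND))
  expect_gt(mean(dsd$SCF), mean(dsd$RAND))
})
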