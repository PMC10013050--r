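test_that("degenerate densities give the expected edge counts", {
  expect_equal(sum(values(generateNetwork("RAND", 20, params = list(p = 0),
                                          seed = 1))), 0)
  # unrewired ring lattice: exactly n*k/2 undirected edges before orientation
  sw <- generateNetwork("SW", 20, params = list(ringDegree = 4, rewire = 0),
                        seed = 1)
  expect_equal(sum(values(sw)), 40)
  # bidirectional orientation doubles the directed edge count
  sw2 <- generateNetwork("SW", 20, params = list(ringDegree = 4, rewire = 0),
                         bidirectional = TRUE, seed = 1)
  expect_equal(sum(values(sw2)), 80)
})

test_that("generation is bit-reproducible under a seed", {
  for (tp in c("RAND", "SW", "SCF")) {
    a <- generateNetwork(tp, 20, seed = 42)
    b <- generateNetwork(tp, 20, seed = 42)
    expect_identical(values(a), values(b))
  }
})

test_that("each skeleton edge gets exactly one direction by default", {
  net <- values(generateNetwork("RAND", 20, seed = 7))
  expect_true(all(net + t(net) <= 1))
  expect_true(all(diag(net) == 0))
})

test_that("edge counts match the class's analytic expectation over draws", {
  nDraw <- 100
  counts <- vapply(seq_len(nDraw), function(i)
    sum(values(generateNetwork("RAND", 20, seed = 1000 + i))), 0.0)
  # binomial(190, 0.35): mean 66.5, sd 6.6; the mean of 100 draws has
  # standard error 0.66
  expect_lt(abs(mean(counts) - 190 * 0.35), 4 * 6.6 / sqrt(nDraw))
  swCounts <- vapply(seq_len(20), function(i)
    sum(values(generateNetwork("SW", 20, seed = 2000 + i))), 0.0)
  expect_true(all(swCounts == 40))   # rewiring preserves the edge count
})

test_that("degree-SD ordering SCF > RAND > SW holds on class averages", {
  dsd <- function(tp, i) {
    v <- values(generateNetwork(tp, 20, seed = 3000 + i))
    sd(colSums(v + t(v)))
  }
  m <- vapply(c("RAND", "SW", "SCF"), function(tp)
    mean(vapply(1:60, function(i) dsd(tp, i), 0.0)), 0.0)
  expect_gt(m[["SCF"]], m[["RAND"]])
  expect_gt(m[["RAND"]], m[["SW"]])
})

test_that("setStrengths dresses every edge with the uniform coupling", {
  expect_equal(sum(values(setStrengths(emptyNet(4), 0.2))), 0)
  one <- edgeNet(3, list(c(1, 2)))
  dressed <- setStrengths(one, 0.2)
  expect_equal(values(dressed)[1, 2], 0.2)
  expect_equal(sum(values(dressed)), 0.2)
  net <- generateNetwork("RAND", 20, seed = 5)
  expect_equal(sum(values(setStrengths(net, 0.2))), 0.2 * sum(values(net)))
  expect_error(setStrengths(net, -1), "positive")
})

test_that("invalid generation parameters are rejected", {
  expect_error(generateNetwork("RAND", 20, params = list(p = 1.5)), "probability")
  expect_error(generateNetwork("SW", 20, params = list(ringDegree = 3)), "even")
  expect_error(generateNetwork("SCF", 20, params = list(attach = 0)), "attachment")
})

test_that("networks round-trip through edge-list TSV with JSON sidecar", {
  dir <- withr::local_tempdir()
  net <- setStrengths(generateNetwork("SW", 10, seed = 9), 0.1)
  writeNetwork(net, file.path(dir, "net"))
  back <- readNetwork(file.path(dir, "net"))
  expect_identical(values(back), values(net))
  expect_identical(topologyType(back), "SW")
  expect_true(file.exists(file.path(dir, "net.graphml")))
})
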