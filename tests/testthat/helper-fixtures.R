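# small deterministic fixtures shared across tests

emptyNet <- function(K = 4) {
  lab <- paste0("X", seq_len(K))
  new("CouplingMatrix", values = matrix(0, K, K, dimnames = list(lab, lab)),
      topology = "RAND")
}

edgeNet <- function(K, edges, C = 1) {
  # edges: matrix/list of (from, to)
  net <- emptyNet(K)
  v <- net@values
  for (e in edges) v[e[1], e[2]] <- C
  initialize(net, values = v)
}

# folded AUROC by exhaustive pair counting (ties half) - oracle
aurocOracle <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  A <- s / (length(a) * length(b))
  max(A, 1 - A)
}
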