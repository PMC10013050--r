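#' Binarize a causality matrix
#'
#' Every strictly positive off-diagonal value becomes an edge, regardless
#' of magnitude (both causality measures carry their own internal
#' significance decision, so a positive value already means "driving
#' detected"). Idempotent.
#'
#' @param cm a \linkS4class{CausalityMatrix}, \linkS4class{CouplingMatrix}
#'   or numeric matrix.
#' @return 0/1 adjacency matrix with zero diagonal.
#' @export
binarize <- function(cm) {
  v <- if (is(cm, "CausalityMatrix") || is(cm, "CouplingMatrix")) values(cm)
       else cm
  a <- (v > 0) * 1
  diag(a) <- 0
  a
}

#' Five graph metrics of a binarized network
#'
#' Computes, on the symmetrized graph (an undirected edge wherever either
#' direction is present): the mean and standard deviation of the degree
#' distribution, the characteristic path length (mean shortest-path length
#' over connected ordered pairs), the small-worldness index
#' \eqn{SWi = (C / C_{rand}) / (\lambda / \lambda_{rand})} with C the mean
#' local clustering coefficient and the reference terms averaged over
#' \code{nReference} random graphs with the same node and edge count, and
#' the degree assortativity (Pearson correlation of end-point degrees over
#' edges).
#'
#' Degenerate cases return NaN rather than zero: an empty graph yields NaN
#' for every metric, a graph with no degree variance yields NaN
#' assortativity. When fewer than half of the node pairs are connected the
#' result carries attribute \code{"lowConnectivity" = TRUE}.
#'
#' @param adjacency 0/1 matrix (directed or undirected) or any object
#'   accepted by [binarize()].
#' @param nReference number of sampled reference graphs for SWi.
#' @param seed RNG seed for the reference graphs.
#' @return named numeric vector \code{c(SWi, degMean, degSD, lambda, r)}.
#' @export
computeMetrics <- function(adjacency, nReference = 20, seed = NULL) {
  a <- binarize(adjacency)
  if (nrow(a) < 2) stop("need at least 2 nodes")
  sym <- 1 * ((a + t(a)) > 0)
  g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected")
  n <- igraph::gorder(g); m <- igraph::gsize(g)
  if (m == 0) {
    out <- c(SWi = NaN, degMean = NaN, degSD = NaN, lambda = NaN, r = NaN)
    attr(out, "lowConnectivity") <- TRUE
    return(out)
  }
  deg <- igraph::degree(g)
  lam <- igraph::mean_distance(g, unconnected = TRUE)
  C <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  swi <- withSeed(seed, {
    Cr <- numeric(nReference); Lr <- numeric(nReference)
    for (i in seq_len(nReference)) {
      gr <- igraph::sample_gnm(n, m)
      Cr[i] <- igraph::transitivity(gr, type = "localaverage", isolates = "zero")
      Lr[i] <- igraph::mean_distance(gr, unconnected = TRUE)
    }
    (C / mean(Cr)) / (lam / mean(Lr))
  })
  r <- if (stats::sd(deg) == 0) NaN else igraph::assortativity_degree(g)
  out <- c(SWi = swi, degMean = mean(deg), degSD = stats::sd(deg),
           lambda = lam, r = r)
  dmat <- igraph::distances(g)
  connFrac <- mean(is.finite(dmat[upper.tri(dmat)]))
  if (connFrac < 0.5) attr(out, "lowConnectivity") <- TRUE
  out
}

#' Names of the five graph metrics, in reporting order
#' @return character vector.
#' @export
metricNames <- function() c("SWi", "degMean", "degSD", "lambda", "r")
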