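## Functional connectivity by normalized mutual information, weighted graph
## metrics with null-model normalization, and the paired max-statistic
## permutation test.

.defaultBins <- function(n) max(2L, as.integer(ceiling(sqrt(n))))

.binSeries <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(NULL)  # constant series: zero entropy
  b <- seq(r[1], r[2], length.out = bins + 1)
  i <- findInterval(x, b, rightmost.closed = TRUE, all.inside = TRUE)
  i
}

#' Shannon entropy of a series (equal-width histogram estimator)
#'
#' @param x Numeric series.
#' @param bins Number of equal-width bins (default `ceiling(sqrt(length(x)))`).
#' @return Entropy in bits, in `[0, log2(bins)]`; a constant series has zero
#'   entropy.
#' @examples
#' shannonEntropy(rep(0:1, 50), bins = 2)  # 1 bit
#' @export
shannonEntropy <- function(x, bins = .defaultBins(length(x))) {
  if (length(x) == 0) stop("empty series")
  if (bins < 2) stop("need at least 2 bins")
  if (length(x) < bins) stop("series shorter than the bin count")
  i <- .binSeries(x, bins)
  if (is.null(i)) return(0)
  p <- tabulate(i, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized mutual information of two series
#'
#' Histogram mutual information normalized by the geometric mean of the two
#' marginal entropies, \eqn{NMI = I(X;Y)/\sqrt{H(X) H(Y)}}: symmetric,
#' bounded in `[0, 1]`, equal to 1 for identical series and near 0 for
#' independent ones. A constant series carries no measurable shared
#' information; the coefficient is defined as 0 in that case (with a
#' warning).
#'
#' @param x,y Numeric series of equal length.
#' @param bins Number of equal-width bins per axis.
#' @return NMI coefficient in `[0, 1]`.
#' @export
nmi <- function(x, y, bins = .defaultBins(length(x))) {
  if (length(x) != length(y)) stop("series lengths differ")
  n <- length(x)
  ix <- .binSeries(x, bins)
  iy <- .binSeries(y, bins)
  if (is.null(ix) || is.null(iy)) {
    warning("constant series: NMI defined as 0")
    return(0)
  }
  joint <- tabulate((ix - 1L) * bins + iy, nbins = bins * bins) / n
  px <- tabulate(ix, nbins = bins) / n
  py <- tabulate(iy, nbins = bins) / n
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  if (hx == 0 || hy == 0) {
    warning("degenerate binning: NMI defined as 0")
    return(0)
  }
  pj <- joint[joint > 0]
  hxy <- -sum(pj * log2(pj))
  mi <- hx + hy - hxy
  min(1, max(0, mi / sqrt(hx * hy)))
}

#' NMI functional-connectivity matrix
#'
#' Pairwise NMI coefficients between all regional time series.
#'
#' @param signals A [BoldSignal-class] or numeric matrix (time x regions).
#' @param bins Histogram bin count (default `ceiling(sqrt(nrow))`).
#' @param source Free-form source tag stored with the network.
#' @return An [NmiNetwork-class]: symmetric, unit diagonal, entries in
#'   `[0, 1]`.
#' @export
nmiMatrix <- function(signals, bins = NULL, source = "model") {
  x <- if (is(signals, "BoldSignal")) signals@series else as.matrix(signals)
  N <- ncol(x)
  if (N < 2) stop("need at least 2 regions")
  if (is.null(bins)) bins <- .defaultBins(nrow(x))
  m <- diag(1, N)
  for (i in seq_len(N - 1))
    for (j in (i + 1):N)
      m[i, j] <- m[j, i] <- nmi(x[, i], x[, j], bins)
  if (is(signals, "BoldSignal")) dimnames(m) <- list(signals@labels, signals@labels)
  new("NmiNetwork", values = m, bins = as.integer(bins), source = source)
}

.asWeights <- function(W) {
  w <- if (is(W, "NmiNetwork")) W@values else as.matrix(W)
  diag(w) <- 0
  w
}

#' Nodal strength
#'
#' Sum of the edge weights attached to each node,
#' \eqn{s_i = \sum_{j \ne i} w_{ij}}.
#'
#' @param W An [NmiNetwork-class] or weight matrix (diagonal ignored).
#' @return Numeric vector of per-node strengths.
#' @export
nodalStrength <- function(W) {
  rowSums(.asWeights(W))
}

#' Nodal degree
#'
#' Number of edges with strictly positive weight attached to each node.
#'
#' @inheritParams nodalStrength
#' @return Integer vector of per-node degrees in `[0, N - 1]`.
#' @export
nodalDegree <- function(W) {
  as.integer(rowSums(.asWeights(W) > 0))
}

#' Onnela weighted clustering coefficient
#'
#' Average geometric mean of edge weights over the triangles around each
#' node, with weights scaled by the network maximum:
#' \eqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j,h}
#'   (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3}},
#' \eqn{\hat w = w / \max w}. Nodes with fewer than two neighbors have
#' \eqn{C_i = 0}.
#'
#' @inheritParams nodalStrength
#' @return Numeric vector of per-node clustering coefficients.
#' @export
weightedClustering <- function(W) {
  w <- .asWeights(W)
  mx <- max(w)
  if (mx == 0) return(rep(0, nrow(w)))
  cw <- (w / mx)^(1 / 3)
  tri <- diag(cw %*% cw %*% cw)
  k <- rowSums(w > 0)
  out <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  as.numeric(out)
}

#' Latora local efficiency
#'
#' Mean inverse shortest-path length within each node's neighborhood
#' subgraph, with edge lengths taken as inverse weights:
#' \eqn{E_i = \frac{1}{k_i (k_i - 1)} \sum_{j \ne h \in N(i)} 1 / d_{jh}},
#' where \eqn{d_{jh}} is the shortest path between neighbors `j` and `h`
#' using only nodes of the neighborhood. Nodes with fewer than two neighbors
#' have \eqn{E_i = 0}; disconnected neighbor pairs contribute 0.
#'
#' @inheritParams nodalStrength
#' @return Numeric vector of per-node local efficiencies.
#' @export
localEfficiency <- function(W) {
  w <- .asWeights(W)
  N <- nrow(w)
  out <- numeric(N)
  for (i in seq_len(N)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                           algorithm = "dijkstra")
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  out
}

#' Null-model ensemble of random networks
#'
#' Conservative surrogates preserving the network's size, density and the
#' full multiset of edge weights: the weights are reassigned to a uniformly
#' random topology with the same number of edges (for a fully connected
#' network this is a pure weight shuffle). The diagonal is preserved.
#'
#' @inheritParams nodalStrength
#' @param n Number of surrogates (default 100).
#' @param seed Integer seed.
#' @return List of `n` weight matrices.
#' @export
nullEnsemble <- function(W, n = 100, seed = 1L) {
  w0 <- if (is(W, "NmiNetwork")) W@values else as.matrix(W)
  w <- w0
  diag(w) <- 0
  N <- nrow(w)
  up <- which(upper.tri(w))
  wts <- w[up][w[up] > 0]
  m <- length(wts)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(.substreamSeed(seed, "null-models"))
  lapply(seq_len(n), function(k) {
    pos <- if (m == length(up)) up else sample(up, m)
    s <- matrix(0, N, N)
    s[pos] <- sample(wts, m)
    s <- s + t(s)
    diag(s) <- diag(w0)
    s
  })
}

#' Null-normalized clustering and efficiency
#'
#' Divides each node's observed clustering and local efficiency by the mean
#' of the same node's values over the null ensemble.
#'
#' @inheritParams nodalStrength
#' @param ensemble List of surrogate weight matrices
#'   (see [nullEnsemble()]).
#' @return List with `clusteringNorm` and `efficiencyNorm`; a zero ensemble
#'   mean yields `NA` for that node.
#' @export
normalizedMetrics <- function(W, ensemble) {
  if (!length(ensemble)) stop("ensemble must be non-empty")
  cObs <- weightedClustering(W)
  eObs <- localEfficiency(W)
  cNull <- rowMeans(vapply(ensemble, weightedClustering, numeric(length(cObs))))
  eNull <- rowMeans(vapply(ensemble, localEfficiency, numeric(length(eObs))))
  ratio <- function(obs, nul) ifelse(nul > 0, obs / nul, NA_real_)
  list(clusteringNorm = ratio(cObs, cNull), efficiencyNorm = ratio(eObs, eNull))
}

#' All graph metrics of a weighted network
#'
#' Convenience wrapper computing strength, degree, Onnela clustering, Latora
#' local efficiency and (optionally) their null-normalized versions.
#'
#' @inheritParams nodalStrength
#' @param nNull Number of null models (0 disables normalization).
#' @param seed Seed for the null ensemble.
#' @return A [GraphMetricsResult-class].
#' @export
graphMetrics <- function(W, nNull = 100, seed = 1L) {
  labels <- if (is(W, "NmiNetwork") && !is.null(rownames(W@values)))
    rownames(W@values) else sprintf("R%02d", seq_len(nrow(.asWeights(W))))
  df <- data.frame(node = labels,
                   strength = nodalStrength(W),
                   degree = nodalDegree(W),
                   clustering = weightedClustering(W),
                   efficiency = localEfficiency(W),
                   clusteringNorm = NA_real_,
                   efficiencyNorm = NA_real_,
                   stringsAsFactors = FALSE)
  if (nNull > 0) {
    ens <- nullEnsemble(W, n = nNull, seed = seed)
    nm <- normalizedMetrics(W, ens)
    df$clusteringNorm <- nm$clusteringNorm
    df$efficiencyNorm <- nm$efficiencyNorm
  }
  new("GraphMetricsResult", metrics = df, nNull = as.integer(nNull),
      seed = as.integer(seed))
}

#' Paired two-sample permutation test with max-statistic FWE control
#'
#' Tests, node by node, whether a metric differs between two paired
#' conditions. `a` and `b` are matrices with one row per paired replicate
#' (seed, subject) and one column per node. The per-node statistic is the
#' mean paired difference; under the null the sign of each replicate's
#' difference vector is exchangeable, so the null distribution is built by
#' random sign flips of whole replicates. Family-wise error control uses the
#' maximal statistic: each node's adjusted p-value is the fraction of
#' permutations whose maximum absolute statistic (over all nodes) reaches
#' that node's observed absolute statistic, with the identity permutation
#' included.
#'
#' @param a,b Numeric matrices (replicates x nodes) of paired metric values;
#'   vectors are treated as a single node.
#' @param nPerm Number of random sign flips (ignored when `exhaustive`).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `2^R` sign patterns (exact test; requires
#'   a modest number of replicates).
#' @return A [PermutationTestResult-class].
#' @export
pairedPermutationTest <- function(a, b, nPerm = 1000, seed = 1L,
                                  exhaustive = FALSE) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  if (!all(dim(a) == dim(b))) stop("a and b must have identical dimensions")
  d <- a - b
  R <- nrow(d)
  if (R < 2 && !exhaustive)
    stop("need at least two paired replicates per node")
  obs <- colMeans(d)
  if (exhaustive) {
    if (R > 20) stop("exhaustive enumeration limited to 20 replicates")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), R)))
    nPerm <- nrow(signs)
    seedUsed <- NA_integer_
  } else {
    old <- .saveSeed(); on.exit(.restoreSeed(old))
    seedUsed <- .substreamSeed(seed, "permutation")
    set.seed(seedUsed)
    signs <- matrix(sample(c(-1, 1), nPerm * R, replace = TRUE), nPerm, R)
  }
  perm <- abs(signs %*% d) / R
  nullMax <- apply(perm, 1, max)
  if (exhaustive) {
    p <- vapply(abs(obs), function(o) mean(nullMax >= o - 1e-12), numeric(1))
  } else {
    p <- vapply(abs(obs),
                function(o) (1 + sum(nullMax >= o - 1e-12)) / (nPerm + 1),
                numeric(1))
  }
  if (all(d == 0)) p[] <- 1
  new("PermutationTestResult", observed = obs, nullMax = as.numeric(nullMax),
      pFWE = p, nPerm = as.integer(nPerm), seed = as.integer(seedUsed),
      exhaustive = exhaustive)
}
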