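test_that("histogram entropy matches closed-form values on designed series", {
  expect_equal(shannonEntropy(rep(3.7, 100), bins = 8), 0)
  expect_equal(shannonEntropy(rep(c(0, 1), 50), bins = 2), 1)
  x4 <- rep(c(0, 1, 2, 3), 25)
  expect_equal(shannonEntropy(x4, bins = 4), 2)
  expect_lte(shannonEntropy(rnorm(500), bins = 8), 3)
  expect_error(shannonEntropy(numeric(0)), "empty")
  expect_error(shannonEntropy(1:10, bins = 20), "shorter")
})

test_that("NMI is 1 on identical series, symmetric, and small under independence", {
  set.seed(10)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_equal(nmi(x, x, bins = 16), 1)
  expect_lt(nmi(x, y, bins = 16), 0.05)
  for (k in 1:5) {
    a <- rnorm(500); b <- rnorm(500)
    expect_equal(nmi(a, b), nmi(b, a))
    expect_gte(nmi(a, b), 0)
    expect_lte(nmi(a, b), 1)
  }
  expect_warning(v <- nmi(rep(1, 100), rnorm(100)), "constant")
  expect_equal(v, 0)
})

test_that("NMI matrix is symmetric with unit diagonal and matches pairwise calls", {
  set.seed(11)
  x <- matrix(rnorm(300 * 4), 300, 4)
  x[, 4] <- x[, 1]  # duplicated region
  net <- nmiMatrix(x, bins = 8)
  v <- nmiValues(net)
  expect_equal(v, t(v))
  expect_equal(diag(v), rep(1, 4))
  expect_equal(v[1, 4], 1)
  expect_equal(v[2, 3], nmi(x[, 2], x[, 3], bins = 8))
  expect_true(all(v >= 0 & v <= 1))
  ## independent panel: off-diagonals near zero
  big <- matrix(rnorm(5e3 * 3), 5e3, 3)
  vb <- nmiValues(nmiMatrix(big, bins = 16))
  expect_lt(max(vb[upper.tri(vb)]), 0.05)
})

test_that("nodal strength and degree match hand-computed and oracle values", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- 0.8
  expect_equal(nodalStrength(w), c(0.6, 1.0, 1.2))
  expect_equal(nodalDegree(w), c(2L, 2L, 2L))
  u <- matrix(0.3, 5, 5)
  expect_equal(nodalStrength(u), rep(4 * 0.3, 5))
  expect_equal(nodalDegree(u), rep(4L, 5))
  expect_equal(nodalStrength(matrix(0, 4, 4)), rep(0, 4))
  w2 <- u; w2[1, 2] <- w2[2, 1] <- 0
  expect_equal(nodalDegree(w2), c(3L, 3L, 4L, 4L, 4L))
})

test_that("graph metrics equal brute-force oracles on random weighted graphs", {
  for (k in 1:20) {
    N <- sample(4:10, 1)
    w <- randomNet(N, density = runif(1, 0.5, 1), seed = 200 + k)
    expect_lt(max(abs(nodalStrength(w) - oracleStrength(w))), 1e-12)
    expect_lt(max(abs(weightedClustering(w) - oracleOnnela(w))), 1e-12)
    expect_lt(max(abs(localEfficiency(w) - oracleLatora(w))), 1e-12)
  }
})

test_that("clustering and efficiency behave on degenerate and uniform graphs", {
  u <- matrix(0.4, 6, 6)  # fully connected, uniform: all metrics exchangeable
  expect_equal(weightedClustering(u), rep(1, 6))
  expect_equal(localEfficiency(u), rep(0.4, 6))
  expect_equal(length(unique(round(nodalStrength(u), 12))), 1)
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 0.5  # nodes with < 2 neighbors
  expect_equal(weightedClustering(w), rep(0, 5))
  expect_equal(localEfficiency(w), rep(0, 5))
})

test_that("fully connected NMI-like networks keep the direct edge as shortest path", {
  set.seed(33)
  w <- matrix(runif(64, 0.5, 1), 8, 8)
  w <- (w + t(w)) / 2; diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  direct <- 1 / w; diag(direct) <- 0
  ## weights in [0.5, 1]: any two-hop path is at least as long as the edge
  expect_equal(d, direct, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("null ensembles preserve the weight multiset, density and diagonal", {
  set.seed(12)
  w <- randomNet(8, density = 0.6, seed = 77)
  diag(w) <- 1
  ens <- nullEnsemble(w, n = 20, seed = 5)
  w0 <- w; diag(w0) <- 0
  for (s in ens[1:5]) {
    s0 <- s; diag(s0) <- 0
    expect_equal(sort(s0[upper.tri(s0)]), sort(w0[upper.tri(w0)]))
    expect_equal(diag(s), diag(w))
    expect_equal(s, t(s))
  }
  ## strength total conserved exactly by construction
  expect_equal(sum(nodalStrength(ens[[1]])), sum(nodalStrength(w)))
  expect_identical(nullEnsemble(w, n = 3, seed = 5), nullEnsemble(w, n = 3, seed = 5))
  expect_false(identical(nullEnsemble(w, n = 3, seed = 5),
                         nullEnsemble(w, n = 3, seed = 6)))
})

test_that("null-normalized metrics are one against an ensemble of copies and calibrated against the null family", {
  w <- randomNet(7, density = 1, seed = 3)
  nm <- normalizedMetrics(w, list(w, w, w))
  expect_equal(nm$clusteringNorm, rep(1, 7))
  expect_equal(nm$efficiencyNorm, rep(1, 7))
  ## max-scaled clustering is invariant to uniform weight rescaling
  nm2 <- normalizedMetrics(2 * w, lapply(list(w, w), function(x) 2 * x))
  expect_equal(nm$clusteringNorm, nm2$clusteringNorm)
  ## a network drawn from the null family itself normalizes to about 1
  ens <- nullEnsemble(w, n = 60, seed = 9)
  probe <- ens[[1]]
  nm3 <- normalizedMetrics(probe, ens[-1])
  expect_equal(mean(nm3$clusteringNorm), 1, tolerance = 0.05)
  expect_equal(mean(nm3$efficiencyNorm), 1, tolerance = 0.05)
  expect_error(normalizedMetrics(w, list()), "non-empty")
})

test_that("paired permutation test contracts: identity, saturation, enumeration", {
  set.seed(21)
  a <- matrix(rnorm(5 * 12), 5, 12)
  ## a == b: all adjusted p are 1
  r0 <- pairedPermutationTest(a, a, nPerm = 200, seed = 1)
  expect_true(all(r0@pFWE == 1))
  ## dominant constant shift: the minimum adjusted p reaches the 1/nPerm
  ## bound (enough replicates that an all-equal sign pattern is never drawn)
  set.seed(23)
  a2 <- matrix(rnorm(20 * 12), 20, 12)
  r1 <- pairedPermutationTest(a2 + 100, a2, nPerm = 500, seed = 1)
  expect_lte(min(r1@pFWE), 1 / 500 + 1e-12)
  ## exhaustive enumeration equals a manual full enumeration
  set.seed(22)
  d <- matrix(rnorm(4 * 3), 4, 3)
  b <- matrix(0, 4, 3)
  rex <- pairedPermutationTest(d, b, exhaustive = TRUE)
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1), c(-1, 1)))
  nullMax <- apply(abs(signs %*% d) / 4, 1, max)
  pManual <- vapply(abs(colMeans(d)),
                    function(o) mean(nullMax >= o - 1e-12), numeric(1))
  expect_equal(rex@pFWE, pManual)
  expect_equal(rex@nPerm, 16L)
})

test_that("permutation test is level-accurate under a small simulated paired null", {
  set.seed(30)
  rej <- 0
  n <- 200
  for (k in 1:n) {
    d <- matrix(rnorm(10 * 15), 10, 15)
    r <- pairedPermutationTest(d, matrix(0, 10, 15), nPerm = 200, seed = k)
    if (min(r@pFWE) <= 0.05) rej <- rej + 1
  }
  ## binomial 95% band around 0.05 at 200 replicates
  expect_gte(rej / n, 0.01)
  expect_lte(rej / n, 0.10)
})
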