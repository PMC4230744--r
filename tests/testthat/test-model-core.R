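test_that("channel open fraction has sigmoid midpoint, limits and monotonicity", {
  expect_equal(channelOpenFraction(0, 0, 0.3), 0.5)
  expect_equal(channelOpenFraction(-0.01, -0.01, 0.15), 0.5)
  expect_equal(channelOpenFraction(1e6, 0.3, 0.15), 1)
  expect_equal(channelOpenFraction(-1e6, 0.3, 0.15), 0)
  ## pointwise value one dispersion above threshold, from the sigmoid directly
  expect_equal(channelOpenFraction(0.3 + 0.15, 0.3, 0.15),
               0.5 * (1 + tanh(1)))
  set.seed(1)
  v <- sort(rnorm(200, 0, 2))
  f <- channelOpenFraction(v, -0.01, 0.15)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  expect_error(channelOpenFraction(0, 0, 0), "dispersion")
})

test_that("firing rate is bounded by Qmax with midpoint Qmax/2", {
  expect_equal(firingRate(0.54, 0.54, 2, 1), 0.5)
  expect_equal(firingRate(0.54 + 2, 0.54, 2, 1), 0.5 * (1 + tanh(1)))
  set.seed(2)
  q <- firingRate(rnorm(1000, 0, 10), 0.54, 2, 1)
  expect_true(all(q >= 0 & q <= 1))
  expect_error(firingRate(0, 0, -1, 1), "dispersion")
  expect_error(firingRate(0, 0, 1, 0), "firing rate")
})

test_that("coupled excitatory input matches loop summation and decouples on diagonal C", {
  set.seed(3)
  C <- matrix(runif(25), 5, 5)
  Q <- runif(5)
  u <- coupledExcitatoryInput(Q, C)
  uLoop <- vapply(1:5, function(i) sum(C[i, ] * Q), numeric(1))
  expect_equal(u, uLoop, tolerance = 1e-15)
  expect_equal(coupledExcitatoryInput(Q, diag(0.5, 5), 2), 0.5 * Q[2])
  expect_equal(coupledExcitatoryInput(Q, matrix(0, 5, 5)), rep(0, 5))
  expect_error(coupledExcitatoryInput(Q[1:3], C), "length")
})

test_that("coupling matrix construction normalizes largest row sum to one", {
  set.seed(4)
  C <- couplingMatrix(matrix(runif(36), 6, 6))
  expect_equal(max(rowSums(couplingWeights(C))), 1)
  expect_true(all(couplingWeights(C) >= 0))
  expect_error(couplingMatrix(matrix(-1, 3, 3)), "nonnegative")
  ## diagonal carries the local-input value before scaling
  w <- matrix(0, 4, 4); w[1, 2] <- 3
  C2 <- couplingMatrix(w, localInput = 1)
  expect_equal(C2@maxRowSum, 4)
  expect_equal(diag(couplingWeights(C2)), rep(0.25, 4))
})

test_that("vectorized drift equals the scalar-loop oracle (R and compiled)", {
  fx <- modelFixture(N = 8, seed = 11)
  roles <- regionRoles(fx$reg)
  set.seed(11)
  for (k in 1:25) {
    y <- c(runif(24, -1, 1), runif(2, 0, 1))
    t <- runif(1, 0, 21200)
    ref <- oracleDrift(t, y, fx$p, couplingWeights(fx$C), fx$het@aIE, roles,
                       mode = "task")
    dR <- neuralDrift(t, y, fx$p, fx$C, fx$het, fx$sched, fx$reg)
    dC <- neuralDrift(t, y, fx$p, fx$C, fx$het, fx$sched, fx$reg,
                      compiled = TRUE)
    expect_lt(max(abs(dR - ref)), 1e-12)
    expect_lt(max(abs(dC - ref)), 1e-12)
  }
})

test_that("drift of an LMC node at zero dopamine and resting schedule is unmodulated", {
  p <- defaultModelParameters()
  reg <- makeRegionManifest(6)
  C <- couplingMatrix(diag(6), setDiagonal = FALSE)
  sched <- taskSchedule("rest", nCycles = 1)
  ## identical scalar state in every region, no heterogeneity, c = 0:
  ## with gain(0) = 1 all regions must have identical drift
  y <- c(rep(0.2, 6), rep(-0.1, 6), rep(0.3, 6), 0, 0)
  d <- neuralDrift(0, y, p, C, NULL, sched, reg)
  expect_equal(d[1:6], rep(d[1], 6))
  expect_equal(d[13:18], rep(d[13], 6))
})

test_that("with diagonal coupling, perturbing one region leaves others' drift unchanged", {
  p <- defaultModelParameters()
  reg <- makeRegionManifest(6)
  C <- couplingMatrix(diag(6), setDiagonal = FALSE)
  sched <- taskSchedule("rest", nCycles = 1)
  set.seed(5)
  y <- c(runif(18, -0.5, 0.5), 0.1, 0.1)
  d0 <- neuralDrift(0, y, p, C, NULL, sched, reg)
  y2 <- y
  y2[c(6, 12, 18)] <- y2[c(6, 12, 18)] + 1  # perturb region 6 (non-LMC/SNc)
  d1 <- neuralDrift(0, y2, p, C, NULL, sched, reg)
  keep <- c(1:5, 7:11, 13:17)
  expect_equal(d0[keep], d1[keep])
  expect_false(isTRUE(all.equal(d0[6], d1[6])))
})

test_that("drift satisfies a linear growth bound with physical channel fractions", {
  ## W is asymptotically confined near [0, 1]; with W in its physical range
  ## the drift is dominated by D (1 + max|x|) for one constant D
  fx <- modelFixture(N = 6, seed = 21)
  ratio <- function(R, n) {
    set.seed(100 + R)
    worst <- 0
    for (k in seq_len(n)) {
      y <- c(runif(12, -R, R), runif(6, 0, 1), runif(2, 0, R))
      d <- neuralDrift(1, y, fx$p, fx$C, fx$het, fx$sched, fx$reg,
                       compiled = TRUE)
      worst <- max(worst, max(abs(d)) / (1 + max(abs(y))))
    }
    worst
  }
  d1 <- ratio(1, 4000); d10 <- ratio(10, 4000); d100 <- ratio(100, 4000)
  D <- max(d1, d10)
  expect_true(is.finite(D))
  ## the ratio must not blow up with the domain radius
  expect_lt(d100, 3 * D)
})

test_that("drift rejects non-finite states with the offending component", {
  fx <- modelFixture(N = 6, seed = 2)
  y <- c(runif(18), 0.1, 0.1)
  y[7] <- NaN
  expect_error(neuralDrift(0, y, fx$p, fx$C, fx$het, fx$sched, fx$reg),
               "component 7")
})

test_that("diffusion is constant, correctly scaled, and noise-free for W and dopamine", {
  p <- defaultModelParameters()
  het <- sampleHeterogeneity(p, 5, seed = 9)
  b <- neuralDiffusion(p, 5, het)
  v <- parameterValues(p)
  expect_equal(b[1:5], v[["delta"]] * het@aNE)
  expect_equal(b[6:10], rep(v[["b"]] * v[["a_ni"]] * v[["delta"]], 5))
  expect_equal(b[11:17], rep(0, 7))
  ## zero amplitude: zero vector
  expect_equal(neuralDiffusion(modelParameters(delta = 0), 5), rep(0, 17))
  ## repeated calls are identical (state/time independence)
  expect_identical(b, neuralDiffusion(p, 5, het))
})

test_that("state layout round-trips through NeuralState", {
  s <- neuralState(V = 1:3, Z = 4:6, W = c(0.1, 0.2, 0.3), c = c(0.5, 0.6))
  y <- stateToVector(s)
  expect_equal(length(y), 11)
  s2 <- vectorToState(y, 3)
  expect_equal(s2@V, s@V)
  expect_equal(s2@c, s@c)
  expect_error(vectorToState(y, 4), "expected")
})

test_that("parameter schema rejects unknown names and enforces invariants", {
  expect_error(modelParameters(nonsense = 1), "unknown parameter")
  expect_error(modelParameters(K_m = -1), "positive")
  expect_error(modelParameters(G_min = 2), "G_min")
  expect_error(modelParameters(beta_max = 1e-5), "beta_max")
  p <- modelParameters(G_max = 25)
  expect_equal(p[["G_max"]], 25)
  expect_equal(p[["K_m"]], 0.125)
})
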