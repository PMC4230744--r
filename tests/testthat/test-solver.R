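test_that("correlated increments have the required moment structure", {
  h <- 0.1
  set.seed(1)
  inc <- correlatedIncrements(2e5, h)
  expect_lt(abs(var(inc$dW) - h) / h, 0.02)
  expect_lt(abs(var(inc$dZ) - h^3 / 3) / (h^3 / 3), 0.02)
  expect_lt(abs(cov(inc$dW, inc$dZ) - h^2 / 2) / (h^2 / 2), 0.02)
  ## determinism under a fixed seed
  set.seed(99); a <- correlatedIncrements(10, h)
  set.seed(99); b <- correlatedIncrements(10, h)
  expect_identical(a, b)
  ## degenerate small-step limit
  set.seed(1)
  tiny <- correlatedIncrements(1000, 1e-12)
  expect_lt(max(abs(tiny$dW)), 1e-4)
  expect_lt(max(abs(tiny$dZ)), 1e-16)
  expect_error(correlatedIncrements(5, 0), "positive")
})

test_that("single steps are exact for pure-noise and constant-drift systems", {
  y <- c(1, 2)
  ## drift-free: Y + sigma e dW for both schemes
  expect_equal(rk15Step(y, 0, 0.1, function(t, x) c(0, 0), c(0.5, 0.5),
                        dW = 0.3, dZ = 0.01), y + 0.5 * 0.3)
  expect_equal(milsteinStep(y, 0, 0.1, function(t, x) c(0, 0), c(0.5, 0.5),
                            dW = 0.3), y + 0.5 * 0.3)
  ## noise-free constant drift: exact quadrature Y + k h
  k <- c(2, -1)
  expect_equal(rk15Step(y, 0, 0.25, function(t, x) k, c(0, 0),
                        dW = 0.3, dZ = 0.01), y + k * 0.25)
  ## Milstein with zero noise is explicit Euler for a linear drift
  A <- -0.7
  expect_equal(milsteinStep(2, 0, 0.1, function(t, x) A * x, 0, dW = 1),
               2 + 0.1 * A * 2)
})

test_that("empirical strong orders are 1.5 (RK) and 1.0 (Euler-Maruyama) on the nonlinear benchmark", {
  rk <- strongConvergenceStudy("rk15", nPaths = 60, seed = 4)
  em <- strongConvergenceStudy("milstein", nPaths = 60, seed = 4)
  expect_gt(rk$slope, 1.25)
  expect_lt(rk$slope, 1.75)
  expect_gt(em$slope, 0.75)
  expect_lt(em$slope, 1.25)
  expect_true(all(diff(rk$error) < 0))  # error shrinks with h
})

test_that("the order-1.5 scheme superconverges on linear drift (OU) while Euler-Maruyama stays first order", {
  ## with additive noise the scheme's h^1.5 error term carries the drift's
  ## second derivative, so it vanishes for the OU equation
  rk <- strongConvergenceStudy("rk15", nPaths = 60, seed = 4, benchmark = "ou")
  em <- strongConvergenceStudy("milstein", nPaths = 60, seed = 4,
                               benchmark = "ou")
  expect_gt(rk$slope, 1.6)
  expect_gt(em$slope, 0.75)
  expect_lt(em$slope, 1.25)
})

test_that("integrateSDE output shape and determinism contracts hold", {
  drift <- function(t, y) -y
  set.seed(2)
  out <- integrateSDE(1, drift, 0.1, h = 0.5, nSteps = 1, stride = 1)
  expect_equal(dim(out$states), c(2, 1))
  expect_equal(out$times, c(0, 0.5))
  expect_error(integrateSDE(1, drift, 0.1, h = 0.5, nSteps = 5, stride = 2),
               "multiple")
})

test_that("compiled and reference engines produce identical full-model paths", {
  fx <- modelFixture(N = 5, seed = 13)
  sv <- solverConfig(h = 0.1, durationMs = 300, seed = 7, stride = 10)
  a <- simulateModel(fx$p, fx$C, fx$reg, fx$sched, sv, het = fx$het)
  b <- simulateModel(fx$p, fx$C, fx$reg, fx$sched, sv, het = fx$het,
                     engine = "reference")
  expect_equal(pathTimes(a), pathTimes(b))
  expect_lt(max(abs(pathStates(a) - pathStates(b))), 1e-9)
  ## same seed twice: bit-identical
  a2 <- simulateModel(fx$p, fx$C, fx$reg, fx$sched, sv, het = fx$het)
  expect_identical(pathStates(a), pathStates(a2))
})

test_that("milstein agrees with rk15 at the working step and degrades at coarse steps", {
  fx <- modelFixture(N = 10, seed = 17)
  svRK <- solverConfig(h = 0.1, durationMs = 1000, seed = 5, stride = 10)
  svM <- solverConfig(h = 0.1, durationMs = 1000, scheme = "milstein",
                      seed = 5, stride = 10)
  ## same seed and step count: identical Wiener path
  ref <- pathStates(simulateModel(fx$p, fx$C, fx$reg, fx$sched, svRK, het = fx$het))
  m01 <- pathStates(simulateModel(fx$p, fx$C, fx$reg, fx$sched, svM, het = fx$het))
  devFine <- max(abs(ref - m01))
  expect_lt(devFine, 0.3)
  ## at a 1 ms step the one-drift-evaluation scheme diverges or deviates
  ## grossly on this strongly nonlinear drift
  svM1 <- solverConfig(h = 1, durationMs = 1000, scheme = "milstein",
                       seed = 5, stride = 1)
  coarse <- tryCatch({
    m1 <- simulateModel(fx$p, fx$C, fx$reg, fx$sched, svM1, het = fx$het)
    max(abs(pathStates(m1) - ref))
  }, error = function(e) {
    expect_match(conditionMessage(e), "diverged")
    Inf
  })
  expect_gt(coarse, 10 * devFine)
})

test_that("solver stride and duration bookkeeping match the contracts", {
  fx <- modelFixture(N = 5, seed = 1)
  sv <- solverConfig(h = 0.1, durationMs = 10, seed = 1, stride = 5)
  out <- simulateModel(fx$p, fx$C, fx$reg, fx$sched, sv, het = fx$het)
  expect_equal(length(pathTimes(out)), 100 / 5 + 1)
  expect_equal(ncol(pathStates(out)), 17)
  expect_s4_class(out, "SamplePath")
  ## dopamine stays nonnegative (clamped after every step)
  expect_true(all(pathStates(out)[, 16:17] >= 0))
})

test_that("rest and task runs share initial conditions and Wiener paths", {
  fx <- modelFixture(N = 5, seed = 23)
  sv <- solverConfig(h = 0.1, durationMs = 200, seed = 11, stride = 10)
  init <- initialState(fx$p, 5, 11)
  rest <- simulateModel(fx$p, fx$C, fx$reg, taskSchedule("rest", nCycles = 1),
                        sv, het = fx$het, initial = init)
  task <- simulateModel(fx$p, fx$C, fx$reg, taskSchedule("task", nCycles = 1),
                        sv, het = fx$het, initial = init)
  expect_identical(pathStates(rest)[1, ], pathStates(task)[1, ])
  ## with beta fixed at its resting value the whole paths coincide
  pEq <- modelParameters(beta_max = 5e-4)
  restEq <- simulateModel(pEq, fx$C, fx$reg, taskSchedule("rest", nCycles = 1),
                          sv, het = fx$het, initial = init)
  taskEq <- simulateModel(pEq, fx$C, fx$reg, taskSchedule("task", nCycles = 1),
                          sv, het = fx$het, initial = init)
  expect_identical(pathStates(restEq), pathStates(taskEq))
})
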