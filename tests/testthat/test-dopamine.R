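test_that("production rate follows the speech schedule as a step function", {
  p <- defaultModelParameters()
  rest <- taskSchedule("rest", nCycles = 5)
  task <- taskSchedule("task", nCycles = 5)
  expect_equal(productionRate(c(0, 5000, 9000, 50000), rest, p), rep(5e-4, 4))
  ## inside the 8.6 s speech window of any cycle
  expect_equal(productionRate(c(0, 100, 8599, 10600 + 100), task, p),
               rep(0.01, 4))
  ## inside the 2 s acquisition gap
  expect_equal(productionRate(c(8600, 10599, 2 * 10600 - 1), task, p),
               rep(5e-4, 3))
})

test_that("Michaelis-Menten uptake has half-saturation at K_m and saturates below V_max", {
  p <- defaultModelParameters()
  expect_equal(uptakeFlux(0, p), 0)
  expect_equal(uptakeFlux(0.125, p), 0.002)
  cs <- 10^seq(-4, 3, length.out = 200)
  fl <- uptakeFlux(cs, p)
  expect_true(all(fl < 0.004))
  expect_true(all(diff(fl) > 0))
  expect_error(uptakeFlux(-0.1, p), "nonnegative")
})

test_that("dopamine drift matches its scalar transcription and fixed point", {
  p <- defaultModelParameters()
  v <- parameterValues(p)
  rest <- taskSchedule("rest", nCycles = 1)
  expect_equal(dopamineDrift(c(0, 0), c(0, 0), 0, rest, p), c(0, 0))
  set.seed(7)
  for (k in 1:20) {
    cc <- runif(2, 0, 2); q <- runif(2, 0, 1); t <- runif(1, 0, 1e5)
    ref <- v[["beta_min"]] * q - v[["V_max"]] * cc / (v[["K_m"]] + cc)
    expect_equal(dopamineDrift(cc, q, t, rest, p), ref, tolerance = 1e-14)
  }
  ## closed-form steady state has zero drift
  Q <- 0.05
  cs <- dopamineSteadyState(Q, v[["beta_min"]], p)
  expect_equal(dopamineDrift(c(cs, cs), c(Q, Q), 0, rest, p), c(0, 0),
               tolerance = 1e-15)
})

test_that("simulated dopamine kinetics converge to the closed-form steady state", {
  p <- defaultModelParameters()
  v <- parameterValues(p)
  Q <- 0.05  # constant SNc drive, beta * Q < V_max
  beta <- v[["beta_min"]]
  cs <- dopamineSteadyState(Q, beta, p)
  drift <- function(t, y) beta * Q - v[["V_max"]] * y / (v[["K_m"]] + y)
  out <- integrateSDE(0, drift, 0, h = 0.1, nSteps = 10000, scheme = "rk15",
                      increments = list(dW = numeric(10000), dZ = numeric(10000)),
                      stride = 10000)
  expect_lt(abs(out$states[2, 1] - cs) / cs, 0.01)
})

test_that("saturated production is detected and warned about", {
  p <- defaultModelParameters()
  expect_warning(cs <- dopamineSteadyState(1, 0.01, p), "saturates")
  expect_identical(cs, Inf)
})

test_that("gain is unity at zero, monotone, and bounded by G_max", {
  p <- defaultModelParameters()
  expect_identical(dopamineGain(0, p), 1)
  grid <- seq(0, 10, length.out = 1e4)
  g <- dopamineGain(grid, p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g <= 50))
  expect_true(all(g >= 1))
  expect_lt(max(dopamineGain(10^seq(-3, 4, length.out = 1000), p)), 50 + 1e-9)
  expect_error(dopamineGain(-1, p), "nonnegative")
})

test_that("modulated coupling respects the gain-chain bound", {
  p <- defaultModelParameters()
  expect_equal(modulatedAee(1, p), 0.4)
  expect_equal(modulatedAee(50, p), 50 * 0.4)
  set.seed(8)
  cc <- runif(1e5, 0, 50)
  ae <- modulatedAee(dopamineGain(cc, p), p)
  expect_true(all(ae >= 0.4 - 1e-12 & ae <= 50 * 0.4 + 1e-12))
  g <- runif(50, 1, 50)
  expect_equal(modulatedAee(g, p), g * 0.4)
  expect_error(modulatedAee(0.5, p), ">= 1")
})

test_that("modulated potassium activation reduces to the unmodulated term at unit gain", {
  p <- defaultModelParameters()
  v <- parameterValues(p)
  set.seed(9)
  W <- runif(50); V <- runif(50, -1, 1)
  unmod <- v[["phi"]] * (channelOpenFraction(V, v[["T_K"]], v[["d_K"]]) - W) /
    v[["tau_K"]]
  expect_equal(modulatedPotassiumActivation(W, V, 1, p), unmod)
  ## scalar oracle and the gain-proportional magnitude bound at G = 50
  g <- 50
  mod <- modulatedPotassiumActivation(W, V, g, p)
  ref <- v[["phi"]] * (g * channelOpenFraction(V, v[["T_K"]], v[["d_K"]]) - W) /
    v[["tau_K"]]
  expect_equal(mod, ref)
  expect_true(all(abs(mod) <= v[["phi"]] / v[["tau_K"]] * (g + abs(W))))
  expect_error(modulatedPotassiumActivation(0.5, 0, 0.9, p), ">= 1")
})
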