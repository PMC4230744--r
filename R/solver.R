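## Time-discrete integration of the SDE: an explicit strong order-1.5
## Runge-Kutta scheme adapted to constant additive scalar noise, an
## Euler-Maruyama reference scheme (the Milstein correction vanishes for
## additive noise), and generation of the correlated Wiener increment pair.

#' Construct a solver configuration
#'
#' @param h Step size in ms (default 0.1, the smallest step at which the
#'   model's fast dopamine transients are resolved without artifacts).
#' @param durationMs Total duration in ms; `NA` to derive it from the task
#'   schedule at simulation time.
#' @param scheme `"rk15"` or `"milstein"`.
#' @param seed Integer seed for the Wiener increments.
#' @param stride Store every `stride`-th step (decouples the integration grid
#'   from the stored resolution).
#' @return A [SolverConfig-class].
#' @export
solverConfig <- function(h = 0.1, durationMs = NA_real_, scheme = c("rk15", "milstein"),
                         seed = 1L, stride = 1L) {
  scheme <- match.arg(scheme)
  new("SolverConfig", h = h, durationMs = as.numeric(durationMs),
      scheme = scheme, seed = as.integer(seed), stride = as.integer(stride))
}

#' Correlated Wiener increment pair
#'
#' A strong order-1.5 step needs, besides the Wiener increment
#' \eqn{\Delta W \sim N(0, h)}, the time-integrated increment
#' \eqn{\Delta Z = \int_t^{t+h}\int_t^s dW_u\, ds} with
#' \eqn{Var(\Delta Z) = h^3/3} and \eqn{Cov(\Delta W, \Delta Z) = h^2/2}.
#' Both are generated from two independent standard normals per step:
#' \eqn{\Delta W = U_1 \sqrt h}, \eqn{\Delta Z = \tfrac12 h^{3/2} (U_1 + U_2/\sqrt 3)}.
#'
#' Draws use the current R random-number stream (Mersenne-Twister unless
#' changed); seed it with [set.seed()] for reproducibility.
#'
#' @param n Number of increment pairs.
#' @param h Step size (> 0).
#' @return List with numeric vectors `dW` and `dZ` of length `n`.
#' @examples
#' set.seed(1); correlatedIncrements(3, 0.1)
#' @export
correlatedIncrements <- function(n, h) {
  if (h <= 0) stop("step size must be positive")
  u <- stats::rnorm(2 * n)
  u1 <- u[seq(1, 2 * n, by = 2)]
  u2 <- u[seq(2, 2 * n, by = 2)]
  list(dW = sqrt(h) * u1, dZ = 0.5 * h^1.5 * (u1 + u2 / sqrt(3)))
}

#' One explicit strong order-1.5 Runge-Kutta step (additive noise)
#'
#' For an SDE \eqn{dY = a(t, Y)\,dt + b\,dW} with constant additive scalar
#' noise, the scheme evaluates the drift three times per step, at the current
#' state and at the supporting values
#' \eqn{\Upsilon_\pm = Y_n + a h \pm b \sqrt h}, and updates
#' \deqn{Y_{n+1} = Y_n + b\,\Delta W + \tfrac{h}{2} a +
#'   \left(\tfrac{h}{4} + \tfrac{\Delta Z}{2\sqrt h}\right) a(t+h, \Upsilon_+) +
#'   \left(\tfrac{h}{4} - \tfrac{\Delta Z}{2\sqrt h}\right) a(t+h, \Upsilon_-).}
#' No diffusion derivatives appear because the noise is additive.
#'
#' @param y State vector.
#' @param t Time.
#' @param h Step size.
#' @param drift Function `(t, y) -> dy` (deterministic force).
#' @param diffusion Constant diffusion vector (same length as `y`).
#' @param dW,dZ Correlated increments for this step
#'   (see [correlatedIncrements()]).
#' @return The state at `t + h`.
#' @export
rk15Step <- function(y, t, h, drift, diffusion, dW, dZ) {
  a0 <- drift(t, y)
  if (any(!is.finite(a0)))
    stop("non-finite drift at t = ", t, " (component ",
         which(!is.finite(a0))[1], ")")
  sq <- sqrt(h)
  yp <- y + a0 * h + diffusion * sq
  ym <- y + a0 * h - diffusion * sq
  ap <- drift(t + h, yp)
  am <- drift(t + h, ym)
  if (any(!is.finite(ap)) || any(!is.finite(am)))
    stop("non-finite drift at supporting value, t = ", t)
  y + diffusion * dW + (h / 2) * a0 +
    (h / 4 + dZ / (2 * sq)) * ap + (h / 4 - dZ / (2 * sq)) * am
}

#' One Milstein step (additive noise)
#'
#' For constant additive noise the Milstein correction term vanishes, so the
#' scheme reduces to Euler-Maruyama,
#' \eqn{Y_{n+1} = Y_n + a(t, Y_n) h + b \Delta W}, one drift evaluation per
#' step; with zero noise it is the explicit Euler method.
#'
#' @inheritParams rk15Step
#' @return The state at `t + h`.
#' @export
milsteinStep <- function(y, t, h, drift, diffusion, dW) {
  a0 <- drift(t, y)
  if (any(!is.finite(a0)))
    stop("non-finite drift at t = ", t, " (component ",
         which(!is.finite(a0))[1], ")")
  y + a0 * h + diffusion * dW
}

#' Integrate an SDE with constant additive scalar noise
#'
#' Reference R implementation of the recursive solution scheme, usable with
#' any drift function. The same scalar increment pair drives every component
#' of a step (scalar-noise contract). For the full neural model prefer
#' [simulateModel()], which runs the compiled core; the two agree to
#' round-off on identical increments.
#'
#' @param y0 Initial state vector.
#' @param drift Function `(t, y) -> dy`.
#' @param diffusion Constant diffusion vector.
#' @param h Step size.
#' @param nSteps Number of steps (must be a multiple of `stride`).
#' @param t0 Initial time.
#' @param scheme `"rk15"` or `"milstein"`.
#' @param increments Optional list `(dW, dZ)` of length-`nSteps` vectors; if
#'   NULL they are drawn from the current RNG stream.
#' @param stride Store every `stride`-th step.
#' @param clampIdx Optional indices clamped at zero after each step (used for
#'   the dopamine components).
#' @return List with `times` and the `states` matrix (one row per stored
#'   point, including `t0`).
#' @export
integrateSDE <- function(y0, drift, diffusion, h, nSteps, t0 = 0,
                         scheme = c("rk15", "milstein"), increments = NULL,
                         stride = 1L, clampIdx = NULL) {
  scheme <- match.arg(scheme)
  if (nSteps < 1) stop("need at least one step")
  if (nSteps %% stride != 0) stop("nSteps must be a multiple of stride")
  if (is.null(increments)) increments <- correlatedIncrements(nSteps, h)
  d <- length(y0)
  nOut <- nSteps %/% stride + 1
  states <- matrix(NA_real_, nOut, d)
  times <- t0 + h * seq(0, nSteps, by = stride)
  states[1, ] <- y <- y0
  row <- 2L
  for (n in seq_len(nSteps)) {
    t <- t0 + (n - 1) * h
    y <- if (scheme == "rk15")
      rk15Step(y, t, h, drift, diffusion, increments$dW[n], increments$dZ[n])
    else
      milsteinStep(y, t, h, drift, diffusion, increments$dW[n])
    if (!is.null(clampIdx)) y[clampIdx] <- pmax(y[clampIdx], 0)
    if (n %% stride == 0) {
      if (any(!is.finite(y)))
        stop("integration diverged at step ", n, " (t = ", t + h,
             "), component ", which(!is.finite(y))[1])
      states[row, ] <- y
      row <- row + 1L
    }
  }
  list(times = times, states = states)
}

#' Simulate the full neural/dopamine model
#'
#' Integrates the coupled SDE over the task schedule with the compiled
#' drift and the chosen scheme, clamping the dopamine concentrations at zero
#' after each step. The Wiener stream is seeded from the solver seed through
#' a named substream, so a rest run and a task run with the same seed share
#' bit-identical noise paths and initial conditions, differing only through
#' the production-rate schedule.
#'
#' @param params [ModelParameters-class].
#' @param coupling [CouplingMatrix-class].
#' @param regions [RegionSet-class].
#' @param schedule [TaskSchedule-class].
#' @param solver [SolverConfig-class]; if `durationMs` is `NA` it is taken
#'   from the schedule (`nCycles * cycleS * 1000`).
#' @param het Optional [RegionalHeterogeneity-class].
#' @param initial Optional [NeuralState-class]; defaults to
#'   [initialState()] seeded from the solver seed.
#' @param engine `"compiled"` (default) or `"reference"` (pure-R loop; same
#'   increments, used for cross-checks).
#' @return A [SamplePath-class].
#' @export
simulateModel <- function(params, coupling, regions, schedule,
                          solver = solverConfig(), het = NULL, initial = NULL,
                          engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  N <- nRegions(regions)
  if (nRegions(coupling) != N)
    stop("coupling matrix is ", nRegions(coupling), " x ", nRegions(coupling),
         " but the region set has ", N, " regions")
  duration <- solver@durationMs
  if (is.na(duration)) duration <- schedule@nCycles * schedule@cycleS * 1000
  h <- solver@h
  stride <- solver@stride
  nSteps <- ceiling(duration / h)
  if (nSteps %% stride != 0) nSteps <- nSteps + (stride - nSteps %% stride)
  if (is.null(initial)) initial <- initialState(params, N, solver@seed)
  y0 <- stateToVector(initial)
  if (length(y0) != 3 * N + 2) stop("initial state does not match region count")
  v <- parameterValues(params)
  aie <- if (is.null(het)) rep(v[["a_ie"]], N) else het@aIE
  bvec <- neuralDiffusion(params, N, het)
  r <- regions@roles
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(.substreamSeed(solver@seed, "simulation"))
  if (engine == "compiled") {
    out <- .integrateModelCpp(y0, 0, h, as.integer(nSteps), as.integer(stride),
                              solver@scheme, v, couplingWeights(coupling), aie,
                              bvec,
                              r[["lmc_left"]] - 1L, r[["lmc_right"]] - 1L,
                              r[["snc_left"]] - 1L, r[["snc_right"]] - 1L,
                              schedule@mode == "task", schedule@cycleS * 1000,
                              schedule@speechS * 1000)
  } else {
    inc <- correlatedIncrements(nSteps, h)
    f <- function(t, y) neuralDrift(t, y, params, coupling, het, schedule, regions)
    out <- integrateSDE(y0, f, bvec, h, nSteps, t0 = 0, scheme = solver@scheme,
                        increments = inc, stride = stride,
                        clampIdx = 3 * N + 1:2)
  }
  new("SamplePath", times = out$times, states = out$states, regions = regions,
      meta = list(seed = solver@seed, scheme = solver@scheme, h = h,
                  stride = stride, mode = schedule@mode,
                  cycleS = schedule@cycleS, speechS = schedule@speechS,
                  nCycles = schedule@nCycles))
}

#' Per-region excitatory firing rates along a path
#'
#' @param path [SamplePath-class].
#' @param params [ModelParameters-class].
#' @return Matrix (time x regions) of `Q_V` in kHz.
#' @export
firingRates <- function(path, params) {
  v <- parameterValues(params)
  N <- nRegions(path)
  V <- path@states[, seq_len(N), drop = FALSE]
  q <- firingRate(V, v[["V_T"]], v[["d_V"]], v[["Q_Vmax"]])
  colnames(q) <- regionLabels(path)
  q
}

#' Empirical strong-convergence study of the SDE schemes
#'
#' Measures the pathwise (strong) convergence order of the integrator on a
#' scalar additive-noise benchmark, as the slope of
#' \eqn{\log_2 E|X_T - X_T^{ref}|} against \eqn{\log_2 h}.
#'
#' Two benchmarks are available. `"cubic"` (the default) integrates the
#' nonlinear SDE \eqn{dX = (-a X - X^3)\,dt + \sigma\,dW}, \eqn{X_0 = 1},
#' against a fine-step reference on the same Brownian path (increments
#' aggregated exactly, including the time-integrated component); expected
#' slopes are about 1.5 for the Runge-Kutta scheme and 1.0 for
#' Euler-Maruyama. `"ou"` integrates the Ornstein-Uhlenbeck equation
#' \eqn{dX = -a X\,dt + \sigma\,dW} against the exact solution coupled to
#' the same path via
#' \eqn{X_{n+1} = X_n e^{-ah} + \sigma(\Delta W_n - a \Delta Z_n)}. Note
#' that for *linear* drift the order-1.5 scheme superconverges: its leading
#' \eqn{h^{1.5}} error term is proportional to the second derivative of the
#' drift and vanishes, so the OU benchmark shows a slope near 2 for the
#' Runge-Kutta scheme (and 1.0 for Euler-Maruyama); the nominal order is
#' only visible on a nonlinear benchmark.
#'
#' @param scheme `"rk15"` or `"milstein"`.
#' @param nPaths Number of independent paths per step size.
#' @param hs Step sizes (default `2^-(3:7)`).
#' @param tEnd Final time.
#' @param a,sigma Drift and noise parameters.
#' @param seed Integer seed.
#' @param benchmark `"cubic"` or `"ou"`.
#' @return List with `h`, the mean absolute endpoint errors `error`, and the
#'   fitted `slope`.
#' @export
strongConvergenceStudy <- function(scheme = c("rk15", "milstein"), nPaths = 200,
                                   hs = 2^-(3:7), tEnd = 1, a = 1, sigma = 1,
                                   seed = 1L,
                                   benchmark = c("cubic", "ou")) {
  scheme <- match.arg(scheme)
  benchmark <- match.arg(benchmark)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(.substreamSeed(seed, paste0("convergence-", scheme)))
  hs <- sort(hs, decreasing = TRUE)
  if (benchmark == "ou") {
    drift <- function(t, y) -a * y
    err <- vapply(hs, function(h) {
      nSteps <- round(tEnd / h)
      e <- numeric(nPaths)
      for (p in seq_len(nPaths)) {
        inc <- correlatedIncrements(nSteps, h)
        out <- integrateSDE(1, drift, sigma, h, nSteps, scheme = scheme,
                            increments = inc, stride = nSteps)
        xref <- 1
        eh <- exp(-a * h)
        for (n in seq_len(nSteps))
          xref <- xref * eh + sigma * (inc$dW[n] - a * inc$dZ[n])
        e[p] <- abs(out$states[2, 1] - xref)
      }
      mean(e)
    }, numeric(1))
  } else {
    drift <- function(t, y) -a * y - y^3
    hFine <- min(hs) / 8
    nFine <- round(tEnd / hFine)
    errM <- matrix(0, nPaths, length(hs))
    for (p in seq_len(nPaths)) {
      incF <- correlatedIncrements(nFine, hFine)
      ref <- integrateSDE(1, drift, sigma, hFine, nFine, scheme = "rk15",
                          increments = incF, stride = nFine)$states[2, 1]
      for (k in seq_along(hs)) {
        h <- hs[k]
        m <- round(h / hFine)
        n <- round(tEnd / h)
        wMat <- matrix(incF$dW, m, n)
        zMat <- matrix(incF$dZ, m, n)
        ## exact aggregation of the time-integrated increment over substeps
        remain <- (m - seq_len(m)) * hFine
        inc <- list(dW = colSums(wMat), dZ = colSums(zMat + remain * wMat))
        out <- integrateSDE(1, drift, sigma, h, n, scheme = scheme,
                            increments = inc, stride = n)
        errM[p, k] <- abs(out$states[2, 1] - ref)
      }
    }
    err <- colMeans(errM)
  }
  fit <- stats::lm(log2(err) ~ log2(hs))
  list(h = hs, error = err, slope = unname(stats::coef(fit)[2]))
}
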