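## Independent, deliberately naive reference implementations used as oracles.
## Everything here is scalar/loop-based and written directly from the model
## definitions, sharing no code with the package internals.

## Scalar, loop-based transcription of the full drift, component by component.
oracleDrift <- function(t, y, params, C, aie, roles, mode = "rest",
                        cycleMs = 10600, speechMs = 8600) {
  v <- parameterValues(params)
  N <- nrow(C)
  V <- y[1:N]; Z <- y[N + 1:N]; W <- y[2 * N + 1:N]; cc <- y[3 * N + 1:2]
  sig <- function(x, T, d) 0.5 * (1 + tanh((x - T) / d))
  QV <- numeric(N); QZ <- numeric(N)
  for (i in 1:N) {
    QV[i] <- v[["Q_Vmax"]] * sig(V[i], v[["V_T"]], v[["d_V"]])
    QZ[i] <- v[["Q_Zmax"]] * sig(Z[i], v[["Z_T"]], v[["d_Z"]])
  }
  gainAt <- function(c) v[["G_min"]] + (v[["G_max"]] - v[["G_min"]]) *
    tanh(v[["m_da"]] * c)
  out <- numeric(3 * N + 2)
  for (i in 1:N) {
    u <- 0
    for (j in 1:N) u <- u + C[i, j] * QV[j]
    g <- 1
    if (i == roles[["lmc_left"]]) g <- gainAt(cc[1])
    if (i == roles[["lmc_right"]]) g <- gainAt(cc[2])
    aee <- g * v[["a_ee"]]
    mCa <- sig(V[i], v[["T_Ca"]], v[["d_Ca"]])
    mNa <- sig(V[i], v[["T_Na"]], v[["d_Na"]])
    mK <- sig(V[i], v[["T_K"]], v[["d_K"]])
    out[i] <- -(v[["g_Ca"]] + v[["r_NMDA"]] * aee * u) * mCa * (V[i] - v[["V_Ca"]]) -
      (v[["g_Na"]] * mNa + aee * u) * (V[i] - v[["V_Na"]]) -
      v[["g_K"]] * W[i] * (V[i] - v[["V_K"]]) -
      v[["g_L"]] * (V[i] - v[["V_L"]]) -
      aie[i] * Z[i] * QZ[i]
    out[N + i] <- v[["b"]] * v[["a_ei"]] * V[i] * QV[i]
    out[2 * N + i] <- v[["phi"]] * (g * mK - W[i]) / v[["tau_K"]]
  }
  beta <- if (mode == "task" && (t %% cycleMs) < speechMs)
    v[["beta_max"]] else v[["beta_min"]]
  for (k in 1:2) {
    snc <- roles[[c("snc_left", "snc_right")[k]]]
    out[3 * N + k] <- beta * QV[snc] - v[["V_max"]] * cc[k] / (v[["K_m"]] + cc[k])
  }
  out
}

## Brute-force graph metric oracles (triple loops / Floyd-Warshall).
oracleStrength <- function(w) {
  N <- nrow(w)
  s <- numeric(N)
  for (i in 1:N) for (j in 1:N) if (i != j) s[i] <- s[i] + w[i, j]
  s
}

oracleOnnela <- function(w) {
  N <- nrow(w)
  diag(w) <- 0
  mx <- max(w)
  if (mx == 0) return(numeric(N))
  wh <- w / mx
  out <- numeric(N)
  for (i in 1:N) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in 1:N) for (h in 1:N)
      if (j != i && h != i && j != h)
        acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    out[i] <- acc / (k * (k - 1))
  }
  out
}

oracleLatora <- function(w) {
  N <- nrow(w)
  diag(w) <- 0
  out <- numeric(N)
  for (i in 1:N) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    d <- matrix(Inf, k, k)
    diag(d) <- 0
    for (a in 1:k) for (b in 1:k)
      if (a != b && w[nb[a], nb[b]] > 0) d[a, b] <- 1 / w[nb[a], nb[b]]
    for (m in 1:k) for (a in 1:k) for (b in 1:k)
      if (d[a, m] + d[m, b] < d[a, b]) d[a, b] <- d[a, m] + d[m, b]
    acc <- 0
    for (a in 1:k) for (b in 1:k)
      if (a != b && is.finite(d[a, b])) acc <- acc + 1 / d[a, b]
    out[i] <- acc / (k * (k - 1))
  }
  out
}

## Random symmetric weighted graph for oracle comparisons.
randomNet <- function(N, density = 0.7, seed = 1) {
  set.seed(seed)
  w <- matrix(0, N, N)
  up <- which(upper.tri(w))
  m <- max(1, round(density * length(up)))
  pos <- sample(up, m)
  w[pos] <- runif(m, 0.05, 1)
  w <- w + t(w)
  w
}

## Small ready-made model fixture shared by several tests.
modelFixture <- function(N = 8, seed = 3) {
  p <- defaultModelParameters()
  reg <- makeRegionManifest(N)
  C <- suppressWarnings(
    generateCouplingMatrix(syntheticConnectomeSpec(N = N, seed = seed)))
  het <- sampleHeterogeneity(p, N, seed = seed)
  list(p = p, reg = reg, C = C, het = het,
       sched = taskSchedule("task", nCycles = 2))
}
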