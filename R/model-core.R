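## Core regional dynamics: channel activation, firing rates, matrix-valued
## excitatory coupling, and the drift/diffusion of the full SDE.

.sigmoid01 <- function(x, center, spread) 0.5 * (1 + tanh((x - center) / spread))

#' Fraction of open ion channels
#'
#' Opening thresholds are assumed normally distributed across the population
#' with mean `threshold` and dispersion `dispersion`, giving a sigmoidal open
#' fraction \eqn{m_j(V) = \frac{1}{2}\left(1 + \tanh\frac{V - T_j}{\delta_j}\right)}.
#'
#' @param V Membrane potential (mV), any numeric vector.
#' @param threshold Mean opening threshold \eqn{T_j} (mV).
#' @param dispersion Threshold dispersion \eqn{\delta_j} (mV), strictly
#'   positive.
#' @return Values in `[0, 1]`, nondecreasing in `V`, equal to 1/2 at
#'   `V = threshold`.
#' @examples
#' channelOpenFraction(0, 0, 0.3)  # 0.5
#' @export
channelOpenFraction <- function(V, threshold, dispersion) {
  if (!is.numeric(dispersion) || any(dispersion <= 0))
    stop("channel threshold dispersion must be strictly positive")
  .sigmoid01(V, threshold, dispersion)
}

#' Mean population firing rate
#'
#' Sigmoidal rate
#' \eqn{Q(V) = \frac{Q_{max}}{2}\left(1 + \tanh\frac{V - \bar V}{\delta}\right)},
#' bounded in `[0, Qmax]` with midpoint `Qmax / 2` at `V = mean`.
#'
#' @param V Membrane potential (mV).
#' @param mean Mean firing-threshold potential (mV).
#' @param dispersion Threshold dispersion (mV), strictly positive.
#' @param Qmax Maximum firing rate (kHz), strictly positive.
#' @return Firing rate in `[0, Qmax]` (kHz).
#' @examples
#' firingRate(0.54, 0.54, 2, 1)  # 0.5 kHz
#' @export
firingRate <- function(V, mean, dispersion, Qmax) {
  if (any(dispersion <= 0)) stop("firing-threshold dispersion must be strictly positive")
  if (any(Qmax <= 0)) stop("maximum firing rate must be strictly positive")
  Qmax * .sigmoid01(V, mean, dispersion)
}

#' Coupled excitatory input to a region
#'
#' The excitatory drive a region receives is the coupling-weighted sum of all
#' regional excitatory firing rates, \eqn{u_i = \sum_j c_{ij} Q_{V,j}}; the
#' diagonal entry carries local excitatory input.
#'
#' @param QV Vector of per-region excitatory firing rates (kHz).
#' @param coupling A [CouplingMatrix-class] or plain numeric matrix.
#' @param i Optional region index; if omitted, the full vector
#'   \eqn{C\,Q_V} is returned.
#' @return Weighted input rate(s).
#' @export
coupledExcitatoryInput <- function(QV, coupling, i = NULL) {
  C <- if (is(coupling, "CouplingMatrix")) coupling@weights else coupling
  if (length(QV) != ncol(C))
    stop("firing-rate vector has length ", length(QV), " but coupling matrix is ",
         nrow(C), " x ", ncol(C))
  u <- as.numeric(C %*% QV)
  if (is.null(i)) u else u[i]
}

#' Construct a coupling matrix
#'
#' Sets the diagonal to `localInput` (local excitatory input within a region)
#' and normalizes the matrix with respect to its largest row sum, which is
#' recorded as metadata.
#'
#' @param weights Nonnegative square numeric matrix of inter-regional
#'   coupling strengths.
#' @param localInput Diagonal value inserted before normalization (default 1).
#' @param setDiagonal Replace the diagonal with `localInput` (default TRUE).
#' @return A [CouplingMatrix-class] with largest row sum 1.
#' @examples
#' couplingMatrix(matrix(runif(16), 4, 4))
#' @export
couplingMatrix <- function(weights, localInput = 1, setDiagonal = TRUE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("coupling matrix must be square")
  if (any(!is.finite(weights))) stop("coupling weights must be finite")
  if (any(weights < 0)) stop("coupling weights must be nonnegative")
  if (setDiagonal) diag(weights) <- localInput
  m <- max(rowSums(weights))
  if (m <= 0) stop("coupling matrix has no positive row sum")
  new("CouplingMatrix", weights = weights / m, maxRowSum = m,
      localInput = localInput)
}

#' Construct a region set
#'
#' @param labels Unique region names.
#' @param roles Named integer vector with `lmc_left`, `lmc_right`,
#'   `snc_left`, `snc_right` (1-based indices into `labels`), or a named
#'   character vector of labels resolved by lookup.
#' @return A [RegionSet-class].
#' @export
regionSet <- function(labels, roles) {
  if (is.character(roles)) {
    idx <- match(roles, labels)
    if (anyNA(idx)) stop("role label(s) not found: ",
                         paste(roles[is.na(idx)], collapse = ", "))
    roles <- stats::setNames(idx, names(roles))
  }
  new("RegionSet", labels = as.character(labels),
      roles = stats::setNames(as.integer(roles), names(roles)))
}

#' Construct a neural state
#'
#' @param V,Z Per-region excitatory and inhibitory membrane potentials (mV).
#' @param W Per-region open potassium-channel fractions.
#' @param c Dopamine concentration (mM) in left and right LMC.
#' @return A [NeuralState-class].
#' @export
neuralState <- function(V, Z, W, c) {
  new("NeuralState", V = as.numeric(V), Z = as.numeric(Z), W = as.numeric(W),
      c = as.numeric(c))
}

#' Flatten / rebuild the state layout
#'
#' The integration layout is the concatenation `[V (N), Z (N), W (N), c (2)]`
#' of dimension `3 N + 2`.
#'
#' @param state A [NeuralState-class].
#' @return `stateToVector`: numeric vector of length `3 N + 2`.
#' @export
stateToVector <- function(state) {
  stopifnot(is(state, "NeuralState"))
  c(state@V, state@Z, state@W, state@c)
}

#' @rdname stateToVector
#' @param y Numeric vector of length `3 N + 2`.
#' @param N Region count.
#' @return `vectorToState`: a [NeuralState-class].
#' @export
vectorToState <- function(y, N) {
  if (length(y) != 3 * N + 2)
    stop("state vector has length ", length(y), ", expected ", 3 * N + 2)
  new("NeuralState", V = y[seq_len(N)], Z = y[N + seq_len(N)],
      W = y[2 * N + seq_len(N)], c = pmax(y[3 * N + 1:2], 0))
}

#' Drift of the full neural/dopamine SDE
#'
#' Deterministic force of the coupled model in the flat `[V, Z, W, c]`
#' layout. Non-LMC regions follow the unmodulated regional dynamics; the two
#' LMC regions apply the dopamine-dependent gain to the potassium activation
#' and to the excitatory-to-excitatory strength; the two dopamine components
#' follow production-minus-Michaelis-Menten-uptake kinetics driven by the
#' ipsilateral SNc firing rate.
#'
#' @param t Time (ms).
#' @param state A [NeuralState-class] or flat numeric vector of length
#'   `3 N + 2`.
#' @param params [ModelParameters-class].
#' @param coupling [CouplingMatrix-class] (or plain matrix already
#'   normalized).
#' @param het [RegionalHeterogeneity-class], or NULL for homogeneous regions
#'   (all `a_ie`, `a_ne` at their means).
#' @param schedule [TaskSchedule-class]; governs the dopamine production rate
#'   \eqn{\beta(t)}.
#' @param regions [RegionSet-class] naming the LMC and SNc indices.
#' @param compiled Use the compiled drift (default FALSE; both routes agree to
#'   round-off and are cross-checked in the tests).
#' @return Numeric vector of length `3 N + 2`: the state derivative (per ms).
#' @export
neuralDrift <- function(t, state, params, coupling, het = NULL, schedule,
                        regions, compiled = FALSE) {
  v <- parameterValues(params)
  C <- if (is(coupling, "CouplingMatrix")) coupling@weights else coupling
  N <- nrow(C)
  y <- if (is(state, "NeuralState")) stateToVector(state) else as.numeric(state)
  if (length(y) != 3 * N + 2)
    stop("state has length ", length(y), ", expected ", 3 * N + 2)
  if (any(!is.finite(y))) {
    bad <- which(!is.finite(y))[1]
    stop("non-finite state passed to drift (component ", bad, ")")
  }
  aie <- if (is.null(het)) rep(v[["a_ie"]], N) else het@aIE
  r <- regions@roles
  if (compiled) {
    return(.neuralDriftCpp(t, y, v, C, aie,
                           r[["lmc_left"]] - 1L, r[["lmc_right"]] - 1L,
                           r[["snc_left"]] - 1L, r[["snc_right"]] - 1L,
                           schedule@mode == "task", schedule@cycleS * 1000,
                           schedule@speechS * 1000))
  }
  V <- y[seq_len(N)]; Z <- y[N + seq_len(N)]; W <- y[2 * N + seq_len(N)]
  cc <- y[3 * N + 1:2]
  QV <- firingRate(V, v[["V_T"]], v[["d_V"]], v[["Q_Vmax"]])
  QZ <- firingRate(Z, v[["Z_T"]], v[["d_Z"]], v[["Q_Zmax"]])
  u <- as.numeric(C %*% QV)
  gain <- rep(1, N)
  gain[r[["lmc_left"]]] <- dopamineGain(max(cc[1], 0), params)
  gain[r[["lmc_right"]]] <- dopamineGain(max(cc[2], 0), params)
  aee <- gain * v[["a_ee"]]
  mCa <- channelOpenFraction(V, v[["T_Ca"]], v[["d_Ca"]])
  mNa <- channelOpenFraction(V, v[["T_Na"]], v[["d_Na"]])
  mK <- channelOpenFraction(V, v[["T_K"]], v[["d_K"]])
  dV <- -(v[["g_Ca"]] + v[["r_NMDA"]] * aee * u) * mCa * (V - v[["V_Ca"]]) -
    (v[["g_Na"]] * mNa + aee * u) * (V - v[["V_Na"]]) -
    v[["g_K"]] * W * (V - v[["V_K"]]) -
    v[["g_L"]] * (V - v[["V_L"]]) -
    aie * Z * QZ
  dZ <- v[["b"]] * v[["a_ei"]] * V * QV
  dW <- v[["phi"]] * (gain * mK - W) / v[["tau_K"]]
  dc <- dopamineDrift(pmax(cc, 0),
                      QV[c(r[["snc_left"]], r[["snc_right"]])],
                      t, schedule, params)
  c(dV, dZ, dW, dc)
}

#' Diffusion vector of the model
#'
#' The noise is constant, additive and scalar: one Wiener increment multiplies
#' the whole vector. Excitatory components are scaled by the per-region
#' non-specific excitatory strength `a_ne` times the noise amplitude
#' \eqn{\delta}; inhibitory components by `b * a_ni * delta`; potassium and
#' dopamine components carry no noise.
#'
#' @param params [ModelParameters-class].
#' @param N Region count.
#' @param het Optional [RegionalHeterogeneity-class] supplying per-region
#'   `a_ne`.
#' @return Constant numeric vector of length `3 N + 2`.
#' @export
neuralDiffusion <- function(params, N, het = NULL) {
  v <- parameterValues(params)
  ane <- if (is.null(het)) rep(v[["a_ne"]], N) else het@aNE
  c(v[["delta"]] * ane,
    rep(v[["b"]] * v[["a_ni"]] * v[["delta"]], N),
    rep(0, N), c(0, 0))
}

#' Initial state shared by rest and task runs
#'
#' `V` and `Z` are drawn uniformly in a small interval around rest
#' (`[-0.1, 0.1]` mV), `W` is the potassium open fraction at that potential,
#' and the dopamine concentration starts at the tonic level `c_0`. The same
#' seed must be used for the rest and task conditions so both start
#' identically.
#'
#' @param params [ModelParameters-class].
#' @param N Region count.
#' @param seed Integer seed.
#' @param width Half-width of the uniform interval (mV).
#' @return A [NeuralState-class].
#' @export
initialState <- function(params, N, seed, width = 0.1) {
  v <- parameterValues(params)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(.substreamSeed(seed, "initial-state"))
  V <- stats::runif(N, -width, width)
  Z <- stats::runif(N, -width, width)
  W <- channelOpenFraction(V, v[["T_K"]], v[["d_K"]])
  neuralState(V, Z, W, c(v[["c_0"]], v[["c_0"]]))
}

## seed plumbing: one global seed expanded into named substreams so the
## simulation, null-model and permutation stages are independently reproducible
.substreamSeed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  s <- as.numeric(seed) %% 2147483647
  as.integer(((s * 48271) %% 2147483647 + h) %% 2147483647)
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
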