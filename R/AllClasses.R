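#' @import methods
NULL

#' Model parameter set
#'
#' Holds every constant of the coupled neural-population / dopamine model as a
#' named numeric vector: ion-channel thresholds, dispersions, conductances and
#' Nernst potentials for Ca, K and Na; leak conductance; firing thresholds and
#' maximum rates of the excitatory and inhibitory populations; synaptic
#' factors; the potassium temperature factor and relaxation time; the noise
#' amplitude and its inhibitory scaling; and the dopamine block (Michaelis-
#' Menten re-uptake, production-rate bounds, tonic level, antagonism parameter
#' and gain bounds). Units are the model's own: mV, mS, ms, mM, kHz.
#'
#' @slot values Named numeric vector holding all parameters.
#' @seealso [defaultModelParameters()], [modelParameters()]
#' @export
setClass("ModelParameters", representation(values = "numeric"))

#' Region manifest
#'
#' Ordered region labels plus the four special roles of the nigro-cortical
#' dopamine pathway: left/right laryngeal motor cortex (LMC, the dopamine
#' target) and left/right substantia nigra pars compacta (SNc, the source).
#'
#' @slot labels Character vector of unique region names.
#' @slot roles Named integer vector with entries `lmc_left`, `lmc_right`,
#'   `snc_left`, `snc_right` giving 1-based region indices.
#' @export
setClass("RegionSet",
         representation(labels = "character", roles = "integer"))

#' Structural coupling matrix
#'
#' Nonnegative N x N inter-regional coupling weights. The diagonal carries the
#' local excitatory input of each region. After construction the matrix is
#' scaled so that its largest row sum equals one; the pre-scaling largest row
#' sum is retained as normalization metadata.
#'
#' @slot weights Nonnegative numeric matrix, largest row sum 1 after scaling.
#' @slot maxRowSum Largest row sum of the matrix before scaling.
#' @slot localInput Diagonal value inserted before normalization.
#' @export
setClass("CouplingMatrix",
         representation(weights = "matrix", maxRowSum = "numeric",
                        localInput = "numeric"))

#' Regional heterogeneity of synaptic strengths
#'
#' Per-region draws of the inhibitory-to-excitatory strength (`aIE`) and the
#' non-specific-to-excitatory strength (`aNE`), sampled from normal
#' distributions with a fixed seed so regions can desynchronize while every
#' run remains reproducible. Draws are strictly positive (non-positive draws
#' are resampled).
#'
#' @slot aIE Numeric vector, one value per region.
#' @slot aNE Numeric vector, one value per region.
#' @slot seed Integer seed the draws were generated from.
#' @export
setClass("RegionalHeterogeneity",
         representation(aIE = "numeric", aNE = "numeric", seed = "integer"))

#' Neural state
#'
#' The instantaneous state of the model: per-region mean excitatory membrane
#' potential `V` (mV), mean inhibitory potential `Z` (mV), fraction of open
#' potassium channels `W`, and the dopamine concentration `c` (mM) in the left
#' and right LMC. The flat layout used throughout integration is
#' `[V (N), Z (N), W (N), c (2)]`, dimension `3 N + 2`.
#'
#' @slot V,Z,W Numeric vectors of length N.
#' @slot c Numeric vector of length 2 (left, right), nonnegative.
#' @export
setClass("NeuralState",
         representation(V = "numeric", Z = "numeric", W = "numeric",
                        c = "numeric"))

#' Task schedule
#'
#' Timing of the speech-production paradigm: cycles of `cycleS` seconds
#' (default 10.6) containing a speech window of `speechS` seconds (default
#' 8.6) followed by a silent acquisition gap. In task mode the dopamine
#' production rate is `beta_max` inside speech windows and `beta_min`
#' otherwise; in rest mode it is `beta_min` throughout.
#'
#' @slot mode `"rest"` or `"task"`.
#' @slot cycleS Cycle length in seconds.
#' @slot speechS Speech-production window per cycle in seconds.
#' @slot nCycles Number of cycles simulated.
#' @export
setClass("TaskSchedule",
         representation(mode = "character", cycleS = "numeric",
                        speechS = "numeric", nCycles = "numeric"))

#' Solver configuration
#'
#' @slot h Step size in ms (default 0.1).
#' @slot durationMs Total integration time in ms.
#' @slot scheme `"rk15"` (explicit strong order-1.5 Runge-Kutta, the default)
#'   or `"milstein"` (Euler-Maruyama; for additive noise the Milstein
#'   correction vanishes).
#' @slot seed Integer seed driving the Wiener increments.
#' @slot stride Store every `stride`-th step.
#' @export
setClass("SolverConfig",
         representation(h = "numeric", durationMs = "numeric",
                        scheme = "character", seed = "integer",
                        stride = "integer"))

#' Simulated sample path
#'
#' A time-discretized trajectory of the model state: times in ms and a
#' (time x dimension) state matrix in the `[V, Z, W, c]` layout.
#'
#' @slot times Strictly increasing numeric vector (ms).
#' @slot states Numeric matrix, one row per stored time point, `3 N + 2`
#'   columns.
#' @slot regions The [RegionSet-class] the path was simulated over.
#' @slot meta List with `seed`, `scheme`, `h`, `stride` and schedule info.
#' @export
setClass("SamplePath",
         representation(times = "numeric", states = "matrix",
                        regions = "RegionSet", meta = "list"))

#' Simulated BOLD signal
#'
#' Per-region BOLD time series (percent signal change) produced by the
#' Balloon-Windkessel forward model, either at the dense simulation grid or
#' decimated to an acquisition TR.
#'
#' @slot series Numeric matrix, time points x regions.
#' @slot interval Sampling interval in seconds.
#' @slot drive Description of the neural drive variable (e.g. `"Q_V"`).
#' @slot labels Region labels.
#' @export
setClass("BoldSignal",
         representation(series = "matrix", interval = "numeric",
                        drive = "character", labels = "character"))

#' NMI functional-connectivity network
#'
#' Symmetric matrix of normalized-mutual-information coefficients between
#' regional time series; entries lie in `[0, 1]` with a unit diagonal.
#'
#' @slot values Symmetric numeric matrix in `[0, 1]`, unit diagonal.
#' @slot bins Histogram bin count used by the entropy estimator.
#' @slot source Free-form tag (e.g. `"model:task"`).
#' @export
setClass("NmiNetwork",
         representation(values = "matrix", bins = "integer",
                        source = "character"))

#' Weighted graph metrics with null-model normalization
#'
#' Per-node strength, degree, Onnela weighted clustering and Latora local
#' efficiency of a weighted network, plus clustering/efficiency divided by
#' their per-node means over an ensemble of null-model surrogates.
#'
#' @slot metrics data.frame with columns `node`, `strength`, `degree`,
#'   `clustering`, `efficiency`, `clusteringNorm`, `efficiencyNorm`.
#' @slot nNull Number of null-model surrogates (0 when not normalized).
#' @slot seed Seed of the null ensemble.
#' @export
setClass("GraphMetricsResult",
         representation(metrics = "data.frame", nNull = "integer",
                        seed = "integer"))

#' Paired max-statistic permutation test result
#'
#' @slot observed Observed per-node statistic (mean paired difference).
#' @slot nullMax Permutation distribution of the maximum statistic.
#' @slot pFWE Per-node family-wise-error-adjusted p-values.
#' @slot nPerm Number of permutations (sign flips) used.
#' @slot seed Seed, or NA for exhaustive enumeration.
#' @slot exhaustive TRUE if all sign patterns were enumerated.
#' @export
setClass("PermutationTestResult",
         representation(observed = "numeric", nullMax = "numeric",
                        pFWE = "numeric", nPerm = "integer", seed = "integer",
                        exhaustive = "logical"))

#' Synthetic connectome specification
#'
#' Recipe for a surrogate structural coupling matrix standing in for a
#' DTI-derived connectome: sparse, heavy-tailed (log-normal) weights on a
#' random topology of given density, optionally symmetric.
#'
#' @slot N Region count.
#' @slot density Edge density in (0, 1].
#' @slot meanlog,sdlog Log-normal weight parameters.
#' @slot symmetric Generate an undirected (symmetric) matrix.
#' @slot seed Integer seed.
#' @export
setClass("SyntheticConnectomeSpec",
         representation(N = "integer", density = "numeric",
                        meanlog = "numeric", sdlog = "numeric",
                        symmetric = "logical", seed = "integer"))

#' Run configuration
#'
#' Bundles everything a full rest/task experiment needs: input paths (or
#' synthetic-input settings), parameter overrides, solver and schedule
#' settings, analysis settings (bins, null-model count, permutation count,
#' alpha) and the global seed, from which named per-stage substreams are
#' derived. Serializes to/from YAML with round-trip identity.
#'
#' @slot paths Named list of file paths (may be empty for synthetic inputs).
#' @slot parameters Named list of [ModelParameters-class] overrides.
#' @slot solver [SolverConfig-class].
#' @slot schedule [TaskSchedule-class].
#' @slot analysis Named list: `bins`, `nNull`, `nPerm`, `alpha`, `trS`.
#' @slot seed Global integer seed.
#' @export
setClass("RunConfig",
         representation(paths = "list", parameters = "list",
                        solver = "SolverConfig", schedule = "TaskSchedule",
                        analysis = "list", seed = "integer"))

## ---- validity ----

setValidity("ModelParameters", function(object) {
  v <- object@values
  need <- .parameterNames()
  miss <- setdiff(need, names(v))
  if (length(miss)) return(paste("missing parameters:", paste(miss, collapse = ", ")))
  extra <- setdiff(names(v), need)
  if (length(extra)) return(paste("unknown parameters:", paste(extra, collapse = ", ")))
  if (anyNA(v) || any(!is.finite(v))) return("parameters must be finite")
  pos <- c("d_Ca", "d_K", "d_Na", "g_Ca", "g_K", "g_Na", "g_L", "d_V", "d_Z",
           "Q_Vmax", "Q_Zmax", "tau_K", "K_m", "V_max", "beta_min", "beta_max",
           "a_ie_sd", "a_ne_sd")
  if (any(v[pos] <= 0))
    return(paste("parameters must be strictly positive:",
                 paste(pos[v[pos] <= 0], collapse = ", ")))
  if (v["G_min"] != 1) return("G_min must equal 1 (unity gain at zero dopamine)")
  if (v["G_max"] < v["G_min"]) return("G_max must be >= G_min")
  if (v["beta_max"] < v["beta_min"]) return("beta_max must be >= beta_min")
  if (v["delta"] < 0) return("noise amplitude delta must be nonnegative")
  TRUE
})

setValidity("RegionSet", function(object) {
  n <- length(object@labels)
  if (n < 4) return("at least 4 regions are required")
  if (anyDuplicated(object@labels)) return("region labels must be unique")
  r <- object@roles
  need <- c("lmc_left", "lmc_right", "snc_left", "snc_right")
  if (!identical(sort(names(r)), sort(need)))
    return("roles must name lmc_left, lmc_right, snc_left, snc_right")
  if (anyDuplicated(r)) return("role indices must be distinct")
  if (any(r < 1L | r > n)) return("role indices out of range")
  TRUE
})

setValidity("CouplingMatrix", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("coupling matrix must be square")
  if (anyNA(w) || any(!is.finite(w))) return("coupling weights must be finite")
  if (any(w < 0)) return("coupling weights must be nonnegative")
  if (abs(max(rowSums(w)) - 1) > 1e-8)
    return("largest row sum must equal 1 after normalization")
  TRUE
})

setValidity("RegionalHeterogeneity", function(object) {
  if (length(object@aIE) != length(object@aNE))
    return("aIE and aNE must have equal length")
  if (any(object@aIE <= 0) || any(object@aNE <= 0))
    return("heterogeneity draws must be strictly positive")
  TRUE
})

setValidity("NeuralState", function(object) {
  n <- length(object@V)
  if (length(object@Z) != n || length(object@W) != n)
    return("V, Z, W must have equal length")
  if (length(object@c) != 2) return("c must have length 2 (left, right LMC)")
  if (any(!is.finite(c(object@V, object@Z, object@W, object@c))))
    return("state must be finite")
  if (any(object@c < 0)) return("dopamine concentration must be nonnegative")
  TRUE
})

setValidity("TaskSchedule", function(object) {
  if (!object@mode %in% c("rest", "task")) return("mode must be 'rest' or 'task'")
  if (object@cycleS <= 0) return("cycle length must be positive")
  if (object@speechS < 0 || object@speechS > object@cycleS)
    return("speech window must lie within [0, cycle length]")
  if (object@nCycles < 1) return("need at least one cycle")
  TRUE
})

setValidity("SolverConfig", function(object) {
  if (object@h <= 0) return("step size h must be positive")
  if (!is.na(object@durationMs) && object@durationMs < object@h)
    return("duration must be at least one step")
  if (!object@scheme %in% c("rk15", "milstein"))
    return("scheme must be 'rk15' or 'milstein'")
  if (object@stride < 1L) return("stride must be >= 1")
  TRUE
})

setValidity("SamplePath", function(object) {
  if (nrow(object@states) != length(object@times))
    return("states must have one row per time point")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  n <- length(object@regions@labels)
  if (ncol(object@states) != 3 * n + 2)
    return("state dimension must be 3 N + 2")
  TRUE
})

setValidity("BoldSignal", function(object) {
  if (ncol(object@series) != length(object@labels))
    return("one column per region required")
  if (any(!is.finite(object@series))) return("BOLD series must be finite")
  if (object@interval <= 0) return("sampling interval must be positive")
  TRUE
})

setValidity("NmiNetwork", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("NMI matrix must be square")
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) return("NMI entries must lie in [0, 1]")
  if (max(abs(v - t(v))) > 1e-12) return("NMI matrix must be symmetric")
  if (max(abs(diag(v) - 1)) > 1e-12) return("NMI diagonal must be 1")
  TRUE
})

setValidity("PermutationTestResult", function(object) {
  if (any(object@pFWE <= 0) || any(object@pFWE > 1))
    return("adjusted p-values must lie in (0, 1]")
  TRUE
})

setValidity("SyntheticConnectomeSpec", function(object) {
  if (object@N < 4L) return("N must be >= 4")
  if (object@density <= 0 || object@density > 1)
    return("density must lie in (0, 1]")
  if (object@sdlog <= 0) return("sdlog must be positive")
  TRUE
})
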