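## Synthetic stand-ins for every input derived from human data: surrogate
## structural connectomes, the 70-region manifest with LMC/SNc roles,
## heterogeneity draws, and the paired rest/task demo experiment.

#' Specify a synthetic structural connectome
#'
#' Surrogate for a tractography-derived structural connectivity matrix:
#' sparse topology of the requested density with heavy-tailed (log-normal)
#' weights, mimicking streamline-count matrices.
#'
#' @param N Region count (>= 4).
#' @param density Edge density in (0, 1] (default 0.3).
#' @param meanlog,sdlog Log-normal weight parameters (defaults 0 and 1).
#' @param symmetric Generate an undirected matrix (default TRUE).
#' @param seed Integer seed.
#' @return A [SyntheticConnectomeSpec-class].
#' @export
syntheticConnectomeSpec <- function(N = 70, density = 0.3, meanlog = 0,
                                    sdlog = 1, symmetric = TRUE, seed = 1L) {
  new("SyntheticConnectomeSpec", N = as.integer(N), density = density,
      meanlog = meanlog, sdlog = sdlog, symmetric = symmetric,
      seed = as.integer(seed))
}

#' Generate a synthetic coupling matrix
#'
#' Draws the random topology and log-normal weights described by `spec`,
#' inserts the local-input diagonal, and normalizes with respect to the
#' largest row sum. A warning is issued if the density leaves a region with
#' no inter-regional connection.
#'
#' @param spec A [SyntheticConnectomeSpec-class].
#' @param localInput Diagonal value inserted before normalization.
#' @return A [CouplingMatrix-class].
#' @examples
#' C <- generateCouplingMatrix(syntheticConnectomeSpec(N = 10, seed = 7))
#' max(rowSums(couplingWeights(C)))  # 1
#' @export
generateCouplingMatrix <- function(spec, localInput = 1) {
  stopifnot(is(spec, "SyntheticConnectomeSpec"))
  N <- spec@N
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(.substreamSeed(spec@seed, "connectome"))
  w <- matrix(0, N, N)
  if (spec@symmetric) {
    up <- which(upper.tri(w))
    nEdges <- max(1L, round(spec@density * length(up)))
    pos <- sample(up, nEdges)
    w[pos] <- stats::rlnorm(nEdges, spec@meanlog, spec@sdlog)
    w <- w + t(w)
  } else {
    off <- which(row(w) != col(w))
    nEdges <- max(1L, round(spec@density * length(off)))
    pos <- sample(off, nEdges)
    w[pos] <- stats::rlnorm(nEdges, spec@meanlog, spec@sdlog)
  }
  isolated <- which(rowSums(w) == 0 & colSums(w) == 0)
  if (length(isolated))
    warning("region(s) without inter-regional connections: ",
            paste(isolated, collapse = ", "))
  couplingMatrix(w, localInput = localInput)
}

.corticalAbbrev <- c("ACC", "MCC", "PCC", "ICC", "Cu", "PCu", "ETC", "FG",
                     "FP", "IFGop", "IFGor", "IFGtr", "IPC", "SPC", "ITC",
                     "STC", "LG", "LMC", "LOFC", "MOFC", "MFG", "mFG", "MTG",
                     "OC", "PCAC", "PHip", "PreCG", "PostCG", "SFG", "SMG",
                     "TP", "TTC")
.subcorticalAbbrev <- c("Put", "SNc", "Th")

#' Build a region manifest
#'
#' For the default `N = 70` this emits the whole-brain parcellation used for
#' the speech-production experiment: 64 cortical and 6 subcortical areas (32
#' cortical labels plus putamen, SNc and thalamus per hemisphere), with the
#' laryngeal motor cortex and SNc roles resolved by name. For other `N`,
#' generic labels `R01..RN` are used with the LMC pair at indices 1-2 and
#' the SNc pair at indices 3-4.
#'
#' @param N Region count (>= 4; default 70).
#' @return A [RegionSet-class].
#' @examples
#' makeRegionManifest(10)
#' @export
makeRegionManifest <- function(N = 70) {
  if (N < 4) stop("need at least 4 regions (bilateral LMC and SNc)")
  if (N == 70) {
    labels <- c(paste0(.corticalAbbrev, "_L"), paste0(.subcorticalAbbrev, "_L"),
                paste0(.corticalAbbrev, "_R"), paste0(.subcorticalAbbrev, "_R"))
    roles <- c(lmc_left = "LMC_L", lmc_right = "LMC_R",
               snc_left = "SNc_L", snc_right = "SNc_R")
    return(regionSet(labels, roles))
  }
  labels <- sprintf("R%02d", seq_len(N))
  labels[1:4] <- c("LMC_L", "LMC_R", "SNc_L", "SNc_R")
  regionSet(labels, c(lmc_left = "LMC_L", lmc_right = "LMC_R",
                      snc_left = "SNc_L", snc_right = "SNc_R"))
}

#' Sample regional heterogeneity
#'
#' Draws per-region inhibitory-to-excitatory (`a_ie`) and non-specific-to-
#' excitatory (`a_ne`) strengths from normal distributions with the means
#' and spreads stored in `params`, using a fixed seed so all simulations of a
#' study share the same regional variation. Non-positive draws are resampled
#' (the strengths are physical conductances).
#'
#' @param params [ModelParameters-class].
#' @param N Region count.
#' @param seed Integer seed.
#' @return A [RegionalHeterogeneity-class].
#' @export
sampleHeterogeneity <- function(params, N, seed = 1L) {
  v <- parameterValues(params)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(.substreamSeed(seed, "heterogeneity"))
  drawPos <- function(mean, sd) {
    x <- stats::rnorm(N, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  new("RegionalHeterogeneity",
      aIE = drawPos(v[["a_ie"]], v[["a_ie_sd"]]),
      aNE = drawPos(v[["a_ne"]], v[["a_ne_sd"]]),
      seed = as.integer(seed))
}

#' Run the paired rest/task demonstration experiment
#'
#' Simulates the resting state and the dopamine-modulated task condition
#' with identical initial conditions, heterogeneity and Wiener paths (one
#' shared seed), differing only in the production-rate schedule; converts
#' both firing-rate outputs to BOLD, samples them at the acquisition TR,
#' computes NMI networks, and derives graph metrics.
#'
#' The default configuration is the scaled-down study (10 regions, 20
#' cycles); the full 70-region, 50-cycle setting is reproduced with
#' `N = 70, nCycles = 50`.
#'
#' @param N Region count.
#' @param nCycles Number of 10.6 s cycles per condition.
#' @param seed Global seed (expanded into per-stage substreams).
#' @param params [ModelParameters-class].
#' @param coupling Optional [CouplingMatrix-class]; defaults to a synthetic
#'   connectome generated from `seed`.
#' @param regions Optional [RegionSet-class]; defaults to
#'   [makeRegionManifest()].
#' @param h Step size (ms).
#' @param stride Storage stride (default 100: drive stored every 10 ms).
#' @param trS Acquisition TR in seconds for the analysis sampling.
#' @param bins NMI histogram bins (default `ceiling(sqrt(samples))`).
#' @param nNull Null-model count for metric normalization (0 to skip).
#' @param betaMaxOverride Optional override of `beta_max` (e.g. set equal to
#'   `beta_min` for a degenerate-schedule check).
#' @return List with elements `rest` and `task` (each holding `path`,
#'   `bold`, `nmi`, `metrics`), plus `regions`, `coupling`,
#'   `heterogeneity` and `seed`.
#' @export
demoExperiment <- function(N = 10, nCycles = 20, seed = 1L,
                           params = defaultModelParameters(), coupling = NULL,
                           regions = NULL, h = 0.1, stride = 100L, trS = 2,
                           bins = NULL, nNull = 100, betaMaxOverride = NULL) {
  if (!is.null(betaMaxOverride)) {
    v <- parameterValues(params)
    v[["beta_max"]] <- betaMaxOverride
    params <- new("ModelParameters", values = v)
  }
  if (is.null(regions)) regions <- makeRegionManifest(N)
  N <- nRegions(regions)
  if (is.null(coupling))
    coupling <- generateCouplingMatrix(syntheticConnectomeSpec(N = N, seed = seed))
  het <- sampleHeterogeneity(params, N, seed = seed)
  init <- initialState(params, N, seed)
  solver <- solverConfig(h = h, seed = seed, stride = stride)
  runCondition <- function(mode) {
    sched <- taskSchedule(mode, nCycles = nCycles)
    path <- simulateModel(params, coupling, regions, sched, solver,
                          het = het, initial = init)
    bold <- balloonWindkessel(path, params = params)
    boldTR <- sampleAtTR(bold, trS)
    net <- nmiMatrix(boldTR, bins = bins, source = paste0("model:", mode))
    metrics <- graphMetrics(net, nNull = nNull, seed = seed)
    list(path = path, bold = boldTR, nmi = net, metrics = metrics)
  }
  list(rest = runCondition("rest"), task = runCondition("task"),
       regions = regions, coupling = coupling, heterogeneity = het,
       seed = seed)
}
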