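#' Number of regions
#' @param x A region-aware object.
#' @return Integer region count.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Region labels
#' @param x A region-aware object.
#' @return Character vector of region names.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Special-role indices (LMC and SNc, left/right)
#' @param x A [RegionSet-class] or object carrying one.
#' @return Named integer vector (`lmc_left`, `lmc_right`, `snc_left`,
#'   `snc_right`).
#' @export
setGeneric("regionRoles", function(x) standardGeneric("regionRoles"))

#' Coupling weight matrix
#' @param x A [CouplingMatrix-class].
#' @return The normalized nonnegative weight matrix.
#' @export
setGeneric("couplingWeights", function(x) standardGeneric("couplingWeights"))

#' Time grid of a trajectory
#' @param x A [SamplePath-class].
#' @return Numeric vector of times (ms).
#' @export
setGeneric("pathTimes", function(x) standardGeneric("pathTimes"))

#' State matrix of a trajectory
#' @param x A [SamplePath-class].
#' @return Numeric matrix (time x dimension), layout `[V, Z, W, c]`.
#' @export
setGeneric("pathStates", function(x) standardGeneric("pathStates"))

#' BOLD series matrix
#' @param x A [BoldSignal-class].
#' @return Numeric matrix (time x regions).
#' @export
setGeneric("boldSeries", function(x) standardGeneric("boldSeries"))

#' NMI coefficient matrix
#' @param x An [NmiNetwork-class].
#' @return Symmetric numeric matrix in `[0, 1]`.
#' @export
setGeneric("nmiValues", function(x) standardGeneric("nmiValues"))

#' Graph metrics table
#' @param x A [GraphMetricsResult-class].
#' @return data.frame of per-node metrics.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

## ---- methods ----

#' @rdname nRegions
setMethod("nRegions", "RegionSet", function(x) length(x@labels))
#' @rdname nRegions
setMethod("nRegions", "CouplingMatrix", function(x) nrow(x@weights))
#' @rdname nRegions
setMethod("nRegions", "SamplePath", function(x) length(x@regions@labels))
#' @rdname nRegions
setMethod("nRegions", "BoldSignal", function(x) ncol(x@series))
#' @rdname nRegions
setMethod("nRegions", "NmiNetwork", function(x) nrow(x@values))

#' @rdname regionLabels
setMethod("regionLabels", "RegionSet", function(x) x@labels)
#' @rdname regionLabels
setMethod("regionLabels", "SamplePath", function(x) x@regions@labels)
#' @rdname regionLabels
setMethod("regionLabels", "BoldSignal", function(x) x@labels)

#' @rdname regionRoles
setMethod("regionRoles", "RegionSet", function(x) x@roles)
#' @rdname regionRoles
setMethod("regionRoles", "SamplePath", function(x) x@regions@roles)

#' @rdname couplingWeights
setMethod("couplingWeights", "CouplingMatrix", function(x) x@weights)

#' @rdname pathTimes
setMethod("pathTimes", "SamplePath", function(x) x@times)
#' @rdname pathStates
setMethod("pathStates", "SamplePath", function(x) x@states)

#' @rdname boldSeries
setMethod("boldSeries", "BoldSignal", function(x) x@series)

#' @rdname nmiValues
setMethod("nmiValues", "NmiNetwork", function(x) x@values)

#' @rdname metricsTable
setMethod("metricsTable", "GraphMetricsResult", function(x) x@metrics)

## ---- show ----

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters with", length(object@values), "constants\n")
  v <- object@values
  cat("  dopamine block: V_max =", v["V_max"], "mM/ms, K_m =", v["K_m"],
      "mM, beta in [", v["beta_min"], ",", v["beta_max"],
      "], G_max =", v["G_max"], "\n")
  invisible(NULL)
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet of", length(object@labels), "regions\n")
  r <- object@roles
  cat("  LMC:", object@labels[r["lmc_left"]], "/", object@labels[r["lmc_right"]],
      "  SNc:", object@labels[r["snc_left"]], "/", object@labels[r["snc_right"]], "\n")
  invisible(NULL)
})

setMethod("show", "CouplingMatrix", function(object) {
  cat("CouplingMatrix", nrow(object@weights), "x", ncol(object@weights),
      "(largest row sum before scaling:", signif(object@maxRowSum, 4), ")\n")
  invisible(NULL)
})

setMethod("show", "SamplePath", function(object) {
  cat("SamplePath:", length(object@times), "time points,",
      ncol(object@states), "state dimensions (", nRegions(object), "regions ),",
      "t in [", min(object@times), ",", max(object@times), "] ms\n")
  cat("  scheme:", object@meta$scheme, " h:", object@meta$h, "ms  seed:",
      object@meta$seed, "\n")
  invisible(NULL)
})

setMethod("show", "BoldSignal", function(object) {
  cat("BoldSignal:", nrow(object@series), "samples x", ncol(object@series),
      "regions, interval", object@interval, "s, drive", object@drive, "\n")
  invisible(NULL)
})

setMethod("show", "NmiNetwork", function(object) {
  cat("NmiNetwork", nrow(object@values), "x", ncol(object@values),
      "(", object@bins, "bins, source:", object@source, ")\n")
  off <- object@values[upper.tri(object@values)]
  cat("  off-diagonal NMI: mean", signif(mean(off), 3), " range [",
      signif(min(off), 3), ",", signif(max(off), 3), "]\n")
  invisible(NULL)
})

setMethod("show", "GraphMetricsResult", function(object) {
  cat("GraphMetricsResult for", nrow(object@metrics), "nodes")
  if (object@nNull > 0) cat(" (normalized over", object@nNull, "null models)")
  cat("\n")
  print(utils::head(object@metrics, 5))
  if (nrow(object@metrics) > 5) cat("  ...\n")
  invisible(NULL)
})

setMethod("show", "PermutationTestResult", function(object) {
  cat("Paired max-statistic permutation test:", length(object@observed),
      "nodes,", object@nPerm, if (object@exhaustive) "sign patterns (exhaustive)"
      else "random sign flips", "\n")
  cat("  min adjusted p:", signif(min(object@pFWE), 4), "\n")
  invisible(NULL)
})
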