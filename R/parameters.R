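## Canonical parameter schema. Values are the published constants of the
## coupled neural/dopamine model; units are model units (mV, mS, ms, mM, kHz).

.parameterNames <- function() names(.defaultParameterValues())

.defaultParameterValues <- function() {
  c(
    ## calcium channels
    T_Ca = -0.01, d_Ca = 0.15, g_Ca = 1.1, V_Ca = 1.0,
    ## potassium channels
    T_K = 0.0, d_K = 0.3, g_K = 2.0, V_K = -0.7,
    ## sodium channels
    T_Na = 0.3, d_Na = 0.15, g_Na = 6.7, V_Na = 0.53,
    ## leak
    V_L = -0.5, g_L = 0.5,
    ## firing-rate sigmoids
    V_T = 0.54, Z_T = 0.0, d_V = 2.0, d_Z = 0.7,
    Q_Vmax = 1.0, Q_Zmax = 1.0,
    ## synaptic factors; a_ie and a_ne are means of per-region normal draws
    a_ee = 0.4, a_ei = 2.0, a_ie = 2.0, a_ne = 0.4, a_ni = 0.4,
    ## heterogeneity spreads (defaults; the source table prints a_ie and a_ne
    ## as distributions whose parameters are not machine-readable)
    a_ie_sd = 0.1, a_ne_sd = 0.05,
    ## potassium relaxation and NMDA/AMPA ratio
    phi = 0.7, tau_K = 1.0, r_NMDA = 0.25,
    ## noise: amplitude (1/ms) and inhibitory scaling factor
    delta = 0.3, b = 0.1,
    ## dopamine block
    V_max = 0.004,    # maximal re-uptake rate, mM/ms
    K_m = 0.125,      # Michaelis-Menten constant, mM
    c_0 = 0.05,       # tonic dopamine level, mM (initial condition)
    beta_min = 5e-4,  # production rate outside speech, mM per unit firing
    beta_max = 0.01,  # production rate during speech
    m_da = 0.2,       # antagonism parameter, 1/mM
    G_min = 1.0, G_max = 50.0
  )
}

#' Default model parameters
#'
#' Returns the published constants of the neural-population model with
#' dopaminergic modulation: ion-channel kinetics of the Breakspear-type
#' regional model, firing-rate sigmoids, synaptic factors, the additive-noise
#' amplitude, and the dopamine release/re-uptake/gain block.
#'
#' The inhibitory-to-excitatory (`a_ie`) and non-specific-to-excitatory
#' (`a_ne`) strengths are means of per-region normal distributions (spreads
#' `a_ie_sd`, `a_ne_sd`); see [sampleHeterogeneity()].
#'
#' @return A [ModelParameters-class] object.
#' @examples
#' p <- defaultModelParameters()
#' p[["K_m"]]
#' @export
defaultModelParameters <- function() {
  new("ModelParameters", values = .defaultParameterValues())
}

#' Construct model parameters with overrides
#'
#' @param ... Named scalar overrides of the defaults (unknown names are
#'   rejected).
#' @return A [ModelParameters-class] object.
#' @examples
#' modelParameters(G_max = 25)
#' @export
modelParameters <- function(...) {
  ov <- list(...)
  v <- .defaultParameterValues()
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(ov), names(v))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    v[names(ov)] <- vapply(ov, function(x) as.numeric(x)[1], numeric(1))
  }
  new("ModelParameters", values = v)
}

#' @describeIn defaultModelParameters Extract a single parameter by name.
#' @param x A [ModelParameters-class].
#' @param i Parameter name.
#' @export
setMethod("[[", "ModelParameters", function(x, i) {
  if (!i %in% names(x@values)) stop("unknown parameter: ", i)
  unname(x@values[[i]])
})

#' All parameter values as a named vector
#'
#' @param p A [ModelParameters-class].
#' @return Named numeric vector.
#' @export
parameterValues <- function(p) {
  stopifnot(is(p, "ModelParameters"))
  p@values
}
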