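## Dopamine release, Michaelis-Menten re-uptake, and the channel-permeability
## gain the SNc exerts on the laryngeal motor cortex.

#' Construct a task schedule
#'
#' @param mode `"rest"` or `"task"`.
#' @param cycleS Cycle length in seconds (default 10.6: 8.6 s speech
#'   production followed by a 2 s acquisition gap).
#' @param speechS Speech window per cycle in seconds (default 8.6).
#' @param nCycles Number of cycles.
#' @return A [TaskSchedule-class].
#' @examples
#' taskSchedule("task", nCycles = 50)
#' @export
taskSchedule <- function(mode = c("rest", "task"), cycleS = 10.6,
                         speechS = 8.6, nCycles = 50) {
  mode <- match.arg(mode)
  new("TaskSchedule", mode = mode, cycleS = cycleS, speechS = speechS,
      nCycles = as.numeric(nCycles))
}

#' Dopamine production rate \eqn{\beta(t)}
#'
#' Piecewise-constant rate: `beta_max` inside speech-production windows of a
#' task run and `beta_min` otherwise (including the whole of a rest run). The
#' switch is a step function at the window boundaries; graded dopamine release
#' emerges through the concentration dynamics, not through smoothing of
#' \eqn{\beta}.
#'
#' @param t Time in ms (vectorized).
#' @param schedule [TaskSchedule-class].
#' @param params [ModelParameters-class].
#' @return Production rate(s), mM per unit firing.
#' @export
productionRate <- function(t, schedule, params) {
  v <- parameterValues(params)
  if (schedule@mode == "rest") return(rep(v[["beta_min"]], length(t)))
  tc <- t %% (schedule@cycleS * 1000)
  ifelse(tc < schedule@speechS * 1000, v[["beta_max"]], v[["beta_min"]])
}

#' Michaelis-Menten dopamine re-uptake flux
#'
#' \eqn{u(c) = V_{max}\, c / (K_m + c)}: saturating, monotone increasing,
#' bounded by `V_max`.
#'
#' @param c Dopamine concentration (mM), nonnegative.
#' @param params [ModelParameters-class].
#' @return Uptake flux (mM/ms) in `[0, V_max)`.
#' @examples
#' uptakeFlux(0.125, defaultModelParameters())  # half-saturation: V_max / 2
#' @export
uptakeFlux <- function(c, params) {
  if (any(c < 0)) stop("dopamine concentration must be nonnegative")
  v <- parameterValues(params)
  v[["V_max"]] * c / (v[["K_m"]] + c)
}

#' Dopamine concentration dynamics
#'
#' Mass balance in each LMC: release proportional to the ipsilateral SNc
#' firing rate minus Michaelis-Menten re-uptake,
#' \eqn{\dot c = \beta(t)\, Q_{SNc} - V_{max} c / (K_m + c)}. The left LMC is
#' driven by the left SNc and the right by the right (strictly ipsilateral).
#'
#' @param c Length-2 concentration vector (mM), nonnegative.
#' @param Qsnc Length-2 vector of left/right SNc excitatory firing rates
#'   (kHz).
#' @param t Time (ms).
#' @param schedule [TaskSchedule-class].
#' @param params [ModelParameters-class].
#' @return Length-2 derivative (mM/ms).
#' @export
dopamineDrift <- function(c, Qsnc, t, schedule, params) {
  stopifnot(length(c) == 2, length(Qsnc) == 2)
  beta <- productionRate(t, schedule, params)
  beta * Qsnc - uptakeFlux(c, params)
}

#' Steady-state dopamine concentration under constant drive
#'
#' For a constant SNc firing rate `Q` and production rate `beta` with
#' `beta * Q < V_max`, the concentration dynamics admit the fixed point
#' \eqn{c^* = K_m \beta Q / (V_{max} - \beta Q)}. If `beta * Q >= V_max`
#' the uptake saturates and the concentration grows without settling; `Inf`
#' is returned with a warning.
#'
#' @param Q Constant firing rate (kHz).
#' @param beta Production rate (mM per unit firing).
#' @param params [ModelParameters-class].
#' @return The steady-state concentration (mM), or `Inf`.
#' @export
dopamineSteadyState <- function(Q, beta, params) {
  v <- parameterValues(params)
  inflow <- beta * Q
  if (inflow >= v[["V_max"]]) {
    warning("production ", inflow, " mM/ms meets or exceeds the maximal uptake ",
            v[["V_max"]], " mM/ms: uptake saturates and no steady state exists")
    return(Inf)
  }
  v[["K_m"]] * inflow / (v[["V_max"]] - inflow)
}

#' Dopamine-dependent gain on LMC channel permeability
#'
#' \eqn{G(c) = G_{min} + (G_{max} - G_{min}) \tanh(m\, c)} with the
#' antagonism parameter `m` controlling the overall impact of dopamine:
#' unity gain at zero dopamine (`G_min = 1`), monotone nondecreasing, bounded
#' above by `G_max`.
#'
#' @param c Dopamine concentration (mM), nonnegative (vectorized).
#' @param params [ModelParameters-class].
#' @return Gain in `[1, G_max]`.
#' @examples
#' dopamineGain(0, defaultModelParameters())  # exactly 1
#' @export
dopamineGain <- function(c, params) {
  if (any(c < 0)) stop("dopamine concentration must be nonnegative")
  v <- parameterValues(params)
  v[["G_min"]] + (v[["G_max"]] - v[["G_min"]]) * tanh(v[["m_da"]] * c)
}

#' Dopamine-modulated excitatory-to-excitatory strength
#'
#' The gain scales the LMC's functional excitatory coupling,
#' \eqn{\tilde a_{ee}(G) = G\, a_{ee}}, so that
#' \eqn{a_{ee} \le \tilde a_{ee} \le G_{max}\, a_{ee}} with equality at
#' `G = 1` (no dopamine) and `G = G_max`.
#'
#' @param gain Gain value(s) `>= 1`.
#' @param params [ModelParameters-class].
#' @param aee Base strength; defaults to the parameter `a_ee`.
#' @return Effective coupling strength (mS).
#' @export
modulatedAee <- function(gain, params, aee = NULL) {
  if (any(gain < 1)) stop("gain must be >= 1")
  if (is.null(aee)) aee <- parameterValues(params)[["a_ee"]]
  gain * aee
}

#' Dopamine-modulated potassium activation
#'
#' In the LMC dopamine raises the opening probability of the potassium
#' channels: the gain scales the relaxation target of the open fraction, so
#' the drift of `W` becomes \eqn{\phi\,(G(c)\, m_K(V) - W)/\tau_K}. At
#' `G = 1` this is identical to the unmodulated potassium term, and its
#' magnitude is bounded by \eqn{(\phi/\tau_K)(G + |W|)} since
#' \eqn{m_K \in [0, 1]}.
#'
#' @param W Open-channel fraction(s).
#' @param V Membrane potential(s) (mV).
#' @param gain Gain value(s) `>= 1`.
#' @param params [ModelParameters-class].
#' @return The potassium activation term (drift of `W`, per ms).
#' @export
modulatedPotassiumActivation <- function(W, V, gain, params) {
  if (any(gain < 1)) stop("gain must be >= 1")
  v <- parameterValues(params)
  mK <- channelOpenFraction(V, v[["T_K"]], v[["d_K"]])
  v[["phi"]] * (gain * mK - W) / v[["tau_K"]]
}
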