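## Balloon-Windkessel conversion of regional neural drive to simulated BOLD.

#' Canonical Balloon-Windkessel constants
#'
#' Signal decay rate `kappa` (1/s), autoregulatory feedback `gamma` (1/s),
#' mean transit time `tau` (s), vessel stiffness (Grubb) exponent `alpha`,
#' resting oxygen extraction fraction `rho`, resting venous volume fraction
#' `V0`, and neural efficacy `epsilon` (response per unit drive).
#'
#' @return Named numeric vector of constants.
#' @export
balloonConstants <- function() {
  c(kappa = 0.65, gamma = 0.41, tau = 0.98, alpha = 0.32, rho = 0.34,
    V0 = 0.02, epsilon = 1.0)
}

#' Balloon-Windkessel hemodynamic forward model
#'
#' Converts a per-region neural drive (by default the excitatory firing rate
#' \eqn{Q_V}) to a BOLD percent-signal-change series. Each region follows the
#' standard four-state system: vasodilatory signal
#' \eqn{\dot s = \epsilon z - \kappa s - \gamma (f - 1)}, blood inflow
#' \eqn{\dot f = s}, venous volume
#' \eqn{\tau \dot v = f - v^{1/\alpha}}, deoxyhemoglobin
#' \eqn{\tau \dot q = f E(f,\rho)/\rho - v^{1/\alpha} q / v}, with
#' \eqn{E(f, \rho) = 1 - (1-\rho)^{1/f}} and readout
#' \eqn{100\, V_0 (k_1 (1-q) + k_2 (1 - q/v) + k_3 (1 - v))},
#' \eqn{k_1 = 7\rho}, \eqn{k_2 = 2}, \eqn{k_3 = 2\rho - 0.2}. Zero drive
#' leaves the system at its fixed point (0% signal change).
#'
#' The system is integrated with a fixed-step fourth-order Runge-Kutta rule
#' (via \pkg{deSolve}) on the drive's own time grid, with the drive
#' interpolated linearly between samples.
#'
#' @param drive Numeric matrix (time x regions) of neural drive, or a
#'   [SamplePath-class] together with `params` (drive = firing rates).
#' @param dt Sampling interval of `drive` in seconds (ignored when `drive`
#'   is a [SamplePath-class]).
#' @param params [ModelParameters-class]; required when `drive` is a
#'   [SamplePath-class].
#' @param constants Hemodynamic constants, see [balloonConstants()]; all time
#'   constants must be positive.
#' @param labels Region labels (defaults to drive column names).
#' @return A [BoldSignal-class] on the dense drive grid.
#' @export
balloonWindkessel <- function(drive, dt = NULL, params = NULL,
                              constants = balloonConstants(), labels = NULL) {
  if (is(drive, "SamplePath")) {
    if (is.null(params)) stop("params needed to derive firing rates from a SamplePath")
    dt <- diff(drive@times[1:2]) / 1000  # ms -> s
    drive <- firingRates(drive, params)
  }
  if (is.null(dt) || dt <= 0) stop("positive drive sampling interval dt (s) required")
  drive <- as.matrix(drive)
  if (any(!is.finite(drive))) stop("neural drive must be finite")
  k <- constants
  if (any(k[c("kappa", "gamma", "tau", "alpha", "rho", "V0")] <= 0))
    stop("hemodynamic constants must be positive")
  if (is.null(labels)) labels <- colnames(drive)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(ncol(drive)))
  N <- ncol(drive)
  nT <- nrow(drive)
  times <- (seq_len(nT) - 1) * dt

  idx <- list(s = seq_len(N), f = N + seq_len(N), v = 2 * N + seq_len(N),
              q = 3 * N + seq_len(N))
  interp <- function(t) {
    # linear interpolation of all regional drives at time t
    pos <- t / dt
    i0 <- pmin(floor(pos), nT - 2)
    w <- pos - i0
    drive[i0 + 1, ] * (1 - w) + drive[i0 + 2, ] * w
  }
  deriv <- function(t, y, parms) {
    s <- y[idx$s]; f <- pmax(y[idx$f], 1e-6)
    v <- pmax(y[idx$v], 1e-6); q <- pmax(y[idx$q], 1e-6)
    z <- interp(t)
    E <- 1 - (1 - k[["rho"]])^(1 / f)
    fout <- v^(1 / k[["alpha"]])
    ds <- k[["epsilon"]] * z - k[["kappa"]] * s - k[["gamma"]] * (f - 1)
    df <- s
    dv <- (f - fout) / k[["tau"]]
    dq <- (f * E / k[["rho"]] - fout * q / v) / k[["tau"]]
    list(c(ds, df, dv, dq))
  }
  ## start each region at the fixed point of its initial drive so the series
  ## reflects neural fluctuations, not a shared onset ramp from zero flow
  z0 <- k[["epsilon"]] * drive[1, ]
  f0 <- 1 + z0 / k[["gamma"]]
  v0 <- f0^k[["alpha"]]
  q0 <- v0 * (1 - (1 - k[["rho"]])^(1 / f0)) / k[["rho"]]
  y0 <- c(rep(0, N), f0, v0, q0)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  v <- sol[, 1 + idx$v, drop = FALSE]
  q <- sol[, 1 + idx$q, drop = FALSE]
  k1 <- 7 * k[["rho"]]; k2 <- 2; k3 <- 2 * k[["rho"]] - 0.2
  bold <- 100 * k[["V0"]] * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
  colnames(bold) <- labels
  new("BoldSignal", series = unname(bold), interval = dt, drive = "Q_V",
      labels = labels)
}

#' Decimate a dense BOLD series to an acquisition TR
#'
#' Averages the dense signal over each acquisition window (anti-alias boxcar)
#' and emits one sample per TR. With `tr` equal to the dense interval this is
#' the identity.
#'
#' @param bold A [BoldSignal-class] on a dense grid.
#' @param tr Repetition time in seconds; must be at least the dense interval.
#' @return A [BoldSignal-class] sampled at `tr`.
#' @export
sampleAtTR <- function(bold, tr) {
  stopifnot(is(bold, "BoldSignal"))
  dt <- bold@interval
  if (tr < dt - 1e-12)
    stop("TR (", tr, " s) must be at least the dense sampling interval (",
         dt, " s)")
  nPer <- max(1L, round(tr / dt))
  x <- bold@series
  nOut <- nrow(x) %/% nPer
  if (nOut < 1) stop("series shorter than one TR")
  grp <- rep(seq_len(nOut), each = nPer)
  y <- rowsum(x[seq_len(nOut * nPer), , drop = FALSE], grp) / nPer
  new("BoldSignal", series = unname(y), interval = nPer * dt,
      drive = bold@drive, labels = bold@labels)
}
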