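---
title: "Modelling dopamine-modulated whole-brain dynamics with nigrosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dopamine-modulated whole-brain dynamics with nigrosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigrosim)
```

## The model

nigrosim simulates the averaged activity of coupled brain regions as a system
of stochastic differential equations. Each region is a conductance-based
neural population in the Breakspear tradition: the mean excitatory membrane
potential $V_i$ is driven by voltage-gated calcium, sodium and potassium
currents plus a leak term, an inhibitory population $Z_i$ feeds back onto it,
and the open-potassium-channel fraction $W_i$ relaxes toward its
voltage-dependent target,

$$\dot W_i = \phi\, (m_K(V_i) - W_i)/\tau_K .$$

Channel open fractions and population firing rates are sigmoids arising from
normally distributed thresholds,
$m_j(V) = \tfrac12\!\left(1 + \tanh\tfrac{V - T_j}{\delta_j}\right)$ and
$Q_V = \tfrac{Q_V^{max}}{2}\!\left(1 + \tanh\tfrac{V - V_T}{\delta_V}\right)$,
so all auxiliary quantities are bounded by construction. Regions interact
through a nonnegative structural coupling matrix $C$: the excitatory input to
region $i$ is $u_i = \sum_j c_{ij} Q_{V,j}$, with the diagonal carrying local
excitatory input (default 1 before scaling) and the whole matrix normalized
with respect to its largest row sum. Non-specific input is additive noise:
one *scalar* Wiener process multiplies a constant diffusion vector whose
excitatory components scale with $a_{ne}\,\delta$ and inhibitory components
with $b\,a_{ni}\,\delta$; the potassium and dopamine components carry no
noise. This scalar-noise structure is what makes an efficient derivative-free
strong order-1.5 scheme possible, but it also means every region sees the
same noise realization — a point that matters below.

Two regions form the nigro-cortical pathway. Dopamine released by the left
and right substantia nigra pars compacta (SNc) accumulates in the ipsilateral
laryngeal motor cortex (LMC) according to a mass balance

$$\dot c = \beta(t)\, Q_{SNc} - \frac{V_{max}\, c}{K_m + c},$$

with production gated by the task schedule ($\beta_{max}$ during 8.6 s speech
windows of each 10.6 s cycle, $\beta_{min}$ otherwise and throughout rest)
and saturating Michaelis–Menten re-uptake. Concentration maps to a
channel-permeability gain
$G(c) = G_{min} + (G_{max} - G_{min}) \tanh(m\,c)$ — unity at zero dopamine,
monotone, bounded by $G_{max} = 50$ — which multiplies the LMC's
excitatory-to-excitatory strength ($\tilde a_{ee} = G\,a_{ee}$, so
$a_{ee} \le \tilde a_{ee} \le G_{max} a_{ee}$) and the target of its
potassium activation ($\dot W = \phi\,(G\,m_K(V) - W)/\tau_K$, reflecting an
increased opening probability of the potassium channels). The functional
forms of the gain and of the modulated potassium activation are constrained
rather than uniquely determined by their published properties (unit gain at
zero, monotonicity, boundedness, proportional drift bounds); the forms above
are the package's choices among the admissible candidates, using only linear,
hyperbolic and Michaelis–Menten elements so the drift remains locally
Lipschitz with linear growth on the physical state domain.

State layout is the concatenation $[V\,(N),\ Z\,(N),\ W\,(N),\ c\,(2)]$,
dimension $3N + 2$, stable across all I/O.

## Numerical integration

The model has constant additive scalar noise, so the explicit strong
order-1.5 Runge–Kutta family specializes to a three-drift-evaluation scheme
with no diffusion derivatives. With supporting values
$\Upsilon_\pm = Y_n + a\,h \pm b\sqrt h$,

$$Y_{n+1} = Y_n + b\,\Delta W + \tfrac h2 a
  + \left(\tfrac h4 + \tfrac{\Delta Z}{2\sqrt h}\right) a(t+h, \Upsilon_+)
  + \left(\tfrac h4 - \tfrac{\Delta Z}{2\sqrt h}\right) a(t+h, \Upsilon_-),$$

where $\Delta W \sim N(0, h)$ and the time-integrated increment $\Delta Z$
with $\mathrm{Var}(\Delta Z) = h^3/3$, $\mathrm{Cov}(\Delta W, \Delta Z) =
h^2/2$ are built from two independent standard normals per step,
$\Delta W = U_1\sqrt h$, $\Delta Z = \tfrac12 h^{3/2}(U_1 + U_2/\sqrt 3)$.
The comparison scheme is Euler–Maruyama (the Milstein correction vanishes for
additive noise; with zero diffusion it is explicit Euler). Both schemes are
validated by empirical strong-convergence studies over step sizes $2^{-3}$
to $2^{-7}$. On the nonlinear benchmark $dX = (-aX - X^3)dt + \sigma dW$
(fine-step reference on the same Brownian path, with exact aggregation of
the time-integrated increments) the measured slopes are the nominal 1.5 and
1.0. A subtlety worth recording: on the Ornstein–Uhlenbeck equation — the
obvious exactly-solvable benchmark — the order-1.5 scheme *superconverges*
to slope $\approx 2$, because with additive noise its leading $h^{1.5}$
error term is proportional to the drift's second derivative, which vanishes
for linear drift. The OU study (exact solution coupled to the path via
$X_{n+1} = X_n e^{-ah} + \sigma(\Delta W_n - a\,\Delta Z_n)$) is retained
as an unbiasedness check and shows slopes $\approx 2$ and 1.0.

The working step size is $h = 0.1$ ms, small enough for dopamine release and
re-uptake (whose linearized time constant is $K_m/V_{max} \approx 31$ ms) to
evolve smoothly; the output stride (default every 100 steps, 10 ms) decouples
storage from integration. Dopamine concentrations are clamped at zero after
each step: the continuous model preserves nonnegativity, but a discrete step
can undershoot. Whether the original analysis post-processed states between
steps is not documented; clamping only the dopamine block is this package's
choice. One global seed is expanded into named substreams (initial state,
heterogeneity, connectome, simulation, null models, permutations) so each
stage is independently reproducible; a rest run and a task run with the same
seed share a bit-identical initial state and Wiener path and differ only
through $\beta(t)$. The R generator (Mersenne-Twister with inversion) is the
documented RNG; the compiled integrator draws from the same stream, and a
pure-R reference engine reproduces its trajectories to round-off.

## Hemodynamics

Regional excitatory firing rate $Q_V$ (configurable) drives a standard
Balloon–Windkessel system per region (signal decay $\kappa = 0.65\,s^{-1}$,
autoregulation $\gamma = 0.41\,s^{-1}$, transit time $\tau = 0.98$ s, Grubb
exponent $\alpha = 0.32$, resting extraction $\rho = 0.34$, $V_0 = 0.02$),
with BOLD read out in percent signal change. The constants are the canonical
values of the hemodynamic-modelling literature and are exposed (and
overridable) through `balloonConstants()`. Each region is initialized at the fixed
point of its initial drive, so the series reflects neural fluctuations
rather than a shared onset ramp from zero flow; with zero drive the output
is identically zero. The dense signal is decimated to an acquisition TR by
boxcar averaging (anti-aliasing) over each TR window.

## Connectivity and graph analysis

Functional connectivity is normalized mutual information,
$\mathrm{NMI} = I(X;Y)/\sqrt{H(X)H(Y)}$, estimated with equal-width
histograms (default $\lceil\sqrt n\rceil$ bins; the estimator was not pinned
down by the original description, and the histogram bin count is exposed).
NMI is symmetric, lies in $[0,1]$, equals 1 for identical series, and a
constant series — having zero entropy — is assigned NMI 0 with a warning.
Graph metrics on the resulting weighted, fully dense networks (no
thresholding anywhere): nodal strength and degree, Onnela weighted
clustering (geometric-mean triangle weights, max-scaled) and Latora local
efficiency (inverse shortest paths within each node's neighborhood, edge
lengths $1/w$). Clustering and efficiency are additionally normalized by
their per-node means over 100 null-model surrogates that conservatively
preserve size, density and the exact weight multiset (a seeded weight
shuffle over a random topology of equal edge count). Rest/task differences
are tested with a paired two-sample permutation test: sign flips of whole
replicates' difference vectors, per-node mean differences as statistics, and
family-wise error control by the maximal statistic across nodes, with the
identity permutation included; an exhaustive enumeration mode covers small
replicate counts exactly. The significance convention is $\alpha = 0.05$.
Calibration uses 20 paired replicates per dataset, a typical fMRI cohort
size.

## Synthetic study conditions

All inputs that originally came from human data are generated: a surrogate
structural connectome (symmetric, log-normal weights, density 0.3 — sparse
and heavy-tailed like streamline-count matrices), the 70-region manifest (64
cortical + 6 subcortical labels, LMC and SNc roles resolvable by name),
per-region heterogeneity of $a_{ie} \sim N(2.0,\,0.1)$ and
$a_{ne} \sim N(0.4,\,0.05)$ (package defaults: spreads of a few percent of
the mean, enough to desynchronize regions without destabilizing a node), and
the task schedule (10.6 s cycles, 8.6 s speech). The demonstration
experiment runs 10 regions for 20 cycles per condition — about 20 s of
compute per condition — while the full 70-region, 50-cycle configuration is
a parameter change away. Initial potentials are drawn uniformly in
$[-0.1, 0.1]$ mV around rest, $W$ starts at its potassium target and $c$ at
the tonic level $c_0 = 0.05$ mM.

What the generator does *not* emulate: tractography weight structure beyond
density and tail shape (no distance dependence, no hubs), physiological
scanner noise, and any empirical inter-subject variability. Passing tests on
synthetic inputs therefore validates the machinery — solver, kinetics,
estimators, tests — not claims about real connectomes.

## A known, deliberate limitation

Under these equations and synthetic inputs the dopamine-modulated condition
does **not** show an increase in mean nodal strength, clustering and
efficiency over rest — the direction reported for empirical speech-production
networks; the package's own acceptance check of that direction fails and is
left failing. The mechanism is instructive: because the noise is a single
scalar Wiener process, all regions share one noise realization and the
resting network already sits near an NMI coherence ceiling. Dopamine alters
the two LMC nodes' local dynamics, which *decorrelates* them from the
common-noise mode, lowering the network means regardless of whether the
potassium gain scales the open fraction, the gating kinetics, or its
inverse, and regardless of TR or bin choices. Reproducing the empirical
direction evidently requires structural connectivity with properties the
synthetic generator does not emulate (real tract-density structure with
strongly coupled motor hubs) or a dynamical regime this parameter set does
not reach. The pipeline reports whatever direction the model produces;
nothing is tuned toward a desired outcome.

## Problem sizes used in the checks

Convergence: 200 paths, $h \in \{2^{-3},\dots,2^{-7}\}$, $T = 1$. Increment
moments: $10^6$ draws. Drift oracle: 100 random 8-region instances at
$10^{-12}$. Boundedness: 10 regions, 60 s at $h = 0.1$ ms. Graph oracles:
100 random graphs with $N \le 10$ at $10^{-12}$. FWE calibration: 70 nodes,
20 pairs, 1000 replicates of 1000 permutations. Direction of effect: 10
regions, 20 cycles, 5 seeds. These sizes were chosen so the whole suite runs
on a laptop-class single core in minutes.

## Worked example

```{r example, eval = FALSE}
ex <- demoExperiment(N = 10, nCycles = 20, seed = 1)
ex$task$nmi
head(metricsTable(ex$task$metrics))

## paired testing across seeds
mats <- lapply(1:5, function(s) {
  e <- demoExperiment(N = 10, nCycles = 20, seed = s, nNull = 0)
  list(rest = metricsTable(e$rest$metrics)$strength,
       task = metricsTable(e$task$metrics)$strength)
})
a <- do.call(rbind, lapply(mats, `[[`, "task"))
b <- do.call(rbind, lapply(mats, `[[`, "rest"))
pairedPermutationTest(a, b, nPerm = 1000, seed = 1)
```
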