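---
title: "Methods: stochastic finite-difference schemes for a ratio-dependent predator-prey system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic finite-difference schemes for a ratio-dependent predator-prey system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochpredprey)
```

## The model

The package simulates the densities of a prey population $P(x,t)$ and a
predator population $Q(x,t)$ on an interval $[0, L]$, coupled through a
ratio-dependent functional response and perturbed by multiplicative noise
that depends on time only:

$$
\frac{\partial P}{\partial t}
  = \sigma_1 \frac{\partial^2 P}{\partial x^2}
  + P(a - bP) - \frac{cPQ}{mQ + P} + \eta_1 P \dot B_1(t),
\qquad
\frac{\partial Q}{\partial t}
  = \sigma_2 \frac{\partial^2 Q}{\partial x^2}
  - dQ + \frac{fPQ}{mQ + P} + \eta_2 Q \dot B_2(t),
$$

with homogeneous Neumann (zero-flux) boundaries. The prey grows
logistically ($a$ growth rate, $a/b$ carrying capacity), predation follows
the ratio-dependent term $cPQ/(mQ+P)$ — per-capita predation depends on
the prey-to-predator ratio rather than on prey density alone — and a
fraction governed by the conversion rate $f$ of consumed prey becomes
predator growth against the mortality $d$. $B_1$, $B_2$ are standard
scalar Wiener processes and $\eta_1$, $\eta_2$ the noise strengths.

All parameters are strictly positive rates except $\eta_i \ge 0$;
`spp_params()` enforces this. The bundled experiment values are
$a = 1.1$, $b = 0.7$, $c = 2.1$, $m = 1$, $d = 0.5$,
$\sigma_i \in \{0.1, 1\}$, $\eta_i = 0.01$, with the conversion rate $f$
acting as the regime control parameter.

## Equilibria and the coexistence criterion

The reaction system has a predator-free equilibrium and, when feasible, a
coexistence equilibrium

$$
P^* = \frac{(am - c)f + cd}{bmf}, \qquad
Q^* = \frac{(f - d)(amf - cf + cd)}{bdm^2f},
$$

feasible iff $f > d$ and $(am - c)f + cd > 0$. Its local character is
decided by the sign of
$\Lambda = (c - mf)d^2 - (c - ma - md)f^2$: positive means a stable
coexistence focus, negative an unstable one with a periodic orbit
(a Hopf-type transition). `hopf_threshold_f()` solves $\Lambda(f) = 0$ in
closed form; for the bundled coefficients the threshold is
$f^* \approx 0.80475$.

Two deliberate conventions:

* **Predator-free point.** The prey drift $P(a - bP)$ vanishes at
  $P = a/b$, so the package reports $(a/b, 0)$ — for the bundled values
  $(11/7, 0) \approx (1.571, 0)$ — and the diagnostics test prey
  convergence against $a/b$, not against the conventional unit-density
  label sometimes attached to this state.
* **Ratio guard.** The ratio term is defined as exactly $0$ when
  $mQ + P = 0$ (an exact branch, no epsilon smoothing), so the extinction
  state $(0,0)$ is a bit-exact fixed point of the drift and of both
  discrete schemes.
* $\Lambda$ is reported raw and "neutral" declared only at exact zero;
  callers choose their own tolerances.

## The two schemes

With $n$ intervals ($h = L/n$, nodes $x_m = mh$, $m = 0..n$), time step
$\Delta\tau$, diffusion numbers $D_i = \Delta\tau\,\sigma_i/h^2$, and
Wiener increments $\Delta B_i \sim N(0, \Delta\tau)$ applied identically
at every node (the noise depends on time only):

**Stochastic forward Euler (SFE)** — explicit forward-time centred-space
with an Euler–Maruyama noise term:

$$
P_m^{k+1} = D_1(P_{m+1}^k + P_{m-1}^k) + (1 - 2D_1)P_m^k
 + \Delta\tau\,P_m^k(a - bP_m^k)
 - c\Delta\tau\,\tfrac{P_m^kQ_m^k}{mQ_m^k + P_m^k}
 + \eta_1 P_m^k \Delta B_1,
$$

and analogously for $Q$ with $(1 - 2D_2 - d\Delta\tau)$ and
$+f\Delta\tau$ ratio term. Outputs are never clipped: the scheme's
negative and divergent behaviour at large $D$ is part of what the package
demonstrates.

**Stochastic non-standard finite difference (NSFD)** — a Mickens-style
construction that moves every loss term into the denominator:

$$
P_m^{k+1} = \frac{D_1(P_{m+1}^k + P_{m-1}^k) + (1 + a\Delta\tau)P_m^k
 + \eta_1 P_m^k \Delta B_1}
 {1 + 2D_1 + b\Delta\tau P_m^k + c\Delta\tau\,\tfrac{Q_m^k}{mQ_m^k + P_m^k}},
\qquad
Q_m^{k+1} = \frac{D_2(Q_{m+1}^k + Q_{m-1}^k) + Q_m^k
 + f\Delta\tau\,\tfrac{P_m^kQ_m^k}{mQ_m^k + P_m^k}
 + \eta_2 Q_m^k \Delta B_2}
 {1 + 2D_2 + d\Delta\tau}.
$$

With zero noise and nonnegative input, both numerators and denominators
are nonnegative, so nonnegativity is preserved *unconditionally* — for any
$\Delta\tau$ and $h$. The fixed points of the NSFD map coincide exactly
with the continuous equilibria (the denominator construction cancels at a
drift root), so the scheme does not bias the steady states.

One correction is built in: the predator numerator carries the $Q_m^k$
term. Without it the update is inconsistent — a spatially constant field
would collapse by a factor $\approx 1/(1+2D_2)$ in a single step — and the
scheme's own linearized form used in the stability analysis includes the
term. Some printed statements of the scheme omit it; the implementation
treats that as a typo.

**Boundaries** are homogeneous Neumann via second-order ghost reflection
(node $-1 \mapsto 1$, $n+1 \mapsto n-1$). **Divergence** is detected by
the loop, not the steppers: any non-finite value or magnitude above a cap
(default $10^6$) halts the run and records the step. The probe node
defaults to the midpoint $\lfloor n/2 \rfloor$ and snapshots default to
every $N/50$ steps.

## Noise design

The driving noise is scalar in space: one increment per species per step,
drawn from substreams derived from a single master seed by fixed offsets,
so a whole experiment is reproducible from one integer. Two species modes
are supported — independent paths (the default, matching the two-process
formulation) and a shared path (the experiment statement writes a single
$\dot B(t)$ in both equations); which one underlies the published figures
is not stated, and ensemble means at $\eta = 0.01$ are insensitive to the
choice. `refine_increments()` produces conditional-Gaussian refinements
whose blocks sum exactly to the coarse increments, which is what couples
trajectories across step sizes in the convergence diagnostics.

## Stability analysis

`stability_report()` evaluates the Von Neumann amplification factors of
the schemes linearized about exponential growth (prey, rate $a$) and decay
(predator, rate $d$), on a 1025-point grid of $\theta \in [0, \pi]$
(the extrema are quadratics in $\sin^2(\theta/2)$, so this grid is far
finer than needed). The mean-square criterion is
$E|g|^2 \le 1 + \chi\,\Delta\tau$; the report computes the smallest
admissible constant

$$
\chi_{\min} = \max\Big(0, \frac{\max_\theta |g_{\mathrm{det}}|^2 - 1}{\Delta\tau}\Big)
 + |\eta_{\mathrm{eff}}|^2,
$$

where $\eta_{\mathrm{eff}}$ is the noise gain of the scheme's update ($\eta_i$
for SFE; $\eta_1/(1+2D_1)$ and $\eta_2/(1+2D_2+d\Delta\tau)$ for NSFD, as in
the schemes' own mean-square bounds). The literal condition
$|g_{\mathrm{det}}|^2 \le 1$ is reported separately as informational: it can
never hold at $\theta = 0$ for the prey when $a > 0$, because low
frequencies genuinely grow at the reaction rate — exactly the $O(\Delta\tau)$
growth the $\chi$ term absorbs. The default tolerance
$\chi_{\mathrm{tol}} = \eta_1^2 + \eta_2^2 + 2\max(a, d) + 1$ admits that
reaction-driven growth while rejecting diffusion-driven blow-up; it is a
package default, callers can tighten or relax it.

The NSFD predator factor satisfies $|g_{\mathrm{det}}| < 1$ for every
frequency and every admissible $(D_2, d\Delta\tau)$, since
$|1 + 2D_2 - 4D_2 s| \le 1 + 2D_2 < 1 + 2D_2 + d\Delta\tau$ for
$s \in [0, 1]$ — the unconditional-stability half of the scheme dichotomy.

## Diagnostics

* `steady_state_distance()` time-averages the stored snapshots over the
  final window (default 10% of the run, matching the steady-state
  protocol below) node by node and takes the worst deviation from a
  reference pair.
* `oscillation_metrics()` discards the first 20% of a probe series as
  transient (the experiments give no burn-in; 20% is comfortably past the
  observed transients), counts crossings of a reference level and averages
  the per-segment maximal excursion.
* `strong_self_convergence()` couples runs at $\Delta\tau, \Delta\tau/2,
  \ldots$ through refined increments and reports RMS terminal
  discrepancies; in the noise-free limit the observed order is the
  classical first order of explicit stepping.
* `empirical_consistency()` measures the mean-square gap between the
  continuous one-step operator applied to a smooth manufactured profile
  (time integrals by composite trapezoid over 64 subintervals per step —
  quadrature error far below the scheme residual being measured — and the
  stochastic integral sampled left-endpoint with conditional refinements
  of the very increment the scheme uses) and the discrete operator, along
  a refinement sequence with $\Delta\tau \propto h^2$. Residuals must
  shrink along the sequence; for profiles constant in space and time both
  operators evaluate identical expressions and the residual is exactly
  zero. This is an empirical surrogate for the schemes' mean-square
  consistency, not a proof, and no convergence *rate* is claimed for the
  stochastic case.

## The experiment presets

`spp_presets()` bundles the five published experiments: stable coexistence
($f = 0.79$), oscillation ($f = 0.80$, $\sigma = 1$), predator-free
($f = 0.4$, $\Delta\tau = 0.01$), extinction of both species ($f = 0.84$),
and the stiff-diffusion dichotomy demo ($\sigma = 1$, $L = 10$, $n = 60$,
so $D = 3.6$). All use constant initial densities $P \equiv 0.6$,
$Q \equiv 0.4$, $N = 5000$ steps, and $\eta = 0.01$.

One preset deviates deliberately from literally constant initial data.
With bit-exactly constant profiles, scalar-in-space noise, and
symmetry-preserving Neumann stencils, every node computes identical
arithmetic, the diffusion stencil cancels exactly at every step, and both
schemes collapse to the same scalar iteration — the unstable spatial modes
of the forward Euler scheme at $D = 3.6$ are never excited and the
dichotomy cannot be observed. Any realistic field has spatial variation
(and the published surface plots clearly do), so the demo preset perturbs
the constant state by a relative cosine, $P_0(x) = 0.6\,(1 + 0.01\cos(\pi
x/L))$ and likewise for $Q_0$. The demo is insensitive to the amplitude:
the Nyquist mode grows by $|g| \approx 13$ per step, so even roundoff-level
asymmetry diverges within a few dozen steps, while the NSFD run is
indifferent to the perturbation. The other four presets keep the printed
constant initial data exactly (`perturb = 0`).

Reported steady values: at $f = 0.79$ the simulated ensemble settles at a
space-time average near $(0.47, 0.27)$; the closed-form equilibrium is
$(0.47016, 0.27269)$. The slight displacement of the simulated average
below $P^*$ is the expected effect of averaging a noisy focus over a
finite window, not a scheme bias (the NSFD fixed points are exact).

## Problem sizes and numerical choices

The published experiment size ($n = 100$ intervals, $N = 5000$ steps) runs
in well under a second per trajectory, so the steady-state checks use it
directly with 5–10 seed ensembles. Property-style tests (positivity,
refinement monotonicity, consistency) use smaller grids ($n = 20$–$40$,
$N \le 100$, 2–8 paths), chosen so each property is exercised far from its
trivial regime while the whole suite stays quick. "$n = 100$" is read as
interval count (101 nodes); this is configurable. The divergence cap of
$10^6$ is arbitrary but irrelevant within several orders of magnitude:
once the SFE instability triggers, iterates pass any fixed cap within a
couple of steps.

## Limitations

* The Von Neumann analysis is scalar (per species, frozen linearization);
  no claim is made about the coupled nonlinear system's stability margins,
  and near the Hopf threshold (e.g. $f = 0.80$, where $\Lambda \approx
  +0.005$ is marginally positive) noise and diffusion can sustain
  oscillations the sign of $\Lambda$ alone does not predict. The package
  therefore reports, and does not assert, the near-threshold behaviour.
* The noise is one-dimensional in each equation and scalar in space;
  space-time white noise and colored noise are out of scope, as are 2-D
  domains, Turing-pattern analysis, and implicit or adaptive solvers.
* Strong convergence *orders* for the stochastic schemes are not claimed;
  the self-convergence table is a monotonicity diagnostic.
* The synthetic experiments emulate the published study conditions
  (constant initial data, small multiplicative noise, moderate grids).
  Passing them shows the schemes behave as analysed under those
  conditions; it says nothing about parameter regions far outside the
  admissible ranges validated here.
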