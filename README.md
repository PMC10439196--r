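# stochpredprey

Simulation and analysis of a **ratio-dependent predator–prey
reaction–diffusion system perturbed by multiplicative time noise**, for
ecological modellers studying how environmental randomness interacts with
dispersal and predation, and for numerical analysts interested in
positivity-preserving stochastic schemes.

The model couples prey density $P(x,t)$ and predator density $Q(x,t)$ on
an interval with zero-flux boundaries:

$$
P_t = \sigma_1 P_{xx} + P(a - bP) - \frac{cPQ}{mQ+P} + \eta_1 P \dot B_1(t),
\qquad
Q_t = \sigma_2 Q_{xx} - dQ + \frac{fPQ}{mQ+P} + \eta_2 Q \dot B_2(t),
$$

with logistic prey growth (rate $a$, carrying capacity $a/b$), a
ratio-dependent functional response (capturing rate $c$, half-saturation
$m$), predator mortality $d$ and conversion rate $f$, scalar Wiener
processes $B_1, B_2$ and noise strengths $\eta_1, \eta_2$.

The package provides:

* two explicit time-stepping schemes — a **stochastic forward Euler**
  (SFE) scheme, conditionally stable and capable of producing negative
  densities, and a Mickens-type **stochastic non-standard finite
  difference** (NSFD) scheme that is unconditionally positivity-preserving
  with fixed points exactly at the continuous equilibria;
* closed-form **equilibrium and coexistence-stability analysis**,
  including the conversion-rate threshold where the coexistence point
  loses stability (`spp_equilibria()`, `hopf_threshold_f()`);
* **Von Neumann amplification-factor reports** under the mean-square
  criterion $E|g|^2 \le 1 + \chi\Delta\tau$ (`stability_report()`);
* diagnostics: steady-state distance, positivity/divergence reports,
  oscillation metrics, **strong self-convergence** with coupled Brownian
  refinement, and an **empirical mean-square consistency** check against
  manufactured solutions;
* five **presets** reproducing the published experiments across the
  regimes of the conversion rate `f` (coexistence, oscillation,
  predator-free, extinction, and a stiff-diffusion demo where SFE diverges
  while NSFD stays positive), plus a thin command-line front end
  (`inst/cli/predprey`) and YAML config I/O.

## Worked example

```r
library(stochpredprey)

p <- spp_params(a = 1.1, b = 0.7, c = 2.1, m = 1, f = 0.79, d = 0.5,
                sigma1 = 0.1, sigma2 = 0.1, eta1 = 0.01, eta2 = 0.01)
spp_equilibria(p)
#> Equilibria of the ratio-dependent predator-prey reaction system
#>   predator-free point : (P, Q) = (1.57143, 0)
#>   coexistence point   : (P*, Q*) = (0.470163, 0.272694)
#>   criterion Lambda    : 0.01545  -> stable
```

The criterion $\Lambda = (c-mf)d^2 - (c-ma-md)f^2$ is positive, so the
coexistence point $(P^*, Q^*)$ is a stable focus; the NSFD run settles
onto it:

```r
g <- spp_grid(L = 30, n = 100, delta_tau = 0.1, N = 5000)
w <- wiener_increments(g$N, g$delta_tau, seed = 1)
sim <- spp_simulate("nsfd", p, g, make_initial_state(g, 0.6, 0.4), w)
summary(sim)
#> NSFD scheme: 5000 steps
#>   space-time mean over final 10% of steps: P = 0.469393, Q = 0.266975
#>   final P range [0.5395, 0.5395]; Q range [0.2835, 0.2835]
#>   min value 0.1277, 0 negative entries
```

The windowed space-time average `(0.469, 0.267)` sits at the stable
coexistence point (the closed forms give `(0.4702, 0.2727)`); the density
never goes negative. On a stiff grid (diffusion number $D = 3.6$) the
forward Euler scheme does exactly what the stability analysis predicts:

```r
run_preset("fig9_stiff_diffusion", "sfe", seed = 1)
#> Stochastic predator-prey simulation (SFE scheme)
#>   grid: 61 nodes on [0, 10], 19/5000 steps of 0.1 completed
#>   noise: independent (seed 1)
#>   DIVERGED at step 19 (cap 1e+06)
#>   min value observed -1.687e+07; negative entries: 321

stability_report("sfe", spp_params(1.1, 0.7, 2.1, 1, 0.7, 0.5, 1, 1, 0.01, 0.01),
                 spp_grid(10, 60, 0.1, 5000))
#> Von Neumann mean-square stability (chi_tol = 3.2)
#>  scheme  species  max_g2 worst_theta minimal_chi verdict literal_condition
#>     sfe     prey 176.624       3.142     1756.24   FALSE             FALSE
#>     sfe predator 180.903       3.142     1799.03   FALSE             FALSE
```

`minimal_chi` is the smallest constant for which the mean-square bound
holds: about 1756 for SFE here (hopeless), versus about 0.27 for the NSFD
prey factor on the same grid — the NSFD run completes all 5000 steps with
every value nonnegative and finite (`run_preset("fig9_stiff_diffusion",
"nsfd", seed = 1)`).

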