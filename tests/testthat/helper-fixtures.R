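# Shared fixtures: the stable-coexistence parameter set used throughout the
# published experiments, and a tiny-step RK4 integrator of the reaction ODEs
# used as an independent oracle for the noise-free, diffusion-free limit.

fig1_params <- function(f = 0.79, sigma = 0.1, eta = 0.01) {
  spp_params(a = 1.1, b = 0.7, c = 2.1, m = 1, f = f, d = 0.5,
             sigma1 = sigma, sigma2 = sigma, eta1 = eta, eta2 = eta)
}

# Classical RK4 on the reaction ODEs with a fixed tiny step; independent of
# the package's steppers (direct drift arithmetic, no ratio-guard shortcut
# needed away from the origin).
rk4_reaction <- function(P0, Q0, p, T, dt = 1e-3) {
  drift <- function(u) {
    den <- p$m * u[2] + u[1]
    r <- if (den == 0) 0 else u[1] * u[2] / den
    c(u[1] * (p$a - p$b * u[1]) - p$c * r,
      -p$d * u[2] + p$f * r)
  }
  n <- ceiling(T / dt)
  dt <- T / n
  u <- c(P0, Q0)
  for (i in seq_len(n)) {
    k1 <- drift(u)
    k2 <- drift(u + dt / 2 * k1)
    k3 <- drift(u + dt / 2 * k2)
    k4 <- drift(u + dt * k3)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  u
}

# Random admissible parameter set (positive rates, moderate magnitudes).
random_params <- function() {
  spp_params(a = runif(1, 0.2, 2), b = runif(1, 0.2, 2),
             c = runif(1, 0.2, 3), m = runif(1, 0.5, 2),
             f = runif(1, 0.2, 2), d = runif(1, 0.1, 1),
             sigma1 = runif(1, 0.01, 1), sigma2 = runif(1, 0.01, 1),
             eta1 = runif(1, 0, 0.05), eta2 = runif(1, 0, 0.05))
}
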