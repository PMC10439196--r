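# small helper: a completed noise-free run held near its start
tiny_sim <- function(P0 = 0.6, Q0 = 0.4, N = 10) {
  p <- spp_params(1.1, 0.7, 2.1, 1, 0.79, 0.5, 1e-300, 1e-300, 0, 0)
  # vanishing reaction influence is not available, so use a 0-step-like grid:
  # constant equilibria are tested through exact fixed points instead
  g <- spp_grid(30, 10, 1e-9, N)
  spp_simulate("nsfd", p, g, make_initial_state(g, P0, Q0))
}

test_that("steady-state distance measures the windowed deviation from a point", {
  # a state held (numerically) at its initial value: dt ~ 1e-9 freezes it
  sim <- tiny_sim(0.6, 0.4)
  expect_equal(steady_state_distance(sim, c(0.6, 0.4)), 0, tolerance = 1e-8)
  expect_equal(steady_state_distance(sim, c(0.4699, 0.2719)),
               max(0.6 - 0.4699, 0.4 - 0.2719), tolerance = 1e-7)
  # prey-only point at the carrying capacity
  sim2 <- tiny_sim(1.1 / 0.7, 0)
  expect_equal(steady_state_distance(sim2, c(1.1 / 0.7, 0)), 0, tolerance = 1e-8)
  expect_error(steady_state_distance(sim, c(0.6, 0.4), window = 0),
               "window")
  div <- run_preset("fig9_stiff_diffusion", "sfe", seed = 2)
  expect_error(steady_state_distance(div, c(0.6, 0.4)), "diverged")
})

test_that("positivity/divergence report summarises stored diagnostics", {
  sim <- tiny_sim()
  rep <- positivity_divergence_report(sim)
  expect_gt(rep$min_value, 0)
  expect_identical(rep$n_negative, 0L)
  expect_false(rep$diverged)
  expect_true(is.na(rep$divergence_step))

  div <- run_preset("fig9_stiff_diffusion", "sfe", seed = 2)
  repd <- positivity_divergence_report(div)
  expect_true(repd$diverged)
  expect_gt(repd$n_negative, 0)
  expect_lt(repd$min_value, 0)
  expect_false(is.na(repd$divergence_step))
})

test_that("oscillation metrics recover a synthetic sinusoid and its invariances", {
  k <- seq_len(5000)
  ref <- 0.47
  osc <- oscillation_metrics(ref + sin(2 * pi * k / 100), ref)
  expect_gte(osc$crossings, 78)
  expect_lte(osc$crossings, 82)
  expect_gt(osc$amplitude, 0.9)
  expect_lte(osc$amplitude, 1.0 + 1e-12)
  # shift invariance: adding a constant to both series and reference
  osc2 <- oscillation_metrics(3.2 + ref + sin(2 * pi * k / 100), 3.2 + ref)
  expect_equal(osc2$crossings, osc$crossings, tolerance = 0.05)
  expect_equal(osc2$amplitude, osc$amplitude, tolerance = 1e-6)
  # monotone decay crosses at most once
  mono <- oscillation_metrics(exp(-k / 500), 0.01)
  expect_lte(mono$crossings, 1)
  expect_identical(oscillation_metrics(rep(ref, 100), ref),
                   list(crossings = 0L, amplitude = 0))
  expect_error(oscillation_metrics(1:5, 0), "at least 10")
})

test_that("the oscillatory regime oscillates around the coexistence point", {
  p <- fig1_params(f = 0.80, sigma = 1)
  g <- spp_grid(30, 50, 0.1, 3000)
  w <- wiener_increments(g$N, g$delta_tau, seed = 21)
  sim <- spp_simulate("nsfd", p, g, make_initial_state(g, 0.6, 0.4), w)
  eq <- spp_equilibria(p)
  osc <- oscillation_metrics(sim$probe$P, eq$coexistence_point[["P"]])
  expect_gt(osc$crossings, 10)
  expect_gt(osc$amplitude, 0.01)
})

test_that("coupled-path refinement discrepancies shrink monotonically", {
  p <- fig1_params()
  g <- spp_grid(30, 20, 0.1, 40)
  init <- make_initial_state(g, 0.6, 0.4)
  tab <- strong_self_convergence("nsfd", p, g, init, n_levels = 3,
                                 n_paths = 8, seed = 5)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$rms_discrepancy > 0))
  expect_true(all(diff(tab$rms_discrepancy) < 0))
  expect_error(strong_self_convergence("nsfd", p, g, init, n_levels = 1),
               "n_levels")
})

test_that("deterministic refinement shows the first order of explicit stepping", {
  p <- fig1_params(eta = 0)
  g <- spp_grid(30, 20, 0.1, 40)
  init <- make_initial_state(g, 0.6, 0.4)
  tab <- strong_self_convergence("nsfd", p, g, init, n_levels = 3,
                                 n_paths = 2, seed = 5)
  ratios <- tab$log2_ratio[-1]
  expect_true(all(abs(ratios - 1) < 0.3))
})

test_that("consistency residuals vanish for constant profiles and shrink on refinement", {
  p <- fig1_params()
  const_psi <- list(P = function(x, t) rep(2, length(x)),
                    Q = function(x, t) rep(1, length(x)),
                    Pxx = function(x, t) rep(0, length(x)),
                    Qxx = function(x, t) rep(0, length(x)))
  grids <- list(spp_grid(10, 20, 0.04, 1), spp_grid(10, 28, 0.02, 1),
                spp_grid(10, 40, 0.01, 1))
  for (scheme in c("sfe", "nsfd")) {
    tab <- empirical_consistency(scheme, const_psi, p, grids,
                                 n_samples = 16, seed = 2)
    expect_equal(tab$residual_P, rep(0, 3), tolerance = 1e-28)
    expect_equal(tab$residual_Q, rep(0, 3), tolerance = 1e-28)
  }
  psi <- manufactured_profile(10)
  for (scheme in c("sfe", "nsfd")) {
    tab <- empirical_consistency(scheme, psi, p, grids, n_samples = 32, seed = 3)
    expect_true(all(diff(tab$residual_P) < 0))
    expect_true(all(diff(tab$residual_Q) < 0))
  }
})

test_that("the stochastic residual component vanishes identically without noise", {
  p0 <- fig1_params(eta = 0)
  psi <- manufactured_profile(10)
  tab <- empirical_consistency("sfe", psi, p0, list(spp_grid(10, 20, 0.04, 1)),
                               n_samples = 8, seed = 4)
  expect_identical(tab$stoch_P, 0)
  expect_identical(tab$stoch_Q, 0)
  expect_error(empirical_consistency("sfe",
    list(P = function(x, t) -x, Q = function(x, t) x + 1,
         Pxx = function(x, t) 0 * x, Qxx = function(x, t) 0 * x),
    p0, list(spp_grid(10, 20, 0.04, 1))), "positive")
})
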