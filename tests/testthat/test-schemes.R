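test_that("single scheme steps reproduce hand-computed values on a constant field", {
  p <- fig1_params()
  g <- spp_grid(30, 100, 0.1, 10)   # D1 = D2 = 1/9
  s0 <- make_initial_state(g, 0.6, 0.4)
  expect_length(s0$P, 101)
  expect_true(all(s0$P == 0.6) && all(s0$Q == 0.4))
  expect_error(make_initial_state(g, -0.1, 0.4), "nonnegative")

  s1 <- sfe_step(s0, p, g, 0, 0)
  expect_equal(s1$P, rep(0.5904, 101), tolerance = 1e-12)
  expect_equal(s1$Q, rep(0.39896, 101), tolerance = 1e-12)
  # additive multiplicative-noise term
  s1n <- sfe_step(s0, p, g, 0.1, 0)
  expect_equal(s1n$P, rep(0.5904 + 0.01 * 0.6 * 0.1, 101), tolerance = 1e-12)

  s2 <- nsfd_step(s0, p, g, 0, 0)
  expect_equal(s2$P, rep(0.799333333333333 / 1.348222222222222, 101),
               tolerance = 1e-12)
  expect_equal(s2$Q, rep(0.507848888888889 / 1.272222222222222, 101),
               tolerance = 1e-12)
})

test_that("the all-zero state is a fixed point of both schemes for any noise", {
  p <- fig1_params()
  g <- spp_grid(30, 20, 0.1, 10)
  z <- make_initial_state(g, 0, 0)
  for (dB in c(0, 0.3, -1)) {
    expect_identical(sfe_step(z, p, g, dB, dB)$P, rep(0, 21))
    expect_identical(nsfd_step(z, p, g, dB, dB)$Q, rep(0, 21))
  }
})

test_that("a spatially constant state stays constant under both schemes", {
  p <- fig1_params(eta = 0)
  g <- spp_grid(30, 40, 0.1, 100)
  for (scheme in c("sfe", "nsfd")) {
    sim <- spp_simulate(scheme, p, g, make_initial_state(g, 0.6, 0.4))
    expect_equal(diff(range(sim$final$P)), 0)
    expect_equal(diff(range(sim$final$Q)), 0)
  }
})

test_that("NSFD is unconditionally positive for nonnegative states", {
  # absurdly large time step, constant field
  p <- fig1_params(eta = 0)
  g_big <- spp_grid(30, 20, 10, 1)
  s_big <- nsfd_step(make_initial_state(g_big, 0.6, 0.4), p, g_big, 0, 0)
  expect_true(all(s_big$P >= 0) && all(s_big$Q >= 0))
  # randomized parameters, rough random fields, extreme steps
  set.seed(99)
  for (i in 1:10) {
    p <- random_params()
    p <- spp_params(p$a, p$b, p$c, p$m, p$f, p$d, p$sigma1, p$sigma2, 0, 0)
    dt <- 10^runif(1, -2, 1.5)
    g <- spp_grid(L = runif(1, 1, 50), n = sample(5:60, 1), delta_tau = dt, N = 20)
    init <- make_initial_state(g, runif(g$n + 1, 0, 3), runif(g$n + 1, 0, 3))
    sim <- spp_simulate("nsfd", p, g, init)
    expect_gte(sim$diagnostics$min_value, 0)
    expect_identical(sim$diagnostics$n_negative, 0L)
    expect_false(sim$diagnostics$diverged)
  }
})

test_that("decoupled NSFD prey iteration climbs monotonically to a/b", {
  # with c = f = 0 the prey map is P -> (1 + a dt) P / (1 + b dt P)
  a <- 1.1; b <- 0.7
  p <- spp_params(a, b, 1e-300, 1, 1e-300, 0.5, 0.1, 0.1, 0, 0)
  g <- spp_grid(30, 4, 0.5, 60)
  sim <- spp_simulate("nsfd", p, g, make_initial_state(g, 0.2, 0))
  traj <- sim$probe$P
  expect_true(all(diff(traj) > 0))
  expect_lt(abs(traj[length(traj)] - a / b), 1e-6)
  expect_true(all(traj < a / b + 1e-12))
})

test_that("both schemes converge to the reaction ODE oracle at first order", {
  p0 <- fig1_params()
  p <- spp_params(p0$a, p0$b, p0$c, p0$m, p0$f, p0$d, 1e-300, 1e-300, 0, 0)
  ref <- rk4_reaction(0.6, 0.4, p, T = 2)
  for (scheme in c("sfe", "nsfd")) {
    errs <- vapply(c(0.05, 0.025), function(dt) {
      g <- spp_grid(30, 4, dt, round(2 / dt))
      sim <- spp_simulate(scheme, p, g, make_initial_state(g, 0.6, 0.4))
      max(abs(c(sim$final$P[1], sim$final$Q[1]) - ref))
    }, numeric(1))
    # halving the step roughly halves the error (explicit first order)
    expect_gt(errs[1] / errs[2], 1.5)
    expect_lt(errs[1] / errs[2], 3)
  }
})

test_that("the simulation loop detects divergence and records provenance", {
  sim <- run_preset("fig9_stiff_diffusion", "sfe", seed = 5)
  d <- sim$diagnostics
  expect_true(d$diverged || d$n_negative > 0)
  expect_true(d$diverged)           # blow-up happens within a few dozen steps
  expect_lt(d$divergence_step, 200)
  expect_lt(nrow(sim$probe), sim$grid$N + 1L)

  simn <- run_preset("fig9_stiff_diffusion", "nsfd", seed = 5)
  expect_false(simn$diagnostics$diverged)
  expect_identical(simn$diagnostics$steps_completed, 5000L)
  expect_gte(simn$diagnostics$min_value, 0)
  expect_true(all(is.finite(c(simn$final$P, simn$final$Q))))
})

test_that("grid/noise mismatches are rejected", {
  p <- fig1_params()
  g <- spp_grid(30, 10, 0.1, 100)
  init <- make_initial_state(g, 0.6, 0.4)
  short <- wiener_increments(50, 0.1, seed = 1)
  expect_error(spp_simulate("nsfd", p, g, init, short), "shorter")
  wrong_dt <- wiener_increments(100, 0.2, seed = 1)
  expect_error(spp_simulate("nsfd", p, g, init, wrong_dt), "delta_tau")
  g2 <- spp_grid(30, 20, 0.1, 100)
  expect_error(spp_simulate("nsfd", p, g2, init, wiener_increments(100, 0.1, 1)),
               "does not match")
})
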