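#' Space-time discretization for the finite-difference schemes
#'
#' Grid convention: the interval `[0, L]` is split into `n` intervals of width
#' `h = L/n`, giving `n + 1` nodes at \eqn{x_m = mh}, `m = 0..n` (0-based);
#' time levels are \eqn{t_k = k \Delta\tau}, `k = 0..N`.  The dimensionless
#' diffusion numbers \eqn{D_1 = \Delta\tau\,\sigma_1 / h^2} and
#' \eqn{D_2 = \Delta\tau\,\sigma_2 / h^2} control explicit-scheme stability
#' and are always recomputed from the stored step sizes.
#'
#' @param L Domain length (> 0).
#' @param n Number of spatial intervals (>= 1); there are `n + 1` nodes.
#' @param delta_tau Time step (> 0).
#' @param N Number of time steps (>= 1); final time is `N * delta_tau`.
#' @return An object of class `"spp_grid"`.
#' @examples
#' spp_grid(L = 30, n = 100, delta_tau = 0.1, N = 5000)
#' @export
spp_grid <- function(L, n, delta_tau, N) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0) stop("L must be positive")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer number of intervals")
  if (!is.numeric(delta_tau) || length(delta_tau) != 1L || delta_tau <= 0)
    stop("delta_tau must be strictly positive")
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be a positive integer number of steps")
  structure(list(L = as.numeric(L), n = as.integer(n),
                 h = as.numeric(L) / as.integer(n),
                 delta_tau = as.numeric(delta_tau), N = as.integer(N),
                 T = as.numeric(delta_tau) * as.integer(N)),
            class = "spp_grid")
}

# Diffusion numbers, always derived, never stored.
diffusion_numbers <- function(grid, params) {
  c(D1 = grid$delta_tau * params$sigma1 / grid$h^2,
    D2 = grid$delta_tau * params$sigma2 / grid$h^2)
}

#' @export
print.spp_grid <- function(x, ...) {
  cat(sprintf("Grid: [0, %g] with %d intervals (h = %g), %d steps of %g (T = %g)\n",
              x$L, x$n, x$h, x$N, x$delta_tau, x$T))
  invisible(x)
}

#' Initial field state
#'
#' Builds the step-0 prey/predator profiles on the nodes of `grid`.  Scalars
#' give the spatially constant profiles used in the published experiments
#' (P = 0.6, Q = 0.4 everywhere); full node vectors of length `n + 1` are also
#' accepted for perturbed initial data.
#'
#' @param grid An [spp_grid()] object.
#' @param P0,Q0 Nonnegative initial densities: scalar or vector of length
#'   `grid$n + 1`.
#' @return An object of class `"spp_state"`: list with `step`, `P`, `Q`, `x`.
#' @export
make_initial_state <- function(grid, P0, Q0) {
  stopifnot(inherits(grid, "spp_grid"))
  expand <- function(v, nm) {
    if (!is.numeric(v) || any(!is.finite(v)))
      stop(sprintf("%s must be finite numeric", nm))
    if (any(v < 0)) stop(sprintf("%s must be nonnegative", nm))
    if (length(v) == 1L) rep(as.numeric(v), grid$n + 1L)
    else if (length(v) == grid$n + 1L) as.numeric(v)
    else stop(sprintf("%s must be a scalar or have length n + 1 = %d",
                      nm, grid$n + 1L))
  }
  structure(list(step = 0L, P = expand(P0, "P0"), Q = expand(Q0, "Q0"),
                 x = seq(0, grid$L, length.out = grid$n + 1L)),
            class = "spp_state")
}

# Neighbour sums with homogeneous Neumann boundaries by second-order ghost
# reflection: node -1 |-> node 1, node n+1 |-> node n-1 (R indices: ghost
# left of node 1 is node 2; ghost right of node n+1 is node n).
neumann_neighbour_sum <- function(u) {
  n1 <- length(u)
  left <- c(u[2L], u[seq_len(n1 - 1L)])
  right <- c(u[2:n1], u[n1 - 1L])
  left + right
}

#' One step of the stochastic forward Euler (SFE) scheme
#'
#' Explicit forward-time centred-space update with an Euler-Maruyama noise
#' increment:
#' \deqn{P_m^{k+1} = D_1(P_{m+1}^k + P_{m-1}^k) + (1 - 2D_1)P_m^k
#'   + \Delta\tau P_m^k(a - bP_m^k) - c\Delta\tau \frac{P_m^k Q_m^k}{mQ_m^k + P_m^k}
#'   + \eta_1 P_m^k \Delta B_1,}
#' and analogously for the predator with \eqn{(1 - 2D_2 - d\Delta\tau)} and
#' \eqn{+ f\Delta\tau} ratio term.  Outputs are deliberately NOT clipped to
#' nonnegative values: the scheme's negative/divergent behaviour at large
#' diffusion numbers is part of what the package demonstrates.
#'
#' @param state A `"spp_state"` (see [make_initial_state()]).
#' @param params An [spp_params()] object.
#' @param grid An [spp_grid()] object matching `state`.
#' @param dB1,dB2 The step-k Wiener increments (scalars).
#' @return The step-(k+1) `"spp_state"`.
#' @export
sfe_step <- function(state, params, grid, dB1 = 0, dB2 = 0) {
  D <- diffusion_numbers(grid, params)
  dt <- grid$delta_tau
  P <- state$P; Q <- state$Q
  r <- ratio_term(P, Q, params$m)
  Pn <- D[["D1"]] * neumann_neighbour_sum(P) + (1 - 2 * D[["D1"]]) * P +
    dt * P * (params$a - params$b * P) - params$c * dt * r +
    params$eta1 * P * dB1
  Qn <- D[["D2"]] * neumann_neighbour_sum(Q) + (1 - 2 * D[["D2"]] - params$d * dt) * Q +
    params$f * dt * r + params$eta2 * Q * dB2
  structure(list(step = state$step + 1L, P = Pn, Q = Qn, x = state$x),
            class = "spp_state")
}

#' One step of the stochastic non-standard finite difference (NSFD) scheme
#'
#' Mickens-type positivity-preserving update: every loss term is moved into
#' the denominator, so nonnegative inputs give nonnegative outputs for any
#' step sizes (when the noise increments are zero):
#' \deqn{P_m^{k+1} = \frac{D_1(P_{m+1}^k + P_{m-1}^k) + (1 + a\Delta\tau)P_m^k
#'   + \eta_1 P_m^k \Delta B_1}{1 + 2D_1 + b\Delta\tau P_m^k
#'   + c\Delta\tau \frac{Q_m^k}{mQ_m^k + P_m^k}},}
#' \deqn{Q_m^{k+1} = \frac{D_2(Q_{m+1}^k + Q_{m-1}^k) + Q_m^k
#'   + f\Delta\tau \frac{P_m^k Q_m^k}{mQ_m^k + P_m^k}
#'   + \eta_2 Q_m^k \Delta B_2}{1 + 2D_2 + d\Delta\tau}.}
#' The \eqn{Q_m^k} carry term in the predator numerator is required for
#' consistency (without it a spatially constant field collapses in one step);
#' it matches the scheme's own linearized form used in the stability analysis.
#'
#' @inheritParams sfe_step
#' @return The step-(k+1) `"spp_state"`.
#' @export
nsfd_step <- function(state, params, grid, dB1 = 0, dB2 = 0) {
  D <- diffusion_numbers(grid, params)
  dt <- grid$delta_tau
  P <- state$P; Q <- state$Q
  r <- ratio_term(P, Q, params$m)
  press <- ratio_pressure(P, Q, params$m)
  Pn <- (D[["D1"]] * neumann_neighbour_sum(P) + (1 + params$a * dt) * P +
           params$eta1 * P * dB1) /
    (1 + 2 * D[["D1"]] + params$b * dt * P + params$c * dt * press)
  Qn <- (D[["D2"]] * neumann_neighbour_sum(Q) + Q + params$f * dt * r +
           params$eta2 * Q * dB2) /
    (1 + 2 * D[["D2"]] + params$d * dt)
  structure(list(step = state$step + 1L, P = Pn, Q = Qn, x = state$x),
            class = "spp_state")
}

#' Simulate the stochastic predator-prey reaction-diffusion system
#'
#' Advances an initial field state through `grid$N` time steps with the chosen
#' scheme, consuming one pair of Wiener increments per step (scalar in space).
#' The loop detects divergence (any non-finite value or magnitude beyond
#' `divergence_cap`) and halts early, recording the offending step; it also
#' tracks the minimum value ever observed and the number of strictly negative
#' entries produced, which is how the forward Euler scheme's failure mode is
#' quantified against the NSFD scheme.
#'
#' @param scheme `"sfe"` or `"nsfd"`.
#' @param params An [spp_params()] object.
#' @param grid An [spp_grid()] object.
#' @param init Initial `"spp_state"`; defaults may be built with
#'   [make_initial_state()].
#' @param noise A `"spp_noise"` object with at least `grid$N` increments on
#'   step `grid$delta_tau`, or `NULL` for a noise-free run.
#' @param probe_node 0-based node index whose time series is recorded every
#'   step; defaults to the domain midpoint `floor(n/2)`.
#' @param snapshot_stride Record a full field snapshot every this many steps;
#'   defaults to `max(1, floor(N/50))`.
#' @param divergence_cap Absolute value beyond which the run is declared
#'   divergent (default `1e6`).
#' @return An object of class `"spp_sim"` with components:
#'   `scheme`, `params`, `grid`, `seed`, `noise_mode`, `probe_node`;
#'   `probe` (data.frame `t`, `P`, `Q`, one row per completed step incl. t=0);
#'   `mean_series` (data.frame of spatial means per step);
#'   `snapshots` (array time x node x species) and `snapshot_times`;
#'   `final` (`"spp_state"`); `diagnostics` (list: `min_value`,
#'   `n_negative`, `diverged`, `divergence_step`, `steps_completed`).
#' @examples
#' p <- spp_params(1.1, 0.7, 2.1, 1, 0.79, 0.5, 0.1, 0.1, 0.01, 0.01)
#' g <- spp_grid(30, 100, 0.1, 200)
#' w <- wiener_increments(g$N, g$delta_tau, seed = 1)
#' sim <- spp_simulate("nsfd", p, g, make_initial_state(g, 0.6, 0.4), w)
#' sim
#' @export
spp_simulate <- function(scheme = c("nsfd", "sfe"), params, grid, init,
                         noise = NULL, probe_node = NULL,
                         snapshot_stride = NULL, divergence_cap = 1e6) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "spp_params"), inherits(grid, "spp_grid"),
            inherits(init, "spp_state"))
  n1 <- grid$n + 1L
  if (length(init$P) != n1 || length(init$Q) != n1)
    stop("initial state does not match the grid")
  N <- grid$N
  if (is.null(noise)) {
    dB1 <- dB2 <- numeric(N)
    noise_mode <- "none"; seed <- NA_integer_
  } else {
    stopifnot(inherits(noise, "spp_noise"))
    if (noise$n_steps < N)
      stop("noise path shorter than the number of time steps")
    if (abs(noise$delta_tau - grid$delta_tau) > 1e-12 * grid$delta_tau)
      stop("noise increments were generated for a different delta_tau")
    dB1 <- noise$dB1; dB2 <- noise$dB2
    noise_mode <- noise$mode; seed <- noise$seed
  }
  if (is.null(probe_node)) probe_node <- grid$n %/% 2L
  if (probe_node < 0 || probe_node > grid$n)
    stop("probe_node must lie in [0, n]")
  if (is.null(snapshot_stride)) snapshot_stride <- max(1L, N %/% 50L)
  stepper <- if (scheme == "sfe") sfe_step else nsfd_step

  pi1 <- probe_node + 1L
  probe_P <- numeric(N + 1L); probe_Q <- numeric(N + 1L)
  mean_P <- numeric(N + 1L); mean_Q <- numeric(N + 1L)
  snap_steps <- unique(c(seq(0L, N, by = snapshot_stride), N))
  snaps <- array(NA_real_, dim = c(length(snap_steps), n1, 2L),
                 dimnames = list(NULL, NULL, c("P", "Q")))
  state <- init
  record <- function(k) {
    probe_P[k + 1L] <<- state$P[pi1]; probe_Q[k + 1L] <<- state$Q[pi1]
    mean_P[k + 1L] <<- mean(state$P); mean_Q[k + 1L] <<- mean(state$Q)
    si <- match(k, snap_steps)
    if (!is.na(si)) { snaps[si, , 1L] <<- state$P; snaps[si, , 2L] <<- state$Q }
  }
  record(0L)
  min_value <- min(init$P, init$Q)
  n_negative <- sum(init$P < 0) + sum(init$Q < 0)
  diverged <- FALSE; divergence_step <- NA_integer_
  k_done <- 0L
  for (k in seq_len(N)) {
    state <- stepper(state, params, grid, dB1[k], dB2[k])
    vals <- c(state$P, state$Q)
    bad <- !is.finite(vals)
    if (any(bad) || any(abs(vals[!bad]) > divergence_cap)) {
      diverged <- TRUE; divergence_step <- k
      fin <- vals[is.finite(vals)]
      if (length(fin)) min_value <- min(min_value, fin)
      n_negative <- n_negative + sum(vals < 0, na.rm = TRUE)
      record(k)
      k_done <- k
      break
    }
    min_value <- min(min_value, vals)
    n_negative <- n_negative + sum(vals < 0)
    record(k)
    k_done <- k
  }
  keep <- seq_len(k_done + 1L)
  snap_keep <- which(snap_steps <= k_done)
  if (diverged && !(k_done %in% snap_steps[snap_keep]))
    snap_keep <- c(snap_keep, match(k_done, snap_steps))
  snap_keep <- snap_keep[!is.na(snap_keep)]
  structure(list(
    scheme = scheme, params = params, grid = grid, seed = seed,
    noise_mode = noise_mode, probe_node = as.integer(probe_node),
    snapshot_stride = as.integer(snapshot_stride),
    divergence_cap = divergence_cap,
    probe = data.frame(t = (keep - 1L) * grid$delta_tau,
                       P = probe_P[keep], Q = probe_Q[keep]),
    mean_series = data.frame(t = (keep - 1L) * grid$delta_tau,
                             P = mean_P[keep], Q = mean_Q[keep]),
    snapshots = snaps[snap_keep, , , drop = FALSE],
    snapshot_times = snap_steps[snap_keep] * grid$delta_tau,
    final = state,
    diagnostics = list(min_value = min_value, n_negative = n_negative,
                       diverged = diverged, divergence_step = divergence_step,
                       steps_completed = k_done)),
    class = "spp_sim")
}

#' @export
print.spp_sim <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Stochastic predator-prey simulation (%s scheme)\n", toupper(x$scheme)))
  cat(sprintf("  grid: %d nodes on [0, %g], %d/%d steps of %g completed\n",
              x$grid$n + 1L, x$grid$L, d$steps_completed, x$grid$N, x$grid$delta_tau))
  cat(sprintf("  noise: %s (seed %s)\n", x$noise_mode, format(x$seed)))
  if (d$diverged) {
    cat(sprintf("  DIVERGED at step %d (cap %g)\n", d$divergence_step, x$divergence_cap))
  } else {
    cat(sprintf("  final spatial means: P = %.6g, Q = %.6g\n",
                mean(x$final$P), mean(x$final$Q)))
  }
  cat(sprintf("  min value observed %.4g; negative entries: %d\n",
              d$min_value, d$n_negative))
  invisible(x)
}

#' @export
summary.spp_sim <- function(object, window = 0.1, ...) {
  d <- object$diagnostics
  ms <- object$mean_series
  nw <- max(1L, ceiling(window * nrow(ms)))
  tail_idx <- seq(nrow(ms) - nw + 1L, nrow(ms))
  out <- list(scheme = object$scheme, diverged = d$diverged,
              steps_completed = d$steps_completed,
              min_value = d$min_value, n_negative = d$n_negative,
              window = window,
              windowed_space_mean = c(P = mean(ms$P[tail_idx]),
                                      Q = mean(ms$Q[tail_idx])),
              final_range = rbind(P = range(object$final$P),
                                  Q = range(object$final$Q)))
  class(out) <- "summary.spp_sim"
  out
}

#' @export
print.summary.spp_sim <- function(x, ...) {
  cat(sprintf("%s scheme: %d steps%s\n", toupper(x$scheme), x$steps_completed,
              if (x$diverged) " (diverged)" else ""))
  cat(sprintf("  space-time mean over final %.0f%% of steps: P = %.6g, Q = %.6g\n",
              100 * x$window, x$windowed_space_mean[["P"]],
              x$windowed_space_mean[["Q"]]))
  cat(sprintf("  final P range [%.4g, %.4g]; Q range [%.4g, %.4g]\n",
              x$final_range["P", 1], x$final_range["P", 2],
              x$final_range["Q", 1], x$final_range["Q", 2]))
  cat(sprintf("  min value %.4g, %d negative entries\n", x$min_value, x$n_negative))
  invisible(x)
}

#' Plot a simulation: probe time series and final profiles
#'
#' @param x A `"spp_sim"` object.
#' @param which `"probe"` for the time series at the probe node, `"final"`
#'   for the final spatial profiles, `"both"` (default) for a 1x2 panel.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.spp_sim <- function(x, which = c("both", "probe", "final"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "probe"))
    graphics::matplot(x$probe$t, x$probe[, c("P", "Q")], type = "l",
                      lty = 1, col = c("forestgreen", "firebrick"),
                      xlab = "t", ylab = "density",
                      main = sprintf("%s: node %d", toupper(x$scheme), x$probe_node), ...)
  if (which %in% c("both", "final"))
    graphics::matplot(x$final$x, cbind(x$final$P, x$final$Q), type = "l",
                      lty = 1, col = c("forestgreen", "firebrick"),
                      xlab = "x", ylab = "density",
                      main = sprintf("final profiles (t = %g)",
                                     x$diagnostics$steps_completed * x$grid$delta_tau), ...)
  invisible(x)
}
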