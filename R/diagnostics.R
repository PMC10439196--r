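#' Distance of a simulation's late-time average from a reference point
#'
#' Time-averages the stored field snapshots over the final `window` fraction
#' of the run, node by node, and returns the supremum over nodes of the
#' absolute deviation from the reference density pair, maximised over the two
#' species.  Used to quantify convergence to an equilibrium.
#'
#' @param result A non-divergent `"spp_sim"` object.
#' @param point Length-2 density pair `(P, Q)` to compare against.
#' @param window Fraction of the run (in time) to average over, in `(0, 1]`;
#'   default 0.1.
#' @return Nonnegative scalar distance.
#' @export
steady_state_distance <- function(result, point, window = 0.1) {
  stopifnot(inherits(result, "spp_sim"))
  if (result$diagnostics$diverged)
    stop("result diverged; use positivity_divergence_report() instead")
  if (!is.numeric(point) || length(point) != 2L)
    stop("point must be a density pair (P, Q)")
  if (window <= 0 || window > 1) stop("window must lie in (0, 1]")
  t_end <- max(result$snapshot_times)
  keep <- result$snapshot_times >= t_end - window * t_end
  if (!any(keep)) keep[length(keep)] <- TRUE
  # average over retained snapshot levels, per node
  Pm <- apply(result$snapshots[keep, , 1L, drop = FALSE], 2L, mean)
  Qm <- apply(result$snapshots[keep, , 2L, drop = FALSE], 2L, mean)
  max(max(abs(Pm - point[1L])), max(abs(Qm - point[2L])))
}

#' Positivity and divergence report for a simulation
#'
#' @param result A `"spp_sim"` object.
#' @return A list with `min_value`, `n_negative` (count of strictly negative
#'   entries produced over the whole run), `diverged`, and
#'   `divergence_step` (`NA` when the run completed).
#' @export
positivity_divergence_report <- function(result) {
  stopifnot(inherits(result, "spp_sim"))
  d <- result$diagnostics
  list(min_value = d$min_value, n_negative = d$n_negative,
       diverged = d$diverged, divergence_step = d$divergence_step)
}

#' Oscillation metrics of a probe time series
#'
#' Discards the first 20% of the series as transient, then counts sign
#' changes of `series - reference` and reports the mean absolute excursion
#' (the maximum deviation within each segment between consecutive crossings,
#' averaged over segments).  A constant series yields `(0, 0)`.
#'
#' @param series Numeric probe series (length >= 10).
#' @param reference Scalar reference level (e.g. an equilibrium density).
#' @return List with `crossings` and `amplitude`.
#' @export
oscillation_metrics <- function(series, reference) {
  if (!is.numeric(series) || length(series) < 10)
    stop("series must be numeric with at least 10 points")
  if (!is.numeric(reference) || length(reference) != 1L)
    stop("reference must be a scalar")
  keep <- series[-seq_len(floor(0.2 * length(series)))]
  dev <- keep - reference
  sgn <- sign(dev)
  nz <- sgn != 0
  runs <- sgn[nz]
  cross_idx <- which(diff(runs) != 0)
  crossings <- length(cross_idx)
  if (crossings == 0)
    return(list(crossings = 0L, amplitude = 0))
  # segment boundaries in the index space of the nonzero deviations
  idx <- which(nz)
  bounds <- c(0L, cross_idx, length(runs))
  seg_amp <- vapply(seq_len(length(bounds) - 1L), function(j) {
    seg <- idx[(bounds[j] + 1L):bounds[j + 1L]]
    max(abs(dev[seg]))
  }, numeric(1))
  list(crossings = as.integer(crossings), amplitude = mean(seg_amp))
}

#' Strong self-convergence of a scheme under coupled Brownian refinement
#'
#' Runs the same Brownian paths at successively halved time steps (the fine
#' increments are conditional refinements of the coarse ones, so consecutive
#' levels see the same driving path) and reports the root-mean-square
#' terminal-state discrepancy between each step size and its half, over
#' `n_paths` paths, all nodes, and both species.  For a stable scheme the
#' discrepancies shrink as the step is refined; in the deterministic limit
#' the observed order is the classical first order of explicit stepping.
#'
#' @param scheme `"sfe"` or `"nsfd"`.
#' @param params An [spp_params()] object.
#' @param grid Base-level [spp_grid()]; level `j` uses `delta_tau / 2^j` and
#'   `N * 2^j` steps on the same spatial grid.
#' @param init Initial `"spp_state"` shared by all levels.
#' @param n_levels Number of refinement pairs (>= 2): pair `j` compares steps
#'   `delta_tau/2^(j-1)` and `delta_tau/2^j`.
#' @param n_paths Number of independent Brownian paths (default 8).
#' @param seed Integer master seed.
#' @return An object of class `"spp_convergence"`: data.frame with columns
#'   `delta_tau_coarse`, `delta_tau_fine`, `rms_discrepancy`, and `log2_ratio`
#'   (of consecutive discrepancies; `NA` in the first row).
#' @export
strong_self_convergence <- function(scheme, params, grid, init,
                                    n_levels, n_paths = 8L, seed = 1L) {
  if (!is.numeric(n_levels) || n_levels < 2)
    stop("n_levels must be at least 2")
  n_levels <- as.integer(n_levels)
  sq_sum <- numeric(n_levels)
  n_tot <- 0L
  for (path in seq_len(n_paths)) {
    w <- wiener_increments(grid$N, grid$delta_tau,
                           seed = substream_seed(seed, 100L + path))
    g <- grid
    sim_prev <- spp_simulate(scheme, params, g, init, w)
    for (lev in seq_len(n_levels)) {
      w <- refine_increments(w, 2L, seed = substream_seed(seed, 1000L * path + lev))
      g <- spp_grid(g$L, g$n, g$delta_tau / 2, g$N * 2L)
      sim_fine <- spp_simulate(scheme, params, g, init, w)
      if (sim_prev$diagnostics$diverged || sim_fine$diagnostics$diverged)
        stop("scheme diverged during the refinement study; reduce the step")
      diff2 <- (sim_fine$final$P - sim_prev$final$P)^2 +
        (sim_fine$final$Q - sim_prev$final$Q)^2
      sq_sum[lev] <- sq_sum[lev] + sum(diff2)
      sim_prev <- sim_fine
    }
  }
  n_nodes <- grid$n + 1L
  rms <- sqrt(sq_sum / (n_paths * n_nodes * 2))
  out <- data.frame(delta_tau_coarse = grid$delta_tau / 2^(seq_len(n_levels) - 1L),
                    delta_tau_fine = grid$delta_tau / 2^seq_len(n_levels),
                    rms_discrepancy = rms,
                    log2_ratio = c(NA, log2(rms[-n_levels] / rms[-1L])))
  attr(out, "scheme") <- scheme
  attr(out, "n_paths") <- n_paths
  class(out) <- c("spp_convergence", "data.frame")
  out
}

#' @export
print.spp_convergence <- function(x, ...) {
  cat(sprintf("Strong self-convergence (%s scheme, %d coupled paths)\n",
              toupper(attr(x, "scheme")), attr(x, "n_paths")))
  df <- as.data.frame(x)
  df$rms_discrepancy <- signif(df$rms_discrepancy, 5)
  df$log2_ratio <- signif(df$log2_ratio, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Manufactured smooth profile for consistency checks
#'
#' Returns a strictly positive smooth space-time profile
#' \eqn{\Psi_P = 2 + \cos(\pi x/L)e^{-t}}, \eqn{\Psi_Q = 1 +
#' 0.5\cos(\pi x/L)e^{-t}} together with its exact second space derivatives,
#' in the closure format consumed by [empirical_consistency()].
#'
#' @param L Domain length.
#' @return List of functions `P(x, t)`, `Q(x, t)`, `Pxx(x, t)`, `Qxx(x, t)`.
#' @export
manufactured_profile <- function(L) {
  w <- pi / L
  list(P = function(x, t) 2 + cos(w * x) * exp(-t),
       Q = function(x, t) 1 + 0.5 * cos(w * x) * exp(-t),
       Pxx = function(x, t) -w^2 * cos(w * x) * exp(-t),
       Qxx = function(x, t) -0.5 * w^2 * cos(w * x) * exp(-t))
}

#' Empirical mean-square consistency of a scheme
#'
#' Measures, for a smooth strictly positive manufactured profile
#' \eqn{\Psi = (\Psi_P, \Psi_Q)}, the mean-square gap between the continuous
#' one-step operator of the stochastic PDE (time integrals by composite
#' quadrature over `quad_sub` subintervals per step, the stochastic integral
#' sampled left-endpoint with refinements of the very increments the scheme
#' uses) and the scheme's discrete one-step operator applied to samples of
#' \eqn{\Psi}.  The gap is averaged over `n_samples` noise draws and over a
#' set of interior nodes, at the first time step.  Along a refinement
#' sequence with \eqn{\Delta\tau \propto h^2} the residual must shrink,
#' which is the empirical counterpart of mean-square consistency.
#'
#' @param scheme `"sfe"` or `"nsfd"`.
#' @param psi Profile list with functions `P`, `Q`, `Pxx`, `Qxx` of `(x, t)`
#'   (see [manufactured_profile()]); `P` must be strictly positive on the
#'   domain (the ratio term's intended regime).
#' @param params An [spp_params()] object.
#' @param grids List of [spp_grid()] objects, coarsest first, with
#'   `delta_tau` proportional to `h^2`.
#' @param n_samples Number of noise draws per level (default 64).
#' @param seed Integer seed.
#' @param quad_sub Quadrature subdivisions per time step (default 64).
#' @return An object of class `"spp_consistency"`: data.frame with one row
#'   per level and columns `delta_tau`, `h`, `residual_P`, `residual_Q`
#'   (mean-square residuals) and `stoch_P`, `stoch_Q` (the purely stochastic
#'   parts, exactly zero when the noise strengths are zero).
#' @export
empirical_consistency <- function(scheme = c("sfe", "nsfd"), psi, params, grids,
                                  n_samples = 64L, seed = 1L, quad_sub = 64L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "spp_params"))
  if (!all(vapply(grids, inherits, logical(1), "spp_grid")))
    stop("grids must be a list of spp_grid objects")
  for (fn in c("P", "Q", "Pxx", "Qxx"))
    if (!is.function(psi[[fn]])) stop("psi must supply functions P, Q, Pxx, Qxx")
  rows <- lapply(grids, function(g) {
    consistency_residual_level(scheme, psi, params, g, n_samples, seed, quad_sub)
  })
  out <- do.call(rbind, rows)
  attr(out, "scheme") <- scheme
  class(out) <- c("spp_consistency", "data.frame")
  out
}

consistency_residual_level <- function(scheme, psi, params, g, n_samples,
                                       seed, quad_sub) {
  dt <- g$delta_tau
  h <- g$h
  nodes <- 1:(g$n - 1L)            # interior 0-based indices
  x <- nodes * h
  xl <- (nodes - 1L) * h
  xr <- (nodes + 1L) * h
  t0 <- 0
  # profile samples
  P0 <- psi$P(x, t0); Q0 <- psi$Q(x, t0)
  if (any(P0 <= 0) || any(Q0 <= 0))
    stop("psi must be strictly positive on the domain")
  P1 <- psi$P(x, t0 + dt); Q1 <- psi$Q(x, t0 + dt)
  Pl <- psi$P(xl, t0); Pr <- psi$P(xr, t0)
  Ql <- psi$Q(xl, t0); Qr <- psi$Q(xr, t0)
  # composite-trapezoid quadrature of the drift integrals over [t0, t0+dt]
  tq <- t0 + dt * seq(0, 1, length.out = quad_sub + 1L)
  wq <- dt / quad_sub * c(0.5, rep(1, quad_sub - 1L), 0.5)
  drift_int <- function(f) {
    acc <- 0
    for (j in seq_along(tq)) acc <- acc + wq[j] * f(tq[j])
    acc
  }
  int_Pxx <- drift_int(function(t) psi$Pxx(x, t))
  int_Qxx <- drift_int(function(t) psi$Qxx(x, t))
  int_logis <- drift_int(function(t) { Pt <- psi$P(x, t); Pt * (params$a - params$b * Pt) })
  int_ratio <- drift_int(function(t) ratio_term(psi$P(x, t), psi$Q(x, t), params$m))
  int_dQ <- drift_int(function(t) psi$Q(x, t))
  r0 <- ratio_term(P0, Q0, params$m)
  press0 <- ratio_pressure(P0, Q0, params$m)
  # deterministic parts of L(Psi) - L|_{m,k}(Psi); P1 - P0 cancels between
  # the two operators
  if (scheme == "sfe") {
    detP <- (-params$sigma1 * int_Pxx - int_logis + params$c * int_ratio) -
      (-params$sigma1 * dt * (Pr - 2 * P0 + Pl) / h^2 -
         dt * P0 * (params$a - params$b * P0) + params$c * dt * r0)
    detQ <- (-params$sigma2 * int_Qxx + params$d * int_dQ - params$f * int_ratio) -
      (-params$sigma2 * dt * (Qr - 2 * Q0 + Ql) / h^2 +
         params$d * dt * Q0 - params$f * dt * r0)
  } else {
    # NSFD one-step operator: the centre of the stencil and the loss terms
    # are evaluated at the forward time level
    detP <- (-params$sigma1 * int_Pxx - int_logis + params$c * int_ratio) -
      (-params$sigma1 * dt * (Pr - 2 * P1 + Pl) / h^2 -
         dt * P0 * (params$a - params$b * P1) + params$c * dt * press0 * P1)
    detQ <- (-params$sigma2 * int_Qxx + params$d * int_dQ - params$f * int_ratio) -
      (-params$sigma2 * dt * (Qr - 2 * Q1 + Ql) / h^2 +
         params$d * dt * Q1 - params$f * dt * r0)
  }
  # stochastic part: eta * [ sum_j Psi(t_j) dB_j  -  Psi(t_0) dB ], with the
  # fine increments dB_j refining the scheme's own step increment dB
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 7L))
  sqP <- 0; sqQ <- 0; stP <- 0; stQ <- 0
  for (s in seq_len(n_samples)) {
    dB1 <- stats::rnorm(1, 0, sqrt(dt))
    dB2 <- stats::rnorm(1, 0, sqrt(dt))
    sub1 <- fine_subincrements(dB1, dt, quad_sub)
    sub2 <- fine_subincrements(dB2, dt, quad_sub)
    ito1 <- numeric(length(x)); ito2 <- numeric(length(x))
    for (j in seq_len(quad_sub)) {
      tj <- t0 + (j - 1L) * dt / quad_sub
      ito1 <- ito1 + psi$P(x, tj) * sub1[j]
      ito2 <- ito2 + psi$Q(x, tj) * sub2[j]
    }
    stoP <- params$eta1 * (ito1 - P0 * dB1)  # continuous minus discrete
    stoQ <- params$eta2 * (ito2 - Q0 * dB2)
    resP <- detP + stoP
    resQ <- detQ + stoQ
    sqP <- sqP + mean(resP^2); sqQ <- sqQ + mean(resQ^2)
    stP <- stP + mean(stoP^2); stQ <- stQ + mean(stoQ^2)
  }
  data.frame(delta_tau = dt, h = h,
             residual_P = sqP / n_samples, residual_Q = sqQ / n_samples,
             stoch_P = stP / n_samples, stoch_Q = stQ / n_samples)
}

# Conditional refinement of one increment into quad_sub pieces summing to it.
fine_subincrements <- function(dB, dt, nsub) {
  z <- stats::rnorm(nsub, 0, sqrt(dt / nsub))
  z - (sum(z) - dB) / nsub
}

#' @export
print.spp_consistency <- function(x, ...) {
  cat(sprintf("Empirical mean-square consistency (%s scheme)\n",
              toupper(attr(x, "scheme"))))
  df <- as.data.frame(x)
  for (cl in c("residual_P", "residual_Q", "stoch_P", "stoch_Q"))
    df[[cl]] <- signif(df[[cl]], 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
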