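#' Model parameters for the stochastic ratio-dependent predator-prey system
#'
#' Validates and bundles the coefficients of the reaction-diffusion system
#' \deqn{P_t = \sigma_1 P_{xx} + P(a - bP) - \frac{cPQ}{mQ + P} + \eta_1 P \dot B_1(t),}
#' \deqn{Q_t = \sigma_2 Q_{xx} - dQ + \frac{fPQ}{mQ + P} + \eta_2 Q \dot B_2(t),}
#' where \eqn{P} is the prey density and \eqn{Q} the predator density.
#'
#' @param a Prey intrinsic growth rate (1/time), strictly positive.
#' @param b Prey self-limitation coefficient (1/(density * time)); the prey
#'   carrying capacity is \eqn{a/b}.
#' @param c Capturing rate (1/time).
#' @param m Half capturing saturation constant (dimensionless).
#' @param f Conversion rate of consumed prey into predator growth (1/time).
#'   This is the control parameter for the regime transitions.
#' @param d Predator death rate (1/time).
#' @param sigma1,sigma2 Diffusion coefficients (length^2/time).
#' @param eta1,eta2 Multiplicative noise strengths (1/sqrt(time)); may be zero.
#'
#' @return An object of class `"spp_params"`: a named list of the ten
#'   validated coefficients.
#' @examples
#' p <- spp_params(a = 1.1, b = 0.7, c = 2.1, m = 1, f = 0.79, d = 0.5,
#'                 sigma1 = 0.1, sigma2 = 0.1, eta1 = 0.01, eta2 = 0.01)
#' p
#' @export
spp_params <- function(a, b, c, m, f, d, sigma1, sigma2, eta1 = 0, eta2 = 0) {
  vals <- list(a = a, b = b, c = c, m = m, f = f, d = d,
               sigma1 = sigma1, sigma2 = sigma2, eta1 = eta1, eta2 = eta2)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", nm))
  }
  strict <- c("a", "b", "c", "m", "f", "d", "sigma1", "sigma2")
  for (nm in strict)
    if (vals[[nm]] <= 0)
      stop(sprintf("parameter '%s' must be strictly positive (got %g)", nm, vals[[nm]]))
  for (nm in c("eta1", "eta2"))
    if (vals[[nm]] < 0)
      stop(sprintf("parameter '%s' must be nonnegative (got %g)", nm, vals[[nm]]))
  structure(lapply(vals, as.numeric), class = "spp_params")
}

#' @export
print.spp_params <- function(x, ...) {
  cat("Stochastic ratio-dependent predator-prey model parameters\n")
  cat(sprintf("  growth/limitation : a = %g, b = %g (carrying capacity a/b = %g)\n",
              x$a, x$b, x$a / x$b))
  cat(sprintf("  interaction       : c = %g, m = %g, f = %g\n", x$c, x$m, x$f))
  cat(sprintf("  predator death    : d = %g\n", x$d))
  cat(sprintf("  diffusion         : sigma1 = %g, sigma2 = %g\n", x$sigma1, x$sigma2))
  cat(sprintf("  noise strengths   : eta1 = %g, eta2 = %g\n", x$eta1, x$eta2))
  invisible(x)
}

# Ratio term PQ/(mQ+P), with the exact guard PQ/(mQ+P) := 0 when mQ+P == 0 so
# the origin is an exact fixed point of the drift.  Vectorised over P, Q.
ratio_term <- function(P, Q, m) {
  den <- m * Q + P
  out <- numeric(length(den))
  ok <- den != 0
  out[ok] <- (P[ok] * Q[ok]) / den[ok]
  out
}

# Per-capita predation pressure Q/(mQ+P), same guard (used by the NSFD
# denominator).
ratio_pressure <- function(P, Q, m) {
  den <- m * Q + P
  out <- numeric(length(den))
  ok <- den != 0
  out[ok] <- Q[ok] / den[ok]
  out
}

#' Deterministic reaction (drift) terms of the predator-prey system
#'
#' Evaluates the reaction parts of the two equations at given densities:
#' prey drift \eqn{P(a - bP) - cPQ/(mQ+P)} and predator drift
#' \eqn{-dQ + fPQ/(mQ+P)}.  The ratio term is defined as 0 when
#' \eqn{mQ + P = 0}, so the extinction state (0, 0) is an exact fixed point.
#'
#' @param P,Q Nonnegative finite densities (vectors of equal length are
#'   accepted and evaluated elementwise).
#' @param params An [spp_params()] object.
#' @return A list with components `prey` and `predator` holding the drifts.
#' @examples
#' p <- spp_params(1.1, 0.7, 2.1, 1, 0.79, 0.5, 0.1, 0.1, 0.01, 0.01)
#' reaction_terms(0.6, 0.4, p)   # c(-0.096, -0.0104)
#' @export
reaction_terms <- function(P, Q, params) {
  stopifnot(inherits(params, "spp_params"))
  if (!is.numeric(P) || !is.numeric(Q) || length(P) != length(Q))
    stop("P and Q must be numeric vectors of equal length")
  if (any(!is.finite(P)) || any(!is.finite(Q)))
    stop("densities must be finite")
  if (any(P < 0) || any(Q < 0))
    stop("densities must be nonnegative")
  r <- ratio_term(P, Q, params$m)
  list(prey = P * (params$a - params$b * P) - params$c * r,
       predator = -params$d * Q + params$f * r)
}

#' Equilibria and coexistence stability of the reaction system
#'
#' Computes the predator-free equilibrium \eqn{(a/b, 0)} and, when feasible,
#' the coexistence equilibrium
#' \deqn{P^* = \frac{(am - c)f + cd}{bmf}, \qquad
#'       Q^* = \frac{(f - d)(amf - cf + cd)}{bdm^2 f},}
#' classified by the sign of the criterion
#' \deqn{\Lambda = (c - mf)d^2 - (c - ma - md)f^2:}
#' \eqn{\Lambda > 0} stable, \eqn{\Lambda < 0} unstable (a Hopf-type
#' transition as the conversion rate \eqn{f} crosses the root of
#' \eqn{\Lambda}).  Coexistence is feasible iff \eqn{f > d} and
#' \eqn{(am - c)f + cd > 0}.
#'
#' @param params An [spp_params()] object.
#' @return An object of class `"spp_equilibria"` with fields
#'   `prey_only_point`, `coexistence_point` (or `NULL`),
#'   `coexistence_feasible`, `criterion_value` (`Lambda`, `NA` when
#'   infeasible), and `classification` (one of `"stable"`, `"unstable"`,
#'   `"neutral"`, `"infeasible"`).
#' @examples
#' p <- spp_params(1.1, 0.7, 2.1, 1, 0.79, 0.5, 0.1, 0.1, 0.01, 0.01)
#' spp_equilibria(p)
#' @export
spp_equilibria <- function(params) {
  stopifnot(inherits(params, "spp_params"))
  a <- params$a; b <- params$b; cc <- params$c
  m <- params$m; f <- params$f; d <- params$d
  numer <- (a * m - cc) * f + cc * d
  feasible <- (f > d) && (numer > 0)
  lambda <- (cc - m * f) * d^2 - (cc - m * a - m * d) * f^2
  if (feasible) {
    Pstar <- numer / (b * m * f)
    Qstar <- (f - d) * (a * m * f - cc * f + cc * d) / (b * d * m^2 * f)
    classification <- if (lambda > 0) "stable" else if (lambda < 0) "unstable" else "neutral"
    coex <- c(P = Pstar, Q = Qstar)
  } else {
    classification <- "infeasible"
    coex <- NULL
  }
  structure(list(prey_only_point = c(P = a / b, Q = 0),
                 coexistence_point = coex,
                 coexistence_feasible = feasible,
                 criterion_value = if (feasible) lambda else NA_real_,
                 classification = classification,
                 params = params),
            class = "spp_equilibria")
}

#' @export
print.spp_equilibria <- function(x, ...) {
  cat("Equilibria of the ratio-dependent predator-prey reaction system\n")
  cat(sprintf("  predator-free point : (P, Q) = (%.6g, 0)\n", x$prey_only_point[["P"]]))
  if (x$coexistence_feasible) {
    cat(sprintf("  coexistence point   : (P*, Q*) = (%.6g, %.6g)\n",
                x$coexistence_point[["P"]], x$coexistence_point[["Q"]]))
    cat(sprintf("  criterion Lambda    : %.6g  -> %s\n",
                x$criterion_value, x$classification))
  } else {
    cat("  coexistence point   : infeasible (requires f > d and (am-c)f + cd > 0)\n")
  }
  invisible(x)
}

#' Conversion-rate threshold where the coexistence stability criterion flips
#'
#' Solves \eqn{\Lambda(f) = (c - mf)d^2 - (c - ma - md)f^2 = 0} for the
#' conversion rate \eqn{f} in closed form (a quadratic in \eqn{f}) and returns
#' the root lying inside `interval`, or `NA` when no admissible root exists.
#' This is the Hopf-type transition point separating the stable-coexistence
#' and oscillatory regimes.
#'
#' @param params An [spp_params()] object; its own `f` is ignored.
#' @param interval Numeric length-2 search interval, which must lie within
#'   `(d, Inf)` (coexistence requires `f > d`).
#' @return The threshold conversion rate, or `NA_real_` if no root of the
#'   criterion lies in the interval.
#' @examples
#' p <- spp_params(1.1, 0.7, 2.1, 1, 0.79, 0.5, 0.1, 0.1)
#' hopf_threshold_f(p, c(0.5, 1.5))   # ~ 0.80475
#' @export
hopf_threshold_f <- function(params, interval) {
  stopifnot(inherits(params, "spp_params"))
  if (!is.numeric(interval) || length(interval) != 2L || interval[1] >= interval[2])
    stop("interval must be an increasing numeric pair")
  if (interval[1] < params$d)
    stop("interval must lie within (d, Inf): coexistence requires f > d")
  a <- params$a; cc <- params$c; m <- params$m; d <- params$d
  # Lambda(f) = -(c - ma - md) f^2 - m d^2 f + c d^2  =: A f^2 + B f + C
  A <- -(cc - m * a - m * d)
  B <- -m * d^2
  C <- cc * d^2
  roots <- if (A == 0) {
    if (B == 0) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  roots <- roots[roots > interval[1] & roots < interval[2]]
  if (length(roots) == 0L) return(NA_real_)
  # multiple admissible roots cannot occur for sign-definite quadratics met in
  # practice, but return the smallest for determinism
  min(roots)
}
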