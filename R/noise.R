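# Species substreams are derived from one master seed by fixed offsets so a
# whole run is reproducible from a single integer.
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) + k * 1000003) %% 2147483647)
}

#' Seeded Wiener increments for the two driving processes
#'
#' Draws the per-step Brownian increments
#' \eqn{\Delta B = B^{(k+1)\Delta\tau} - B^{k\Delta\tau} \sim N(0, \Delta\tau)}
#' consumed by the time-stepping schemes.  The noise is scalar in space: one
#' increment per species per time step, applied identically at every node.
#'
#' @param n_steps Number of time steps (>= 1).
#' @param delta_tau Time step (> 0).
#' @param seed Integer master seed; the two species substreams are derived
#'   from it by fixed offsets.
#' @param mode `"independent"` (default) draws separate increments for the two
#'   species; `"shared"` drives both equations with the same Brownian path.
#' @return An object of class `"spp_noise"`: list with `dB1`, `dB2` (length
#'   `n_steps`), `n_steps`, `delta_tau`, `mode`, `seed`.
#' @examples
#' w <- wiener_increments(100, 0.1, seed = 1)
#' var(w$dB1)  # ~ 0.1
#' @export
wiener_increments <- function(n_steps, delta_tau, seed,
                              mode = c("independent", "shared")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("n_steps must be a positive integer")
  if (!is.numeric(delta_tau) || length(delta_tau) != 1L || delta_tau <= 0)
    stop("delta_tau must be strictly positive")
  n_steps <- as.integer(n_steps)
  sd <- sqrt(delta_tau)
  # draw each substream under its own derived seed
  dB1 <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(seed, 1L))
    stats::rnorm(n_steps, 0, sd)
  })
  dB2 <- if (mode == "shared") dB1 else local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(seed, 2L))
    stats::rnorm(n_steps, 0, sd)
  })
  structure(list(dB1 = dB1, dB2 = dB2, n_steps = n_steps,
                 delta_tau = delta_tau, mode = mode, seed = seed),
            class = "spp_noise")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Refine Wiener increments onto a finer time grid (coupled paths)
#'
#' Conditional-Gaussian (Brownian-bridge) refinement: each coarse increment is
#' split into `factor` fine increments whose sum equals the coarse increment
#' exactly, with the correct conditional law
#' \eqn{N(\Delta B / r, \; \delta (I - J/r))} where \eqn{\delta =
#' \Delta\tau / r}.  Used to run the same Brownian path at several step sizes
#' in strong self-convergence studies.
#'
#' @param coarse An [wiener_increments()] object.
#' @param factor Integer refinement factor (>= 2).
#' @param seed Integer seed for the conditional fine-scale randomness.
#' @return A `"spp_noise"` object with `factor * n_steps` increments on step
#'   `delta_tau / factor`, whose consecutive blocks of `factor` sum exactly to
#'   the coarse increments.
#' @export
refine_increments <- function(coarse, factor, seed) {
  stopifnot(inherits(coarse, "spp_noise"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 2 ||
      factor != round(factor))
    stop("factor must be an integer >= 2")
  factor <- as.integer(factor)
  fine_dt <- coarse$delta_tau / factor
  refine_one <- function(dB, sub) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(seed, sub))
    n <- length(dB)
    z <- matrix(stats::rnorm(n * factor, 0, sqrt(fine_dt)), nrow = factor)
    # recentre each block so its sum matches the coarse increment exactly
    adj <- sweep(z, 2L, (colSums(z) - dB) / factor, "-")
    as.numeric(adj)
  }
  dB1 <- refine_one(coarse$dB1, 11L)
  dB2 <- if (coarse$mode == "shared") dB1 else refine_one(coarse$dB2, 12L)
  structure(list(dB1 = dB1, dB2 = dB2,
                 n_steps = coarse$n_steps * factor,
                 delta_tau = fine_dt, mode = coarse$mode, seed = seed),
            class = "spp_noise")
}

#' @export
print.spp_noise <- function(x, ...) {
  cat(sprintf("Wiener increments: %d steps of delta_tau = %g (%s driving noise, seed %s)\n",
              x$n_steps, x$delta_tau, x$mode, format(x$seed)))
  invisible(x)
}
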