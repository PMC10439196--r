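#' Bundled experiment presets
#'
#' The five presets carry the parameter sets of the published numerical
#' experiments, one per regime of the conversion rate `f` (plus the
#' large-diffusion-number demonstration where the forward Euler scheme
#' diverges while the NSFD scheme stays positive and bounded).
#'
#' @return A data.frame with one row per preset: all model coefficients,
#'   grid settings, initial densities, the relative amplitude `perturb` of a
#'   cosine perturbation of the initial field (nonzero only for the
#'   divergence demo, whose point is the response of the spatial modes), and
#'   the expected regime label.
#' @examples
#' spp_presets()
#' @export
spp_presets <- function() {
  base <- list(a = 1.1, b = 0.7, c = 2.1, m = 1, d = 0.5,
               eta1 = 0.01, eta2 = 0.01, P0 = 0.6, Q0 = 0.4, N = 5000L,
               perturb = 0)
  rows <- list(
    fig1_coexistence = c(base, list(sigma1 = 0.1, sigma2 = 0.1, f = 0.79,
                                    L = 30, n = 100L, delta_tau = 0.1,
                                    regime = "coexistence")),
    fig3_oscillation = c(base, list(sigma1 = 1, sigma2 = 1, f = 0.80,
                                    L = 30, n = 100L, delta_tau = 0.1,
                                    regime = "oscillatory")),
    fig5_predator_free = c(base, list(sigma1 = 0.1, sigma2 = 0.1, f = 0.4,
                                      L = 30, n = 100L, delta_tau = 0.01,
                                      regime = "predator_free")),
    fig7_extinction = c(base, list(sigma1 = 0.1, sigma2 = 0.1, f = 0.84,
                                   L = 30, n = 100L, delta_tau = 0.1,
                                   regime = "extinction")))
  fig9 <- c(base, list(sigma1 = 1, sigma2 = 1, f = 0.7,
                       L = 10, n = 60L, delta_tau = 0.1,
                       regime = "sfe_divergence_demo"))
  # the dichotomy demo needs spatial modes excited: a bit-exactly constant
  # field never sees the diffusion stencil, so both schemes would collapse
  # to the same scalar iteration
  fig9$perturb <- 0.01
  rows$fig9_stiff_diffusion <- fig9
  cols <- c("a", "b", "c", "m", "f", "d", "sigma1", "sigma2", "eta1", "eta2",
            "L", "n", "delta_tau", "N", "P0", "Q0", "perturb", "regime")
  df <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    data.frame(preset = nm, as.data.frame(r[cols]), stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

preset_config <- function(name) {
  tab <- spp_presets()
  if (!name %in% tab$preset)
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 name, paste(tab$preset, collapse = ", ")))
  as.list(tab[tab$preset == name, setdiff(names(tab), c("preset", "regime"))])
}

config_param_keys <- c("a", "b", "c", "m", "f", "d",
                       "sigma1", "sigma2", "eta1", "eta2")

#' Read a flat configuration file
#'
#' Configurations are flat key-to-value YAML mappings holding the ten model
#' coefficients (`a, b, c, m, f, d, sigma1, sigma2, eta1, eta2`) plus any of
#' the run keys `scheme, L, n, delta_tau, N, P0, Q0, seed, noise_mode,
#' probe_node, snapshot_stride, divergence_cap`.
#'
#' @param path File path.
#' @return Named list of config values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  # quote bare keys: YAML 1.1 would otherwise read the keys `f` and `n`
  # (conversion rate, interval count) as booleans
  lines <- sub("^([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]*:", "'\\1':", lines)
  cfg <- yaml::yaml.load(paste(lines, collapse = "\n"))
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == ""))
    stop("config must be a flat named mapping")
  missing <- setdiff(config_param_keys, names(cfg))
  if (length(missing))
    stop(sprintf("config is missing model parameters: %s",
                 paste(missing, collapse = ", ")))
  cfg
}

#' Write a flat configuration file
#'
#' @param config Named list of config values.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  txt <- yaml::as.yaml(config)
  # force-quote every top-level key (see read_config)
  txt <- gsub("(^|\n)([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]*:", "\\1'\\2':", txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}

config_to_inputs <- function(cfg) {
  p <- do.call(spp_params, cfg[config_param_keys])
  grid <- spp_grid(L = cfg$L, n = cfg$n, delta_tau = cfg$delta_tau, N = cfg$N)
  eps <- cfg$perturb %||% 0
  x <- seq(0, grid$L, length.out = grid$n + 1L)
  shape <- 1 + eps * cos(pi * x / grid$L)
  init <- make_initial_state(grid, cfg$P0 * shape, cfg$Q0 * shape)
  list(params = p, grid = grid, init = init)
}

#' Run a simulation from a configuration list
#'
#' @param cfg Named list as returned by [read_config()] (model parameters,
#'   grid keys, `P0`, `Q0`, and optionally `scheme`, `seed`, `noise_mode`,
#'   `probe_node`, `snapshot_stride`, `divergence_cap`).
#' @param scheme,seed Override the config's `scheme`/`seed`.
#' @return A `"spp_sim"` object.
#' @export
run_config <- function(cfg, scheme = NULL, seed = NULL) {
  inputs <- config_to_inputs(cfg)
  scheme <- scheme %||% cfg$scheme %||% "nsfd"
  seed <- seed %||% cfg$seed %||% 1L
  mode <- cfg$noise_mode %||% "independent"
  noise <- wiener_increments(inputs$grid$N, inputs$grid$delta_tau,
                             seed = seed, mode = mode)
  spp_simulate(scheme, inputs$params, inputs$grid, inputs$init, noise,
               probe_node = cfg$probe_node,
               snapshot_stride = cfg$snapshot_stride,
               divergence_cap = cfg$divergence_cap %||% 1e6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a bundled preset and persist its outputs
#'
#' Runs [spp_simulate()] with a bundled preset (see [spp_presets()]) and, if
#' `out_dir` is given, writes: `probe.csv` (header `t,P,Q`, 6 significant
#' digits), `snapshots.rds` (array time x node x species, full precision),
#' and `metadata.json` (all config, seed, scheme, noise mode, package
#' version, config hash) — enough to re-create the run exactly with
#' [replay_run()].  A `run.log` records the seed and any divergence event.
#'
#' @param name Preset name, one of
#'   `fig1_coexistence, fig3_oscillation, fig5_predator_free,
#'   fig7_extinction, fig9_stiff_diffusion`.
#' @param scheme `"sfe"` or `"nsfd"`.
#' @param seed Integer seed.
#' @param out_dir Output directory, or `NULL` (default) to skip persistence.
#' @param noise_mode `"independent"` or `"shared"`.
#' @return A `"spp_sim"` object (invisibly when persisting).
#' @export
run_preset <- function(name, scheme = c("nsfd", "sfe"), seed = 1L,
                       out_dir = NULL, noise_mode = "independent") {
  scheme <- match.arg(scheme)
  cfg <- preset_config(name)
  cfg$scheme <- scheme
  cfg$seed <- seed
  cfg$noise_mode <- noise_mode
  sim <- run_config(cfg)
  if (is.null(out_dir)) return(sim)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  persist_run(sim, cfg, out_dir, preset = name)
  invisible(sim)
}

persist_run <- function(sim, cfg, out_dir, preset = NULL) {
  probe_path <- file.path(out_dir, "probe.csv")
  probe <- sim$probe
  probe[] <- lapply(probe, function(v) signif(v, 6))
  utils::write.csv(probe, probe_path, row.names = FALSE, quote = FALSE)
  saveRDS(list(snapshots = sim$snapshots, times = sim$snapshot_times),
          file.path(out_dir, "snapshots.rds"))
  cfg_file <- tempfile(fileext = ".yml")
  write_config(cfg, cfg_file)
  meta <- list(package = "stochpredprey",
               version = as.character(utils::packageVersion("stochpredprey")),
               preset = preset, config = cfg,
               config_md5 = unname(tools::md5sum(cfg_file)))
  unlink(cfg_file)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  d <- sim$diagnostics
  log_lines <- c(
    sprintf("scheme=%s seed=%s noise_mode=%s", sim$scheme, format(sim$seed),
            sim$noise_mode),
    sprintf("steps_completed=%d of %d", d$steps_completed, sim$grid$N),
    if (d$diverged) sprintf("DIVERGENCE at step %d", d$divergence_step)
    else "completed without divergence",
    sprintf("min_value=%g n_negative=%d", d$min_value, d$n_negative))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Re-create a persisted run from its metadata record
#'
#' @param metadata_path Path to a `metadata.json` written by [run_preset()].
#' @return The re-created `"spp_sim"` object (identical to the original).
#' @export
replay_run <- function(metadata_path) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  run_config(as.list(meta$config))
}
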