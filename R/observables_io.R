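#' Atomic time unit in femtoseconds
#' @export
AU_TO_FS <- 0.02418884254

#' Aggregate trajectory records into ensemble observables
#'
#' Computes both electronic-population measures on the shared time grid:
#' the fraction of trajectories on each surface, `Pi_k(t)` (the quantity
#' conventionally reported as the population), and the ensemble mean of
#' the electronic populations, `rho_kk(t)`, which is retained alongside
#' it for the internal-consistency diagnostic.  Aggregation is
#' order-independent over the record list.
#'
#' @param records list of `trajectory_record` objects sharing one time
#'   grid.
#' @return an `ensemble_result` (see [run_ensemble()]).
#' @export
aggregate_records <- function(records) {
  stopifnot(length(records) >= 1)
  t0 <- records[[1]]$record$t
  for (r in records) {
    if (length(r$record$t) != length(t0) || any(r$record$t != t0))
      stop("records do not share a common time grid")
  }
  nsnap <- length(t0); n <- length(records)
  Pi <- matrix(0, nsnap, 2); rho <- matrix(0, nsnap, 2); ind <- numeric(nsnap)
  n_acc <- 0L; n_fru <- 0L
  seg <- numeric(n); jump <- numeric(n); nrm <- numeric(n)
  counts <- integer(n)
  for (i in seq_along(records)) {
    r <- records[[i]]$record
    Pi[cbind(seq_len(nsnap), r$active)] <- Pi[cbind(seq_len(nsnap), r$active)] + 1
    rho[, 1] <- rho[, 1] + r$pop1; rho[, 2] <- rho[, 2] + r$pop2
    ind <- ind + r$pop1 * r$pop2
    d <- records[[i]]$diagnostics
    n_acc <- n_acc + d$n_accepted; n_fru <- n_fru + d$n_frustrated
    seg[i] <- d$max_seg_drift; jump[i] <- d$max_hop_jump; nrm[i] <- d$max_norm_dev
    counts[i] <- d$n_accepted
  }
  out <- list(t = t0, Pi = Pi / n, rho = rho / n, indicator = ind / n,
              n_traj = n, n_states = 2L,
              hops = list(accepted = n_acc, frustrated = n_fru,
                          mean_accepted_per_traj = n_acc / n, counts = counts),
              drift = list(seg = seg, hop_jump = jump, norm = nrm),
              config = records[[1]]$config,
              model_label = records[[1]]$model_label)
  class(out) <- "ensemble_result"
  out
}

#' Internal-consistency error of a surface-hopping ensemble
#'
#' The fewest-switches prescription is built on the requirement that the
#' ensemble fraction of trajectories per state match the ensemble-averaged
#' electronic population; running the hopping algorithm stochastically on
#' independent trajectories breaks this.  The error is `|Pi_k - rho_kk|`
#' per time and state, and its maximum.
#'
#' @param result an `ensemble_result`.
#' @return list with `series` (time x states matrix) and scalar `max`.
#' @export
internal_consistency_error <- function(result) {
  err <- abs(result$Pi - result$rho)
  list(series = err, max = max(err))
}

#' Ensemble decoherence indicator
#'
#' The mean over trajectories of the pairwise coherence
#' `rho_nn rho_kk` (summed over state pairs for more than two states);
#' bounded by 0.25 per pair, and zero for a fully decohered ensemble.
#'
#' @param x an `ensemble_result` (uses the accumulated indicator) or a
#'   list of `trajectory_record`s.
#' @return numeric vector `indicator(t)`.
#' @export
decoherence_indicator <- function(x) {
  if (inherits(x, "ensemble_result")) return(x$indicator)
  agg <- aggregate_records(x)
  agg$indicator
}

#' Monte-Carlo standard error of a trajectory-fraction population
#'
#' Binomial formula `sqrt(p (1 - p) / n)`.
#'
#' @param p fraction.
#' @param n number of trajectories.
#' @return standard error.
#' @export
binomial_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)

#' Time-step / ensemble-size convergence harness
#'
#' Repeats an ensemble run over a ladder of nuclear time steps (and
#' optionally ensemble sizes) and tabulates the final-time population
#' `Pi_1(t_final)` with its Monte-Carlo standard error.  A dt pair is
#' flagged when its results differ by more than `z` combined standard
#' errors; any flagged pair marks the run non-converged with respect to
#' the time step.  Very localized crossings fail this check unless dt
#' resolves the interaction region.
#'
#' @param model a built-in `surfhop_model`.
#' @param ics_fun function `(n, seed) -> list(R, P)` generating initial
#'   conditions.
#' @param config an [sh_config()]; its `dt` and `n_steps` are overridden
#'   per run so that the total time `dt * n_steps` is preserved.
#' @param dt_list decreasing vector of nuclear time steps (a.u.), length
#'   >= 2.
#' @param n_list ensemble sizes (recycled against `dt_list` runs).
#' @param active,C0 initial electronic condition, as in [run_ensemble()].
#' @param z flag threshold in combined standard errors.
#' @return list with data frame `table` (`dt`, `n`, `Pi1`, `se`), logical
#'   `converged`, and `flagged_pairs`.
#' @export
convergence_harness <- function(model, ics_fun, config, dt_list,
                                n_list = NULL, active = 1L, C0 = NULL, z = 3) {
  stopifnot(length(dt_list) >= 2)
  if (is.null(n_list)) n_list <- rep(1000L, length(dt_list))
  if (length(n_list) == 1L) n_list <- rep(n_list, length(dt_list))
  t_total <- config$dt * config$n_steps
  rows <- list()
  for (i in seq_along(dt_list)) {
    cfg <- config
    cfg$dt <- dt_list[i]
    cfg$n_steps <- as.integer(round(t_total / dt_list[i]))
    cfg$record_every <- max(1L, cfg$n_steps %/% 200L)
    n <- n_list[i]
    ens <- run_ensemble(model, ics_fun(n, config$seed), cfg,
                        active = active, C0 = C0)
    p1 <- final_populations(ens)[1]
    rows[[i]] <- data.frame(dt = dt_list[i], n = n, Pi1 = p1,
                            se = binomial_se(p1, n))
  }
  tab <- do.call(rbind, rows)
  flagged <- list()
  for (i in seq_len(nrow(tab) - 1)) {
    comb <- sqrt(tab$se[i]^2 + tab$se[i + 1]^2)
    if (abs(tab$Pi1[i] - tab$Pi1[i + 1]) > z * comb)
      flagged[[length(flagged) + 1]] <- c(tab$dt[i], tab$dt[i + 1])
  }
  list(table = tab, converged = length(flagged) == 0, flagged_pairs = flagged)
}

# ---------------------------------------------------------------------------
# config parsing and result persistence
# ---------------------------------------------------------------------------

.config_schema <- list(
  model = c("name"),
  initial = c("n_traj", "x0", "k0", "sigma_x", "state"),
  dynamics = c("dt", "n_steps")
)

#' Read and validate a run configuration
#'
#' YAML key-value file with blocks `model` (name, optional params),
#' `initial` (n_traj, x0, k0, sigma_x, state, optional momenta), `dynamics`
#' (dt, n_steps, optional n_substeps, rescale, frustrated, exit_x,
#' record_every), `decoherence` (scheme, optional sigma, spawn_threshold,
#' alpha), and `seed`.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config list (class `surfhop_config`).
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  for (blk in names(.config_schema)) {
    if (is.null(cfg[[blk]]))
      stop(sprintf("config error at '%s': required block missing", blk))
    for (key in .config_schema[[blk]]) {
      if (is.null(cfg[[blk]][[key]]))
        stop(sprintf("config error at '%s.%s': required key missing", blk, key))
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$decoherence)) cfg$decoherence <- list(scheme = "none")
  class(cfg) <- "surfhop_config"
  cfg
}

#' Write a run configuration
#'
#' @param cfg config list.
#' @param path YAML file path.
#' @return the path, invisibly.
#' @export
write_config <- function(cfg, path) {
  cc <- unclass(cfg)
  yaml::write_yaml(cc, path)
  invisible(path)
}

#' Execute a configured ensemble run
#'
#' @param cfg a config list or YAML path (see [read_config()]).
#' @return an `ensemble_result`, with the full config echoed in
#'   `$run_config` and the derived settings in `$config`.
#' @export
run_from_config <- function(cfg) {
  if (is.character(cfg) || !inherits(cfg, "surfhop_config")) cfg <- read_config(cfg)
  model <- get_model(cfg$model$name, params = cfg$model$params)
  ini <- cfg$initial
  ics <- scattering_initial_conditions(
    n = ini$n_traj, x0 = ini$x0, k0 = ini$k0, sigma_x = ini$sigma_x,
    mass = model$masses[1], seed = cfg$seed,
    momenta = if (is.null(ini$momenta)) "sampled" else ini$momenta)
  dyn <- cfg$dynamics
  dec <- cfg$decoherence
  sigma <- dec$sigma
  if (identical(dec$scheme, "shxf") && is.null(sigma)) sigma <- ics$sigma
  shc <- sh_config(
    dt = dyn$dt, n_steps = dyn$n_steps,
    n_substeps = if (is.null(dyn$n_substeps)) 20L else dyn$n_substeps,
    rescale = if (is.null(dyn$rescale)) "iso" else dyn$rescale,
    frustrated = if (is.null(dyn$frustrated)) "keep" else dyn$frustrated,
    decoherence = dec$scheme, sigma = sigma,
    spawn_threshold = if (is.null(dec$spawn_threshold)) 1e-4 else dec$spawn_threshold,
    alpha = if (is.null(dec$alpha)) 0.1 else dec$alpha,
    seed = cfg$seed,
    record_every = if (is.null(dyn$record_every)) 1L else dyn$record_every,
    exit_x = if (is.null(dyn$exit_x)) Inf else dyn$exit_x)
  res <- run_ensemble(model, ics, shc, active = ini$state)
  res$run_config <- cfg
  res
}

#' Write ensemble results to disk
#'
#' Produces `summary.csv` (columns `t_au`, `t_fs`, `Pi_k...`,
#' `rho_kk...`, `indicator`), `metadata.json` (full config echo, seeds,
#' scheme parameters, hop and frustrated-hop counts, energy-drift and
#' norm-drift quantiles, package version), and `hops.csv` when hop-level
#' data are present.
#'
#' @param result an `ensemble_result`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  k <- result$n_states
  df <- data.frame(t_au = result$t, t_fs = result$t * AU_TO_FS)
  for (j in seq_len(k)) df[[paste0("Pi_", j)]] <- result$Pi[, j]
  for (j in seq_len(k)) df[[paste0("rho_", j, j)]] <- result$rho[, j]
  df$indicator <- result$indicator
  utils::write.csv(df, file.path(dir, "summary.csv"), row.names = FALSE)
  qs <- function(v) if (length(v)) as.list(stats::quantile(v, c(0.5, 0.9, 1))) else NULL
  meta <- list(
    model = result$model_label,
    n_traj = result$n_traj,
    config = unclass(result$config),
    run_config = if (!is.null(result$run_config)) unclass(result$run_config) else NULL,
    afssh_reset_rate = "1/tau_r = -(dF.dR)/2 (moment-contraction companion of the collapse rate)",
    hops = result$hops[c("accepted", "frustrated", "mean_accepted_per_traj")],
    energy_drift_quantiles = qs(result$drift$seg),
    hop_energy_jump_quantiles = qs(result$drift$hop_jump),
    norm_drift_quantiles = qs(result$drift$norm),
    package_version = as.character(utils::packageVersion("surfhop")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Compare an ensemble run with the exact wavepacket oracle
#'
#' @param result an `ensemble_result` from a scattering run.
#' @param oracle output of [run_oracle()] for matching initial conditions.
#' @return list with `Pi_final`, `exact_final`, and `abs_error` per state.
#' @export
compare_with_oracle <- function(result, oracle) {
  pf <- final_populations(result)
  ef <- oracle$P[nrow(oracle$P), ]
  list(Pi_final = pf, exact_final = ef, abs_error = abs(pf - ef))
}
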