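#' Surface-hopping run configuration
#'
#' @param dt nuclear time step (a.u.), > 0.
#' @param n_steps number of nuclear steps.
#' @param n_substeps electronic RK4 substeps per nuclear step (>= 1);
#'   energies and couplings are linearly interpolated across the step.
#' @param rescale velocity adjustment after an accepted hop: `"iso"`
#'   (uniform scaling), `"nacv"` (along the nonadiabatic coupling vector),
#'   or `"nacv+iso"` (NACV first, isotropic fallback when frustrated).
#' @param frustrated policy at energy-forbidden hops: `"keep"` the
#'   momentum or `"reverse"` it.
#' @param decoherence `"none"`, `"shxf"`, `"edc"`, or `"afssh"`.
#' @param sigma SHXF Gaussian width (bohr); required for `"shxf"`.
#' @param spawn_threshold SHXF auxiliary-trajectory spawn threshold on the
#'   nonactive population.
#' @param alpha SHEDC energy constant (Hartree); conventional value 0.1.
#' @param seed base RNG seed; each trajectory derives an independent
#'   counter-based stream from it.
#' @param record_every store every k-th nuclear step in the record.
#' @param exit_x optional |x| beyond which an outward-moving trajectory is
#'   frozen (free flight, electronic state held); `Inf` disables.
#' @return object of class `sh_config`.
#' @export
sh_config <- function(dt = 0.4, n_steps = 1000L, n_substeps = 20L,
                      rescale = c("iso", "nacv", "nacv+iso"),
                      frustrated = c("keep", "reverse"),
                      decoherence = c("none", "shxf", "edc", "afssh"),
                      sigma = NULL, spawn_threshold = 0.01, alpha = 0.1,
                      seed = 1L, record_every = 1L, exit_x = Inf) {
  rescale <- match.arg(rescale)
  frustrated <- match.arg(frustrated)
  decoherence <- match.arg(decoherence)
  if (dt <= 0) stop("dt must be positive")
  if (n_substeps < 1) stop("n_substeps must be >= 1")
  if (decoherence == "shxf") {
    if (is.null(sigma)) stop("decoherence = 'shxf' requires sigma")
    if (sigma <= 0) stop("sigma must be positive")
    if (spawn_threshold <= 0 || spawn_threshold >= 1)
      stop("spawn_threshold must be in (0, 1)")
  }
  if (alpha < 0) stop("alpha must be >= 0")
  cfg <- list(dt = dt, n_steps = as.integer(n_steps),
              n_substeps = as.integer(n_substeps), rescale = rescale,
              frustrated = frustrated, decoherence = decoherence,
              sigma = if (is.null(sigma)) NA_real_ else sigma,
              spawn_threshold = spawn_threshold, alpha = alpha,
              seed = as.integer(seed), record_every = as.integer(record_every),
              exit_x = exit_x)
  class(cfg) <- "sh_config"
  cfg
}

#' Trajectory state
#'
#' @param R positions (bohr).
#' @param V velocities (bohr / a.u. time).
#' @param active active-state index (1-based).
#' @param C complex BO coefficient vector, norm 1.
#' @param t time (a.u.).
#' @return object of class `trajectory_state`.
#' @export
trajectory_state <- function(R, V, active = 1L, C = NULL, t = 0) {
  if (is.null(C)) {
    C <- rep(0 + 0i, max(2L, active))
    C[active] <- 1 + 0i
  }
  nrm <- sum(Mod(C)^2)
  if (abs(nrm - 1) > 1e-6) stop("electronic coefficients must have unit norm")
  st <- list(R = as.numeric(R), V = as.numeric(V), active = as.integer(active),
             C = as.complex(C), t = t, adiab = NULL)
  class(st) <- "trajectory_state"
  st
}

#' One velocity-Verlet nuclear step on the active surface
#'
#' @param state a [trajectory_state()]; its `adiab` cache is refreshed with
#'   eigenvector phase continuity.
#' @param model a `surfhop_model`.
#' @param dt time step (a.u.).
#' @return the advanced `trajectory_state`.
#' @export
nuclear_step <- function(state, model, dt) {
  ad <- state$adiab
  if (is.null(ad)) ad <- adiabatic_point(model, state$R)
  a <- state$active
  acc_old <- -ad$gradients[a, ] / model$masses
  R_new <- state$R + state$V * dt + 0.5 * acc_old * dt^2
  ad_new <- adiabatic_point(model, R_new, prev = ad)
  acc_new <- -ad_new$gradients[a, ] / model$masses
  state$R <- R_new
  state$V <- state$V + 0.5 * (acc_old + acc_new) * dt
  state$t <- state$t + dt
  state$adiab <- ad_new
  state
}

#' Coupled-coefficient electronic propagation over one nuclear step
#'
#' Integrates `i dC_n/dt = eps_n C_n - i sum_k (v . d_nk) C_k + i xi_n`
#' with a fixed-substep RK4 scheme; energies and velocity-coupling
#' products are interpolated linearly between the step endpoints.  With
#' `xi_fun = NULL` the propagation is norm-conserving to machine-level
#' accuracy per step.
#'
#' @param C complex coefficient vector at step start.
#' @param eps_start,eps_end adiabatic energies at the step endpoints.
#' @param vd_start,vd_end matrices of `sum_nu V_nu d_nk,nu` at the step
#'   endpoints (antisymmetric).
#' @param dt nuclear step (a.u.).
#' @param n_substeps RK4 substeps.
#' @param xi_fun optional function `(C, tau) -> complex vector` added to
#'   `dC/dt` (the decoherence contribution), with `tau` the fractional
#'   position inside the step.
#' @return the propagated coefficient vector.
#' @export
electronic_step <- function(C, eps_start, eps_end, vd_start, vd_end, dt,
                            n_substeps = 20L, xi_fun = NULL) {
  ns <- length(C)
  deriv <- function(Cv, tau) {
    eps <- eps_start + tau * (eps_end - eps_start)
    vd <- vd_start + tau * (vd_end - vd_start)
    d <- -1i * eps * Cv - vd %*% Cv
    if (!is.null(xi_fun)) d <- d + xi_fun(Cv, tau)
    d
  }
  h <- dt / n_substeps
  for (j in seq_len(n_substeps) - 1L) {
    t0 <- j / n_substeps; tm <- (j + 0.5) / n_substeps; t1 <- (j + 1) / n_substeps
    k1 <- deriv(C, t0)
    k2 <- deriv(C + 0.5 * h * k1, tm)
    k3 <- deriv(C + 0.5 * h * k2, tm)
    k4 <- deriv(C + h * k3, t1)
    C <- C + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  nrm <- sum(Mod(C)^2)
  if (is.null(xi_fun) && abs(nrm - 1) > 1e-6)
    stop("electronic norm drift exceeds 1e-6: integration unstable, reduce dt")
  as.complex(C)
}

#' Fewest-switches hopping probabilities
#'
#' Evaluates the fewest-switches expression
#' `zeta_ak = max(0, 2 dt (V . d_ak) Re(C_a* C_k) / |C_a|^2)` for every
#' state k other than the active state a.  Negative raw values are clamped
#' to zero.
#'
#' @param state a [trajectory_state()] with a populated `adiab` cache.
#' @param dt nuclear step (a.u.).
#' @return numeric vector of length `n_states`: hopping probability per
#'   target state (0 at the active position).
#' @export
hop_probability <- function(state, dt) {
  a <- state$active
  C <- state$C
  ad <- state$adiab
  ns <- length(C)
  rho_aa <- Mod(C[a])^2
  zeta <- numeric(ns)
  if (rho_aa < 1e-12) {
    warning("active population below 1e-12; hopping probabilities set to 0")
    return(zeta)
  }
  for (k in seq_len(ns)) {
    if (k == a) next
    vd_ak <- sum(state$V * ad$nacv[a, k, ])
    zeta[k] <- max(0, 2 * dt * vd_ak * Re(Conj(C[a]) * C[k]) / rho_aa)
  }
  zeta
}

#' Cumulative-window hop selection
#'
#' A hop from the active state to the n-th listed target is made if
#' `sum_{k<n} zeta_k < r <= sum_{k<=n} zeta_k`, with targets ordered by
#' ascending state index.
#'
#' @param zeta nonnegative probabilities per target state (sum <= 1).
#' @param r uniform random number in \[0, 1\].
#' @return index into `zeta` of the selected target, or `NA_integer_` for
#'   no hop.
#' @export
attempt_hop <- function(zeta, r) {
  stopifnot(all(zeta >= 0), sum(zeta) <= 1 + 1e-12)
  cz <- cumsum(zeta)
  hit <- which(r <= cz & r > c(0, utils::head(cz, -1)))
  if (length(hit) == 0) return(NA_integer_)
  hit[1]
}

#' Isotropic velocity rescaling after a hop
#'
#' Every velocity is scaled uniformly by `kappa = sqrt(1 - deps/KE)` so
#' that total energy is conserved; if the potential-energy gain exceeds
#' the kinetic energy the hop is frustrated and `V` is returned untouched.
#'
#' @param V velocities.
#' @param masses per-DOF masses.
#' @param deps potential-energy change `eps_target - eps_current` (Hartree).
#' @return list with `V` and logical `accepted`.
#' @export
rescale_isotropic <- function(V, masses, deps) {
  KE <- 0.5 * sum(masses * V^2)
  if (KE == 0) {
    if (deps < 0) {
      warning("zero kinetic energy: downhill rescaling direction undefined; hop rejected")
      return(list(V = V, accepted = FALSE))
    }
    return(list(V = V, accepted = deps == 0))
  }
  if (KE < deps) return(list(V = V, accepted = FALSE))
  list(V = sqrt(1 - deps / KE) * V, accepted = TRUE)
}

#' Velocity rescaling along the nonadiabatic coupling vector
#'
#' Solves `(sum_nu d^2/(2 M)) gamma^2 + (sum_nu V d) gamma + deps = 0` and
#' applies `V_nu -> V_nu + gamma d_nu / M_nu` with the real root of
#' smaller magnitude; no real root means the hop is frustrated.
#'
#' @param V velocities.
#' @param masses per-DOF masses.
#' @param d NACV between the two states (per DOF).
#' @param deps potential-energy change (Hartree).
#' @return list with `V`, logical `accepted`, and `reason`
#'   (`"ok"`, `"energy"`, or `"zero_nacv"`).
#' @export
rescale_nacv <- function(V, masses, d, deps) {
  if (all(d == 0)) {
    return(list(V = V, accepted = FALSE, reason = "zero_nacv"))
  }
  a <- sum(d^2 / (2 * masses))
  b <- sum(V * d)
  disc <- b^2 - 4 * a * deps
  if (disc < 0) return(list(V = V, accepted = FALSE, reason = "energy"))
  g1 <- (-b + sqrt(disc)) / (2 * a)
  g2 <- (-b - sqrt(disc)) / (2 * a)
  gam <- if (abs(g1) <= abs(g2)) g1 else g2
  list(V = V + gam * d / masses, accepted = TRUE, reason = "ok")
}

#' Dispatch velocity rescaling by mode
#'
#' `"nacv+iso"` first tries NACV rescaling and falls back to isotropic
#' scaling when the NACV hop is frustrated; the branch that fired is
#' reported for the hop log.
#'
#' @param mode `"iso"`, `"nacv"`, or `"nacv+iso"`.
#' @param V,masses,d,deps as in [rescale_nacv()].
#' @return list with `V`, `accepted`, `branch`.
#' @export
rescale_dispatch <- function(mode = c("iso", "nacv", "nacv+iso"),
                             V, masses, d = NULL, deps = 0) {
  mode <- match.arg(mode)
  if (mode == "iso") {
    r <- rescale_isotropic(V, masses, deps)
    return(list(V = r$V, accepted = r$accepted,
                branch = if (r$accepted) "iso" else "frustrated"))
  }
  r <- rescale_nacv(V, masses, d, deps)
  if (r$accepted) return(list(V = r$V, accepted = TRUE, branch = "nacv"))
  if (mode == "nacv") {
    return(list(V = V, accepted = FALSE,
                branch = paste0("frustrated_", r$reason)))
  }
  ri <- rescale_isotropic(V, masses, deps)
  list(V = ri$V, accepted = ri$accepted,
       branch = if (ri$accepted) "iso_fallback" else "frustrated")
}

.scheme_code <- c(none = 0L, shxf = 1L, edc = 2L, afssh = 3L)
.rescale_code <- c(iso = 0L, nacv = 1L, `nacv+iso` = 2L)
.frustrated_code <- c(keep = 0L, reverse = 1L)

.check_engine_model <- function(model) {
  if (is.na(model$engine_id) || model$n_states != 2L || model$n_dof != 1L)
    stop("the trajectory engine supports the built-in two-state 1D models; ",
         "use the step-level operations for other systems")
}

#' Propagate a single surface-hopping trajectory
#'
#' Full loop per nuclear step: velocity-Verlet nuclear step, electronic
#' RK4 substeps (with the configured decoherence plugin), fewest-switches
#' hop test, velocity rescaling on accepted hops, frustrated-hop policy on
#' rejected ones.  Deterministic for a fixed `(seed, traj_id)` pair.
#'
#' @param model a built-in `surfhop_model` (two states, one DOF).
#' @param state0 a [trajectory_state()].
#' @param config an [sh_config()].
#' @param traj_id trajectory index, keying the per-trajectory RNG stream.
#' @param collect_full also record complex coefficients, the quantum
#'   momentum, per-step hop probabilities, and every RNG draw (replay).
#' @return object of class `trajectory_record`: data frame `record`
#'   (time series of R, V, active, populations, energies, total energy),
#'   data frame `hops` (time, from, to, accepted, rescale branch, draw),
#'   `diagnostics` (norm drift, energy drift, counters), `final` state.
#' @export
run_trajectory <- function(model, state0, config, traj_id = 1L,
                           collect_full = FALSE) {
  .check_engine_model(model)
  stopifnot(inherits(state0, "trajectory_state"), inherits(config, "sh_config"))
  res <- .propagate_cpp(model$engine_id, model$engine_params, model$masses,
                        state0$R[1], state0$V[1], state0$active - 1L,
                        state0$C, config$dt, config$n_steps,
                        config$n_substeps, config$record_every,
                        .scheme_code[[config$decoherence]],
                        if (is.na(config$sigma)) 1 else config$sigma,
                        config$spawn_threshold, config$alpha,
                        .rescale_code[[config$rescale]],
                        .frustrated_code[[config$frustrated]],
                        config$seed, traj_id, config$exit_x, collect_full)
  rec <- res$record
  df <- data.frame(t = rec$t, R = rec$x, V = rec$v, active = rec$active,
                   pop1 = rec$pop[, 1], pop2 = rec$pop[, 2],
                   eps1 = rec$energies[, 1], eps2 = rec$energies[, 2],
                   etot = rec$etot)
  hops <- as.data.frame(res$hops)
  out <- list(record = df, hops = hops, diagnostics = res$diagnostics,
              final = res$final, traj_id = traj_id, config = config,
              model_label = model$label)
  if (collect_full) {
    out$C_record <- res$C_record
    out$Q_record <- res$Q_record
    out$zeta_record <- res$zeta_record
    out$debug1 <- res$debug1
    out$debug2 <- res$debug2
    out$draws <- res$draws
  }
  class(out) <- "trajectory_record"
  out
}

#' Propagate a surface-hopping ensemble
#'
#' Runs one trajectory per row of the initial-condition ensemble and
#' accumulates ensemble observables on the shared time grid: the fraction
#' of trajectories on each surface `Pi_k(t)`, the mean electronic
#' populations `rho_kk(t)`, and the decoherence indicator (ensemble mean
#' of `rho_11 rho_22`).
#'
#' @param model a built-in `surfhop_model`.
#' @param ics list with matrices `R` and `P` (one row per trajectory), as
#'   from [wigner_sample()] or [scattering_initial_conditions()].
#' @param config an [sh_config()].
#' @param active initial active state for every trajectory (1-based).
#' @param C0 initial coefficient vector (defaults to pure `active`).
#' @return object of class `ensemble_result` with `t`, matrices `Pi` and
#'   `rho` (time x states), `indicator`, `n_traj`, hop/frustrated counts,
#'   energy-drift and norm-drift statistics, per-trajectory final states,
#'   and the config echo.
#' @export
run_ensemble <- function(model, ics, config, active = 1L, C0 = NULL) {
  .check_engine_model(model)
  R <- as.matrix(ics$R); P <- as.matrix(ics$P)
  n <- nrow(R)
  if (is.null(C0)) { C0 <- rep(0 + 0i, 2); C0[active] <- 1 + 0i }
  nsnap <- config$n_steps %/% config$record_every + 1L
  Pi <- matrix(0, nsnap, 2)
  rho <- matrix(0, nsnap, 2)
  ind <- numeric(nsnap)
  tgrid <- NULL
  n_acc <- 0L; n_fru <- 0L; n_frozen <- 0L; n_coll <- 0L
  seg_drift <- numeric(n); hop_jump <- numeric(n); norm_dev <- numeric(n)
  fin_active <- integer(n); fin_x <- numeric(n); fin_p1 <- numeric(n)
  hop_counts <- integer(n)
  for (i in seq_len(n)) {
    res <- .propagate_cpp(model$engine_id, model$engine_params, model$masses,
                          R[i, 1], P[i, 1] / model$masses, active - 1L, C0,
                          config$dt, config$n_steps, config$n_substeps,
                          config$record_every,
                          .scheme_code[[config$decoherence]],
                          if (is.na(config$sigma)) 1 else config$sigma,
                          config$spawn_threshold, config$alpha,
                          .rescale_code[[config$rescale]],
                          .frustrated_code[[config$frustrated]],
                          config$seed, i, config$exit_x, FALSE)
    rec <- res$record
    if (is.null(tgrid)) tgrid <- rec$t
    act <- rec$active
    Pi[cbind(seq_len(nsnap), act)] <- Pi[cbind(seq_len(nsnap), act)] + 1
    rho <- rho + rec$pop
    ind <- ind + rec$pop[, 1] * rec$pop[, 2]
    d <- res$diagnostics
    n_acc <- n_acc + d$n_accepted; n_fru <- n_fru + d$n_frustrated
    n_frozen <- n_frozen + d$n_frozen_aux; n_coll <- n_coll + d$n_collapse
    seg_drift[i] <- d$max_seg_drift; hop_jump[i] <- d$max_hop_jump
    norm_dev[i] <- d$max_norm_dev
    hop_counts[i] <- d$n_accepted
    fin_active[i] <- res$final$active; fin_x[i] <- res$final$x
    fin_p1[i] <- Mod(res$final$C[1])^2
  }
  out <- list(t = tgrid, Pi = Pi / n, rho = rho / n, indicator = ind / n,
              n_traj = n, n_states = 2L,
              hops = list(accepted = n_acc, frustrated = n_fru,
                          mean_accepted_per_traj = n_acc / n,
                          counts = hop_counts),
              drift = list(seg = seg_drift, hop_jump = hop_jump,
                           norm = norm_dev, frozen_aux = n_frozen,
                           collapses = n_coll),
              final = data.frame(active = fin_active, x = fin_x, pop1 = fin_p1),
              config = config, model_label = model$label)
  class(out) <- "ensemble_result"
  out
}

#' @export
print.ensemble_result <- function(x, ...) {
  nf <- length(x$t)
  cat(sprintf("<ensemble_result> %s: %d trajectories, %d frames, t in [0, %.1f] a.u.\n",
              x$model_label, x$n_traj, nf, max(x$t)))
  cat(sprintf("  scheme %s | final Pi = (%s) | accepted hops/traj %.2f | frustrated %d\n",
              x$config$decoherence,
              paste(sprintf("%.3f", x$Pi[nf, ]), collapse = ", "),
              x$hops$mean_accepted_per_traj, x$hops$frustrated))
  invisible(x)
}

#' Final-state populations of an ensemble
#'
#' @param result an `ensemble_result`.
#' @param measure `"Pi"` (fraction of trajectories) or `"rho"` (mean
#'   electronic population).
#' @return numeric vector over states at the final recorded time.
#' @export
final_populations <- function(result, measure = c("Pi", "rho")) {
  measure <- match.arg(measure)
  m <- result[[measure]]
  m[nrow(m), ]
}
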