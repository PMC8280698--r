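#' Quantum momentum from auxiliary-trajectory positions
#'
#' The nuclear quantum momentum `-grad|chi|/|chi|` is approximated by
#' centering an equal-width Gaussian at each auxiliary-trajectory position
#' and evaluating the mixture's log-derivative at the real trajectory's
#' position to leading order:
#' `Q_nu = (R_nu - sum_k |C_k|^2 Raux_k,nu) / (2 sigma_nu^2)`.
#' The active state's "auxiliary" position is the real position itself.
#'
#' @param R real trajectory position (bohr).
#' @param aux_positions matrix `n_states x n_dof` of auxiliary positions
#'   (the active row equals `R`).
#' @param populations `|C_k|^2`, summing to 1 over live states.
#' @param sigma Gaussian width per DOF (bohr), > 0.
#' @return numeric quantum-momentum vector (1/bohr).
#' @export
quantum_momentum <- function(R, aux_positions, populations, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  aux_positions <- as.matrix(aux_positions)
  center <- colSums(populations * aux_positions)
  (R - center) / (2 * sigma^2)
}

#' SHXF decoherence contribution to the electronic equation
#'
#' The exact-factorization correction couples the quantum momentum to the
#' accumulated-force difference between surfaces:
#' `xi_n = sum_nu (Q_nu / M_nu) (f_n,nu - sum_l |C_l|^2 f_l,nu) C_n`
#' (hbar = 1).  The term redistributes population without changing the
#' norm, vanishes when a single state carries all population or when the
#' accumulated forces coincide, and drives population toward the state
#' whose accumulated force is aligned with the quantum momentum -- in
#' surface-hopping operation, the active state.
#'
#' @param C complex coefficients.
#' @param Q quantum momentum per DOF (1/bohr).
#' @param f accumulated forces, matrix `n_states x n_dof`
#'   (`f_k = -int grad eps_k dt`).
#' @param masses per-DOF masses.
#' @return complex vector `xi` (the additive contribution to `dC/dt`).
#' @export
shxf_xi <- function(C, Q, f, masses) {
  f <- as.matrix(f)
  pops <- Mod(C)^2
  fbar <- colSums(pops * f)
  lam <- as.numeric((f - matrix(fbar, nrow(f), ncol(f), byrow = TRUE)) %*%
                      (Q / masses))
  as.complex(lam * C)
}

#' SHXF auxiliary-trajectory update (reference implementation)
#'
#' Spawns an auxiliary trajectory on a nonactive surface once its
#' population exceeds `spawn_threshold`, launched from the parent position
#' along the parent's velocity direction with a speed fixed by isotropic
#' energy partition, `KE_aux = KE_parent + eps_active - eps_n`.  Each step
#' the position advances by its velocity; the speed is then refreshed from
#' energy conservation on surface n along the auxiliary's own direction of
#' travel (it reflects at its own classical turning points), and the
#' accumulated force is incremented by the resulting momentum change,
#' `f_n += M * dV_aux`.  A classically forbidden spawn (negative
#' partitioned kinetic energy) freezes the auxiliary (zero velocity) and
#' increments the `frozen` counter.  The auxiliary is killed when its
#' population drops below the threshold.
#'
#' This is the step-level R counterpart of the compiled engine's
#' bookkeeping, exposed for inspection and testing.
#'
#' @param state a [trajectory_state()] with populated `adiab` cache.
#' @param aux auxiliary state list (or `NULL` before any spawn): fields
#'   `alive`, `state` (which surface), `R`, `V`, `E` (conserved energy on
#'   its surface), `f` (`n_states x n_dof` accumulated forces), `frozen`,
#'   `spawn_t`.
#' @param model a `surfhop_model`.
#' @param dt nuclear step (a.u.).
#' @param spawn_threshold population cutoff.
#' @return updated auxiliary state list.
#' @export
shxf_update_aux <- function(state, aux, model, dt, spawn_threshold = 1e-4) {
  a <- state$active
  ns <- model$n_states
  pops <- Mod(state$C)^2
  n <- setdiff(seq_len(ns), a)[1]        # single nonactive surface (2-state)
  eps <- state$adiab$energies
  if (is.null(aux) || !isTRUE(aux$alive)) {
    if (pops[n] <= spawn_threshold) {
      return(list(alive = FALSE, state = n, R = state$R, V = 0 * state$V,
                  dir = 0 * state$V, E = NA_real_,
                  f = matrix(0, ns, model$n_dof),
                  frozen = FALSE, n_frozen = 0L, spawn_t = NA_real_))
    }
    KE_par <- 0.5 * sum(model$masses * state$V^2)
    KE_aux <- KE_par + eps[a] - eps[n]
    frozen <- KE_aux < 0
    n_frozen <- if (frozen) 1L else 0L
    vn <- sqrt(sum(state$V^2))
    dir <- if (vn > 0) state$V / vn else rep(0, length(state$V))
    Vaux <- if (frozen) 0 * state$V
            else dir * sqrt(2 * KE_aux / sum(model$masses * dir^2))
    return(list(alive = TRUE, state = n, R = state$R, V = Vaux, dir = dir,
                E = 0.5 * sum(model$masses * Vaux^2) + eps[n],
                f = matrix(0, ns, model$n_dof), frozen = frozen,
                n_frozen = n_frozen, spawn_t = state$t))
  }
  if (pops[aux$state] < min(1e-4, spawn_threshold)) {
    # kill hysteresis: spawning waits for genuine transfer, killing waits
    # for the population to become negligible
    aux$alive <- FALSE
    aux$f[] <- 0
    return(aux)
  }
  V_old <- aux$V
  aux$R <- aux$R + aux$V * dt
  eps_aux <- adiabatize(model$diabatic(aux$R))$energies[aux$state]
  KE_new <- aux$E - eps_aux
  if (KE_new >= 0) {
    aux$V <- aux$dir * sqrt(2 * KE_new / sum(model$masses * aux$dir^2))
  } else if (!isTRUE(aux$frozen)) {
    aux$dir <- -aux$dir    # classical turning point: reflect
    aux$V <- 0 * aux$V
  } else {
    aux$V <- 0 * aux$V     # spawn-forbidden aux stays at rest
  }
  aux$f[aux$state, ] <- aux$f[aux$state, ] + model$masses * (aux$V - V_old)
  aux
}

#' Energy-based decoherence damping (SHEDC)
#'
#' Nonactive amplitudes decay as `C_n <- C_n exp(-dt/tau_n)` with
#' `tau_n = (hbar/|eps_n - eps_a|) (1 + alpha/T)`, where `T` is the
#' nuclear kinetic energy; the active coefficient's magnitude is then
#' rescaled so the total population is 1 (its phase is untouched).  The
#' correction acts on the coefficients, not on the populations.  A zero
#' gap means an infinite decoherence time: no damping for that pair.
#'
#' @param C complex coefficients.
#' @param active active-state index (1-based).
#' @param eps adiabatic energies (Hartree).
#' @param T nuclear kinetic energy (Hartree), > 0.
#' @param alpha energy constant (Hartree), conventionally 0.1.
#' @param dt time step (a.u.).
#' @return damped, renormalized coefficient vector.
#' @export
edc_apply <- function(C, active, eps, T, alpha = 0.1, dt) {
  if (T <= 0) stop("kinetic energy must be positive")
  a <- active
  for (n in seq_along(C)) {
    if (n == a) next
    gap <- abs(eps[n] - eps[a])
    if (gap < 1e-12) next                # infinite tau: explicit no-damping branch
    tau <- (1 / gap) * (1 + alpha / T)
    C[n] <- C[n] * exp(-dt / tau)
  }
  off <- sum(Mod(C[-a])^2)
  target <- 1 - off
  if (target > 0) {
    can <- Mod(C[a])^2
    C[a] <- if (can > 0) C[a] * sqrt(target / can) else complex(real = sqrt(target))
  }
  C
}

#' A-FSSH moment propagation
#'
#' Advances the position and momentum moments of each nonactive surface
#' with the force difference `dF_n = -(grad eps_n - grad eps_a)` driving
#' `dP` and `dP/M` driving `dR`, in a velocity-Verlet step consistent with
#' the nuclear integrator.  Moments are zeroed on hops and on reset events
#' (by the caller).
#'
#' @param moments list with matrices `dR`, `dP`, `dF` (`n_states x n_dof`;
#'   active row zero).
#' @param adiab an `adiabatic_point` at the end of the step.
#' @param active active-state index.
#' @param masses per-DOF masses.
#' @param dt time step (a.u.).
#' @return updated moments list.
#' @export
afssh_step_moments <- function(moments, adiab, active, masses, dt) {
  a <- active
  for (n in seq_len(nrow(moments$dR))) {
    if (n == a) next
    dF_new <- -(adiab$gradients[n, ] - adiab$gradients[a, ])
    moments$dR[n, ] <- moments$dR[n, ] + moments$dP[n, ] / masses * dt +
      0.5 * moments$dF[n, ] / masses * dt^2
    moments$dP[n, ] <- moments$dP[n, ] + 0.5 * (moments$dF[n, ] + dF_new) * dt
    moments$dF[n, ] <- dF_new
  }
  moments$dR[a, ] <- 0; moments$dP[a, ] <- 0; moments$dF[a, ] <- 0
  moments
}

#' A-FSSH collapse and reset rates
#'
#' The collapse rate for a nonactive state n grows with how fast the
#' auxiliary trajectory separates from the active one,
#' `1/tau_c = (dF_n . dR_n)/2 - 2 |(eps_n - eps_a) d_an . dR_n|`
#' (hbar = 1), the second term being the off-diagonal-force contribution
#' built on the NACV.  The companion reset rate is
#' `1/tau_r = -(dF_n . dR_n)/2`: moments are reset when the surfaces pull
#' the auxiliary back toward the parent.
#'
#' @param moments list with matrices `dR`, `dP`, `dF`.
#' @param adiab an `adiabatic_point`.
#' @param active active-state index.
#' @return list of numeric vectors `collapse` and `reset` (per state;
#'   0 for the active state).
#' @export
afssh_rate <- function(moments, adiab, active) {
  a <- active
  ns <- nrow(moments$dR)
  collapse <- numeric(ns); reset <- numeric(ns)
  for (n in seq_len(ns)) {
    if (n == a) next
    dF <- -(adiab$gradients[n, ] - adiab$gradients[a, ])
    growth <- 0.5 * sum(dF * moments$dR[n, ])
    Fan <- (adiab$energies[n] - adiab$energies[a]) * adiab$nacv[a, n, ]
    collapse[n] <- growth - 2 * abs(sum(Fan * moments$dR[n, ]))
    reset[n] <- -growth
  }
  list(collapse = collapse, reset = reset)
}

#' A-FSSH stochastic collapse
#'
#' For each nonactive state, the amplitude is collapsed to zero when
#' `dt_c * rate` exceeds the state's uniform draw, with the active
#' amplitude increased so the total population stays 1.  A nonpositive
#' rate can never collapse.  Reset events zero the state's moments
#' without touching the coefficients.
#'
#' @param C complex coefficients.
#' @param active active-state index.
#' @param rates output of [afssh_rate()].
#' @param dt_c collapse time interval (a.u.; the nuclear step by default).
#' @param r_collapse,r_reset uniform draws per state.
#' @return list with `C`, logical vectors `collapsed` and `reset`.
#' @export
afssh_collapse <- function(C, active, rates, dt_c, r_collapse, r_reset) {
  a <- active
  ns <- length(C)
  collapsed <- logical(ns); reset <- logical(ns)
  for (n in seq_len(ns)) {
    if (n == a) next
    if (rates$collapse[n] > 0 && r_collapse[n] < dt_c * rates$collapse[n]) {
      C[n] <- 0 + 0i
      s <- sum(Mod(C)^2)
      if (s > 0) C <- C / sqrt(s)
      collapsed[n] <- TRUE
    } else if (rates$reset[n] > 0 && r_reset[n] < dt_c * rates$reset[n]) {
      reset[n] <- TRUE
    }
  }
  list(C = C, collapsed = collapsed, reset = reset)
}
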