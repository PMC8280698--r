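# shared fixtures and independent mini-oracles for the test suite

# characteristic-polynomial eigenvalue oracle (Faddeev-LeVerrier + polyroot),
# independent of LAPACK-based eigen()
charpoly_eigenvalues <- function(H) {
  n <- nrow(H)
  cf <- numeric(n + 1); cf[1] <- 1   # coefficients of lambda^n ... lambda^0
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    M <- H %*% M + cf[k] * diag(n)
    cf[k + 1] <- -sum(diag(H %*% M)) / k
  }
  roots <- polyroot(rev(cf))
  sort(Re(roots))
}

# constant-potential model: flat decoupled surfaces at the given energies
flat_model <- function(e1 = 0, e2 = 0.3, mass = 2000) {
  model_system(
    label = "flat", n_states = 2L, n_dof = 1L, masses = mass,
    diabatic = function(R) diag(c(e1, e2)),
    diabatic_gradient = function(R) array(0, dim = c(2, 2, 1)))
}

# single harmonic surface (state 1) with a flat far-away second state
harmonic_model <- function(k = 0.002, mass = 2000, offset = 0.5) {
  model_system(
    label = "harmonic", n_states = 2L, n_dof = 1L, masses = mass,
    diabatic = function(R) diag(c(0.5 * k * R^2, 0.5 * k * R^2 + offset)),
    diabatic_gradient = function(R)
      array(c(k * R, 0, 0, k * R), dim = c(2, 2, 1)))
}

# standard scattering ensemble used across dynamical tests
tully1_ics <- function(n, k0 = 15, seed = 3)
  scattering_initial_conditions(n, -6, k0, 0.35, 2000, seed)

# random complex coefficient vector with unit norm
random_unit_C <- function(n = 2) {
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  z / sqrt(sum(Mod(z)^2))
}

# hand-built adiabatic_point-like object for decoherence unit tests
fake_adiab <- function(energies, gradients, nacv01 = 0) {
  ns <- length(energies)
  nacv <- array(0, dim = c(ns, ns, 1))
  nacv[1, 2, 1] <- nacv01; nacv[2, 1, 1] <- -nacv01
  structure(list(energies = energies,
                 gradients = matrix(gradients, ns, 1),
                 nacv = nacv, eigvecs = diag(ns)),
            class = "adiabatic_point")
}
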