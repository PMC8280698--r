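#' Harmonic-mode specification for Wigner sampling
#'
#' Describes a set of uncoupled harmonic oscillators in their vibrational
#' ground state, from which initial nuclear conditions are drawn and the
#' SHXF Gaussian width is derived.
#'
#' @param frequencies per-mode angular frequency omega (a.u.), positive.
#' @param masses per-mode mass (a.u.), positive.
#' @param center equilibrium position R0 per mode (bohr).
#' @return object of class `harmonic_spec`.
#' @export
harmonic_spec <- function(frequencies, masses, center = 0) {
  frequencies <- as.numeric(frequencies)
  masses <- as.numeric(masses)
  if (length(masses) == 1L) masses <- rep(masses, length(frequencies))
  if (length(center) == 1L) center <- rep(center, length(frequencies))
  if (length(masses) != length(frequencies) || length(center) != length(frequencies))
    stop("frequencies, masses and center must have matching lengths")
  if (any(frequencies <= 0)) stop("frequencies must be strictly positive")
  if (any(masses <= 0)) stop("masses must be strictly positive")
  s <- list(frequencies = frequencies, masses = masses, center = as.numeric(center))
  class(s) <- "harmonic_spec"
  s
}

#' Wigner sampling of the harmonic ground state
#'
#' Draws initial positions and momenta from the Wigner distribution of the
#' ground vibrational state of each uncoupled mode: per mode,
#' `R ~ N(R0, 1/(2 m omega))` and `P ~ N(0, m omega / 2)`.  Positions and
#' momenta are uncorrelated.  With `momenta = "zero"` only geometries are
#' sampled and all momenta are set to 0.
#'
#' @param spec a [harmonic_spec()].
#' @param n number of samples (>= 1).
#' @param seed RNG seed; the same seed reproduces the identical ensemble.
#' @param momenta `"sampled"` or `"zero"`.
#' @return list with matrices `R` and `P` (`n x n_modes`) and the `seed`.
#' @export
wigner_sample <- function(spec, n, seed, momenta = c("sampled", "zero")) {
  stopifnot(inherits(spec, "harmonic_spec"), n >= 1)
  momenta <- match.arg(momenta)
  nm <- length(spec$frequencies)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  R <- matrix(0, n, nm); P <- matrix(0, n, nm)
  for (j in seq_len(nm)) {
    m <- spec$masses[j]; w <- spec$frequencies[j]
    R[, j] <- stats::rnorm(n, spec$center[j], sqrt(1 / (2 * m * w)))
    if (momenta == "sampled") P[, j] <- stats::rnorm(n, 0, sqrt(m * w / 2))
  }
  list(R = R, P = P, seed = seed, momenta = momenta)
}

#' SHXF Gaussian width from the sampled ground state
#'
#' The auxiliary-trajectory Gaussians are assigned the position-space
#' standard deviation of the ground-state nuclear density,
#' `sigma = sqrt(1/(2 m omega))` per mode, removing empiricism from the
#' choice of sigma.  A scalar `override` (a single value for the whole
#' system, as used for molecular runs) is honored verbatim and recorded.
#'
#' @param spec a [harmonic_spec()].
#' @param override optional positive scalar sigma (bohr) used instead of
#'   the derived per-mode values.
#' @return numeric vector of sigma per mode (or the scalar override),
#'   with attribute `"derived"` saying which route was taken.
#' @export
sigma_from_ground_state <- function(spec, override = NULL) {
  stopifnot(inherits(spec, "harmonic_spec"))
  if (!is.null(override)) {
    if (length(override) != 1L || override <= 0)
      stop("sigma override must be a positive scalar")
    out <- as.numeric(override)
    attr(out, "derived") <- FALSE
    return(out)
  }
  out <- sqrt(1 / (2 * spec$masses * spec$frequencies))
  attr(out, "derived") <- TRUE
  out
}

#' Scattering initial conditions for the 1D models
#'
#' Convenience wrapper: Wigner-samples a single harmonic mode whose
#' ground-state position spread is `sigma_x` (so the momentum spread is
#' `1/(2 sigma_x)`, a minimum-uncertainty packet matching the wavepacket
#' oracle's initial Gaussian), centered at `x0`, then shifts all momenta
#' by the incoming momentum `k0`.
#'
#' @param n number of trajectories.
#' @param x0 packet center (bohr).
#' @param k0 mean incoming momentum (a.u.).
#' @param sigma_x position standard deviation (bohr).
#' @param mass nuclear mass (a.u.).
#' @param seed RNG seed.
#' @param momenta `"sampled"` or `"zero"` (zero: every P is exactly k0).
#' @return list with `R`, `P` (n x 1 matrices), the implied
#'   `spec`, and `sigma` (the ground-state width, used as SHXF default).
#' @export
scattering_initial_conditions <- function(n, x0, k0, sigma_x, mass, seed,
                                          momenta = "sampled") {
  w <- 1 / (2 * mass * sigma_x^2)     # so that var(R) = sigma_x^2
  spec <- harmonic_spec(w, mass, x0)
  s <- wigner_sample(spec, n, seed, momenta)
  s$P <- s$P + k0
  list(R = s$R, P = s$P, spec = spec,
       sigma = as.numeric(sigma_from_ground_state(spec)))
}

#' Write / read a trajectory initial-condition ensemble as columnar text
#'
#' One row per trajectory: `id`, positions, momenta.  Runs are restartable
#' and auditable from this file.
#'
#' @param ens a list with matrices `R` and `P` as from [wigner_sample()].
#' @param path file path (tab-separated text).
#' @return `write_ensemble`: the path, invisibly. `read_ensemble`: a list
#'   with matrices `R` and `P`.
#' @export
write_ensemble <- function(ens, path) {
  R <- as.matrix(ens$R); P <- as.matrix(ens$P)
  df <- data.frame(id = seq_len(nrow(R)), R = R, P = P)
  colnames(df) <- c("id", paste0("R", seq_len(ncol(R))), paste0("P", seq_len(ncol(P))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  rc <- grep("^R", colnames(df)); pc <- grep("^P", colnames(df))
  list(R = as.matrix(df[, rc, drop = FALSE]),
       P = as.matrix(df[, pc, drop = FALSE]))
}
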