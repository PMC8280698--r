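#' Uniform spatial grid for wavepacket propagation
#'
#' @param xmin,xmax grid extent (bohr).
#' @param n number of points (a power of 2 keeps the FFT fast).
#' @return list with `x`, `dx`, `n`, and the FFT momentum grid `k`.
#' @export
wavepacket_grid <- function(xmin, xmax, n = 2048L) {
  n <- as.integer(n)
  dx <- (xmax - xmin) / n
  x <- xmin + dx * (seq_len(n) - 1)
  k <- 2 * pi / (n * dx) * c(0:(n %/% 2 - 1), -(n %/% 2):-1)
  list(x = x, dx = dx, n = n, k = k)
}

.wp_edge_density <- function(wp) {
  dens <- rowSums(Mod(wp$amps)^2) * wp$grid$dx
  m <- 8L
  max(dens[c(seq_len(m), wp$grid$n - seq_len(m) + 1L)])
}

.wp_norm <- function(wp) sum(Mod(wp$amps)^2) * wp$grid$dx

# diabatic potential tables and the mixing angle on the grid, cached per wp
.wp_pot <- function(wp, model) {
  if (!is.null(wp$pot) && identical(wp$pot$label, model$label)) return(wp$pot)
  if (!is.na(model$engine_id)) {
    tab <- .model_eval_grid_cpp(model$engine_id, model$engine_params, wp$grid$x)
  } else {
    H <- vapply(wp$grid$x, function(xx) {
      h <- model$diabatic(xx); c(h[1, 1], h[2, 2], h[1, 2])
    }, numeric(3))
    tab <- list(V11 = H[1, ], V22 = H[2, ], V12 = H[3, ])
  }
  tab$label <- model$label
  tab
}

# pointwise adiabatic rotation: columns of U are (lower, upper) eigvecs,
# same closed form and sign convention as the trajectory engine
.wp_rotation <- function(pot) {
  dd <- 0.5 * (pot$V11 - pot$V22)
  al <- atan2(pot$V12, dd)
  c2 <- cos(0.5 * al); s2 <- sin(0.5 * al)
  # lower: (-s2, c2), upper: (c2, s2)
  list(l1 = -s2, l2 = c2, u1 = c2, u2 = s2)
}

#' Initialize a Gaussian wavepacket on one electronic state
#'
#' `psi(x) = (2 pi sigma^2)^(-1/4) exp(-(x - x0)^2/(4 sigma^2) + i k0 x)`,
#' so the position density has standard deviation `sigma` and the mean
#' momentum is `k0`.  With `representation = "adiabatic"` the packet is
#' placed on an adiabatic state and rotated pointwise into the diabatic
#' basis used for propagation.
#'
#' @param grid a [wavepacket_grid()].
#' @param model a two-state `surfhop_model`.
#' @param center packet center x0 (bohr).
#' @param momentum mean momentum k0 (a.u.).
#' @param width position standard deviation sigma (bohr).
#' @param state initial electronic state (1-based; state 1 is the lower
#'   adiabatic state when `representation = "adiabatic"`).
#' @param mass nuclear mass (a.u.); defaults to the model's.
#' @param representation `"adiabatic"` or `"diabatic"`.
#' @return object of class `wavepacket`: `grid`, complex matrix `amps`
#'   (`n x 2`, diabatic), `mass`, `t`.
#' @export
init_gaussian <- function(grid, model, center, momentum, width, state = 1L,
                          mass = NULL, representation = c("adiabatic", "diabatic")) {
  representation <- match.arg(representation)
  if (center - 5 * width < grid$x[1] || center + 5 * width > grid$x[grid$n])
    stop("wavepacket support overlaps the grid edge; enlarge the grid")
  psi <- (2 * pi * width^2)^(-1 / 4) *
    exp(-(grid$x - center)^2 / (4 * width^2) + 1i * momentum * grid$x)
  amps <- matrix(0 + 0i, grid$n, 2)
  wp <- list(grid = grid, amps = amps,
             mass = if (is.null(mass)) model$masses[1] else mass, t = 0)
  if (representation == "diabatic") {
    wp$amps[, state] <- psi
  } else {
    pot <- .wp_pot(wp, model)
    rot <- .wp_rotation(pot)
    if (state == 1L) { wp$amps[, 1] <- rot$l1 * psi; wp$amps[, 2] <- rot$l2 * psi }
    else             { wp$amps[, 1] <- rot$u1 * psi; wp$amps[, 2] <- rot$u2 * psi }
    wp$pot <- pot
  }
  nrm <- .wp_norm(wp)
  wp$amps <- wp$amps / sqrt(nrm)
  class(wp) <- "wavepacket"
  wp
}

# half-step diabatic potential propagator: exact 2x2 matrix exponential
# exp(-i dt V(x)) per grid point, returned as three complex vectors
.wp_half_potential <- function(pot, dt) {
  mm <- 0.5 * (pot$V11 + pot$V22)
  dd <- 0.5 * (pot$V11 - pot$V22)
  r <- sqrt(dd^2 + pot$V12^2)
  ph <- exp(-1i * dt * mm)
  sinc <- ifelse(r > 0, sin(dt * r) / r, dt)
  list(p11 = ph * (cos(dt * r) - 1i * sinc * dd),
       p22 = ph * (cos(dt * r) + 1i * sinc * dd),
       p12 = ph * (-1i * sinc * pot$V12))
}

#' One split-operator step
#'
#' Half-step exact diabatic potential phase, full kinetic step in Fourier
#' space, half-step potential phase.  Unitary up to roundoff.
#'
#' @param wp a `wavepacket`.
#' @param model the model system.
#' @param dt_q quantum time step (a.u.).
#' @return the advanced `wavepacket`.
#' @export
split_operator_step <- function(wp, model, dt_q) {
  wp <- propagate_wavepacket(wp, model, dt_q, 1L)
  wp
}

#' Propagate a wavepacket for many split-operator steps
#'
#' @param wp a `wavepacket`.
#' @param model the model system.
#' @param dt_q quantum time step (a.u.).
#' @param n_steps number of steps.
#' @param check_edges abort when edge density exceeds `1e-10` (grid too
#'   small for the dynamics).
#' @return the advanced `wavepacket`.
#' @export
propagate_wavepacket <- function(wp, model, dt_q, n_steps, check_edges = TRUE) {
  pot <- .wp_pot(wp, model)
  wp$pot <- pot
  hv <- .wp_half_potential(pot, dt_q / 2)
  kin <- exp(-1i * dt_q * wp$grid$k^2 / (2 * wp$mass))
  a1 <- wp$amps[, 1]; a2 <- wp$amps[, 2]
  n <- wp$grid$n
  for (s in seq_len(n_steps)) {
    b1 <- hv$p11 * a1 + hv$p12 * a2
    b2 <- hv$p12 * a1 + hv$p22 * a2
    b1 <- stats::fft(kin * stats::fft(b1), inverse = TRUE) / n
    b2 <- stats::fft(kin * stats::fft(b2), inverse = TRUE) / n
    a1 <- hv$p11 * b1 + hv$p12 * b2
    a2 <- hv$p12 * b1 + hv$p22 * b2
  }
  wp$amps[, 1] <- a1; wp$amps[, 2] <- a2
  wp$t <- wp$t + dt_q * n_steps
  if (check_edges && .wp_edge_density(wp) > 1e-10)
    stop("wavepacket density reached the grid edge: grid too small")
  wp
}

#' Position and momentum expectation values and moments
#'
#' @param wp a `wavepacket`.
#' @return list with `norm`, `x_mean`, `x_var`, `p_mean`.
#' @export
wavepacket_moments <- function(wp) {
  dx <- wp$grid$dx
  dens <- rowSums(Mod(wp$amps)^2)
  nrm <- sum(dens) * dx
  xm <- sum(wp$grid$x * dens) * dx / nrm
  xv <- sum((wp$grid$x - xm)^2 * dens) * dx / nrm
  pk1 <- Mod(stats::fft(wp$amps[, 1]))^2
  pk2 <- Mod(stats::fft(wp$amps[, 2]))^2
  pm <- sum(wp$grid$k * (pk1 + pk2)) / sum(pk1 + pk2)
  list(norm = nrm, x_mean = xm, x_var = xv, p_mean = pm)
}

#' Adiabatic populations of a wavepacket
#'
#' Rotates the diabatic amplitudes to the adiabatic basis pointwise and
#' integrates the per-state density.
#'
#' @param wp a `wavepacket`.
#' @param model the model system.
#' @return numeric vector `P_n` (sums to 1).
#' @export
adiabatic_populations <- function(wp, model) {
  pot <- .wp_pot(wp, model)
  rot <- .wp_rotation(pot)
  low <- rot$l1 * wp$amps[, 1] + rot$l2 * wp$amps[, 2]
  up <- rot$u1 * wp$amps[, 1] + rot$u2 * wp$amps[, 2]
  c(sum(Mod(low)^2), sum(Mod(up)^2)) * wp$grid$dx
}

#' Per-state transmission and reflection probabilities
#'
#' Integrates the adiabatic per-state density left and right of a dividing
#' point once the packet has left the interaction region.
#'
#' @param wp a `wavepacket`.
#' @param model the model system.
#' @param dividing_point x value separating reflection from transmission.
#' @param interaction_halfwidth probability mass within this distance of
#'   the dividing point must be below `1e-4`, else the propagation is not
#'   converged.
#' @return data frame with one row per adiabatic state: `reflection`,
#'   `transmission`.
#' @export
scattering_probabilities <- function(wp, model, dividing_point = 0,
                                     interaction_halfwidth = 1) {
  pot <- .wp_pot(wp, model)
  rot <- .wp_rotation(pot)
  low <- Mod(rot$l1 * wp$amps[, 1] + rot$l2 * wp$amps[, 2])^2
  up <- Mod(rot$u1 * wp$amps[, 1] + rot$u2 * wp$amps[, 2])^2
  x <- wp$grid$x; dx <- wp$grid$dx
  near <- abs(x - dividing_point) < interaction_halfwidth
  if (sum((low + up)[near]) * dx > 1e-4)
    stop("not converged: packet still in the interaction region")
  left <- x < dividing_point
  data.frame(state = 1:2,
             reflection = c(sum(low[left]), sum(up[left])) * dx,
             transmission = c(sum(low[!left]), sum(up[!left])) * dx)
}

#' Run the exact scattering oracle for a built-in model
#'
#' Initializes a Gaussian on an adiabatic state, propagates with the
#' split-operator method until the interaction region has emptied (or
#' `t_max`), and returns the adiabatic populations over time.
#'
#' @param model the model system.
#' @param x0,k0,sigma_x initial packet center, momentum, and width.
#' @param state initial adiabatic state.
#' @param dt_q quantum time step (a.u.).
#' @param t_max maximum propagation time (a.u.).
#' @param grid optional [wavepacket_grid()] (a default is chosen from the
#'   run parameters).
#' @param sample_every store populations every this many steps.
#' @return list with `t`, matrix `P` (time x 2 adiabatic populations),
#'   and the final `wavepacket`.
#' @export
run_oracle <- function(model, x0, k0, sigma_x, state = 1L, dt_q = 0.5,
                       t_max = 4000, grid = NULL, sample_every = 20L) {
  if (is.null(grid)) {
    span <- abs(k0) / model$masses[1] * t_max + 10 * sigma_x + abs(x0)
    grid <- wavepacket_grid(-span, span,
                            n = 2^ceiling(log2(span * 2 / 0.03)))
  }
  wp <- init_gaussian(grid, model, x0, k0, sigma_x, state = state)
  nsteps <- ceiling(t_max / dt_q)
  nchunk <- ceiling(nsteps / sample_every)
  tgrid <- numeric(nchunk + 1); P <- matrix(0, nchunk + 1, 2)
  tgrid[1] <- 0; P[1, ] <- adiabatic_populations(wp, model)
  for (i in seq_len(nchunk)) {
    wp <- propagate_wavepacket(wp, model, dt_q, sample_every)
    tgrid[i + 1] <- wp$t
    P[i + 1, ] <- adiabatic_populations(wp, model)
  }
  list(t = tgrid, P = P, wp = wp)
}
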