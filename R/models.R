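#' Construct an analytic diabatic model system
#'
#' A model system bundles a symmetric diabatic potential matrix, its
#' position derivatives, and per-degree-of-freedom nuclear masses.  It is
#' the source of adiabatic (Born--Oppenheimer) energies, Hellmann--Feynman
#' gradients, and nonadiabatic coupling vectors (NACVs) for the dynamics.
#'
#' All quantities are in Hartree atomic units: energies in Hartree,
#' positions in bohr, masses in electron masses.
#'
#' @param label identifier string.
#' @param n_states number of electronic states.
#' @param n_dof number of nuclear degrees of freedom.
#' @param masses numeric vector of length `n_dof`, strictly positive (a.u.).
#' @param diabatic function `R -> n_states x n_states` symmetric matrix
#'   of diabatic potentials (Hartree) at position `R` (bohr).
#' @param diabatic_gradient function `R -> array(n_states, n_states, n_dof)`
#'   of derivatives (Hartree/bohr).
#' @param engine_id optional integer id of a compiled built-in model (used
#'   by the fast ensemble propagator); `NA` for user-defined models.
#' @param engine_params numeric parameter vector for the compiled model.
#'
#' @return an object of class `surfhop_model`.
#' @export
model_system <- function(label, n_states, n_dof, masses, diabatic,
                         diabatic_gradient, engine_id = NA_integer_,
                         engine_params = numeric()) {
  stopifnot(is.function(diabatic), is.function(diabatic_gradient))
  if (any(masses <= 0)) stop("masses must be strictly positive")
  if (length(masses) != n_dof) stop("need one mass per degree of freedom")
  m <- list(label = label, n_states = as.integer(n_states),
            n_dof = as.integer(n_dof), masses = as.numeric(masses),
            diabatic = diabatic, diabatic_gradient = diabatic_gradient,
            engine_id = engine_id, engine_params = as.numeric(engine_params))
  class(m) <- "surfhop_model"
  m
}

#' @export
print.surfhop_model <- function(x, ...) {
  cat(sprintf("<surfhop_model> %s: %d states, %d DOF, mass %s a.u.\n",
              x$label, x$n_states, x$n_dof,
              paste(signif(x$masses, 4), collapse = ", ")))
  invisible(x)
}

# builds a 1D two-state surfhop_model on top of the compiled potentials,
# so R-level and engine-level evaluations share one implementation
.builtin_1d <- function(label, engine_id, params, mass) {
  pars <- as.numeric(params)
  model_system(
    label = label, n_states = 2L, n_dof = 1L, masses = mass,
    diabatic = function(R) .model_eval_cpp(engine_id, pars, as.numeric(R))$H,
    diabatic_gradient = function(R) {
      G <- .model_eval_cpp(engine_id, pars, as.numeric(R))$dH
      array(G, dim = c(2L, 2L, 1L))
    },
    engine_id = engine_id, engine_params = pars)
}

.builtin_defaults <- list(
  single_crossing = list(id = 1L, mass = 2000,
    params = c(A = 0.01, B = 1.6, C = 0.005, D = 1.0)),
  dual_crossing = list(id = 2L, mass = 2000,
    params = c(A = 0.10, B = 0.28, C = 0.015, D = 0.06, E0 = 0.05)),
  extended_coupling = list(id = 3L, mass = 2000,
    params = c(A = 6e-4, B = 0.10, C = 0.90)),
  sharp_slope = list(id = 4L, mass = 2000,
    params = c(A = 0.03, B = 4.0, C = 6e-5, D = 8.0))
)

#' Catalogue of built-in model Hamiltonians
#'
#' Four one-dimensional two-state scattering models:
#' \describe{
#'   \item{`single_crossing`}{single avoided crossing (standard
#'     parameterization: A = 0.01, B = 1.6, C = 0.005, D = 1); one
#'     nonadiabatic event per passage.}
#'   \item{`dual_crossing`}{dual avoided crossing with Stueckelberg
#'     interference (A = 0.1, B = 0.28, C = 0.015, D = 0.06, E0 = 0.05).}
#'   \item{`extended_coupling`}{extended coupling with reflection; the
#'     upper-state packet reflects and recrosses the coupling region,
#'     the classic stress test for internal consistency.}
#'   \item{`sharp_slope`}{steeply sloped crossing with a very narrow
#'     coupling region (tanh diagonals, narrow Gaussian coupling), an
#'     in-house fixture in which coarse nuclear time steps can step over
#'     the interaction region entirely.}
#' }
#' All use a nuclear mass of 2000 a.u.
#'
#' @return named list of `surfhop_model` objects.
#' @export
builtin_models <- function() {
  out <- lapply(names(.builtin_defaults), function(nm) get_model(nm))
  names(out) <- names(.builtin_defaults)
  out
}

#' Retrieve a built-in model by name, optionally overriding parameters
#'
#' @param name one of `names(builtin_models())` (aliases `tully1`,
#'   `tully2`, `tully3` are accepted).
#' @param params named list/vector overriding individual potential
#'   parameters.
#' @param mass nuclear mass override (a.u.).
#' @return a `surfhop_model`.
#' @export
get_model <- function(name, params = NULL, mass = NULL) {
  alias <- c(tully1 = "single_crossing", tully2 = "dual_crossing",
             tully3 = "extended_coupling")
  if (name %in% names(alias)) name <- alias[[name]]
  if (!name %in% names(.builtin_defaults))
    stop(sprintf("unknown model label '%s' (available: %s)", name,
                 paste(names(.builtin_defaults), collapse = ", ")))
  def <- .builtin_defaults[[name]]
  p <- def$params
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown model parameters: ", paste(bad, collapse = ", "))
    p[names(params)] <- unlist(params)
  }
  .builtin_1d(name, def$id, p, if (is.null(mass)) def$mass else mass)
}

#' Dump the built-in model catalogue as JSON
#'
#' @param path optional file to write to; otherwise the JSON string is
#'   returned.
#' @return JSON string (invisibly if written to file).
#' @export
model_catalogue_json <- function(path = NULL) {
  cat_list <- lapply(.builtin_defaults, function(d)
    list(engine_id = d$id, mass = d$mass, params = as.list(d$params)))
  js <- jsonlite::toJSON(cat_list, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Diagonalize a symmetric diabatic matrix with phase continuity
#'
#' Eigenvalues are returned in ascending order.  Each eigenvector's sign is
#' chosen to maximize overlap with the corresponding column of
#' `prev_eigvecs` (continuity along a path); without a previous frame the
#' first non-negligible component is made positive.
#'
#' @param H symmetric real matrix (Hartree).
#' @param prev_eigvecs optional orthonormal matrix from the previous
#'   evaluation point.
#' @return list with `energies` (ascending) and `eigvecs` (columns).
#' @export
adiabatize <- function(H, prev_eigvecs = NULL) {
  H <- as.matrix(H)
  if (max(abs(H - t(H))) > 1e-10 * max(1, max(abs(H))))
    stop("diabatic matrix must be symmetric")
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    if (!is.null(prev_eigvecs)) {
      if (sum(vecs[, j] * prev_eigvecs[, j]) < 0) vecs[, j] <- -vecs[, j]
    } else {
      lead <- which(abs(vecs[, j]) > 1e-12)[1]
      if (vecs[lead, j] < 0) vecs[, j] <- -vecs[, j]
    }
  }
  list(energies = vals, eigvecs = vecs)
}

#' Adiabatic energies, gradients and NACVs at a nuclear position
#'
#' Diagonalizes the diabatic matrix at `R` and rotates the diabatic
#' gradient: gradients are the Hellmann--Feynman diagonal elements
#' `(U' dH U)_nn` and the NACV between states n and k is
#' `d_nk = (U' dH U)_nk / (eps_k - eps_n)`.
#'
#' @param model a `surfhop_model`.
#' @param R position vector (bohr).
#' @param prev optional previous `adiabatic_point` result, used for
#'   eigenvector phase continuity.
#' @return list of class `adiabatic_point` with `energies` (ascending),
#'   `gradients` (`n_states x n_dof`), `nacv`
#'   (`n_states x n_states x n_dof`, antisymmetric), `eigvecs`.
#' @export
adiabatic_point <- function(model, R, prev = NULL) {
  H <- model$diabatic(R)
  ad <- adiabatize(H, prev$eigvecs)
  ns <- model$n_states; nd <- model$n_dof
  gaps <- outer(ad$energies, ad$energies, "-")
  if (any(abs(gaps[upper.tri(gaps)]) < 1e-10))
    stop("conical-intersection point: degenerate adiabatic energies (NACV undefined)")
  dH <- model$diabatic_gradient(R)
  grad <- matrix(0, ns, nd)
  nacv <- array(0, dim = c(ns, ns, nd))
  U <- ad$eigvecs
  for (v in seq_len(nd)) {
    G <- t(U) %*% dH[, , v] %*% U
    G <- (G + t(G)) / 2            # numerically exact symmetry -> exact d_nk = -d_kn
    grad[, v] <- diag(G)
    dmat <- G / t(gaps)          # d_nk = G_nk / (e_k - e_n)
    diag(dmat) <- 0
    nacv[, , v] <- dmat
  }
  out <- list(energies = ad$energies, gradients = grad, nacv = nacv,
              eigvecs = U)
  class(out) <- "adiabatic_point"
  out
}
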