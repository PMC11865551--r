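## Convenience layer tying the modules together: FCI training-state solves,
## one-call model training, and energy/force providers for molecular
## dynamics.

#' Solve an FCI training state at one geometry
#'
#' Builds AO integrals, the SAO transform and the SAO-basis Hamiltonian, and
#' diagonalizes. The returned CI vector is expressed in the SAO basis of the
#' given geometry, ready for [add_training_state()].
#'
#' @param geom a [geometry()]
#' @param basis_name built-in basis name
#' @param tol Davidson residual tolerance
#' @param guess optional warm-start CI vector (numeric) for Davidson
#' @return list with `state` (`ci_vector`), `energy`, `sao`
#'   (`sao_integrals`), `transform`, `ao`
#' @export
fci_training_state <- function(geom, basis_name, tol = 1e-9, guess = NULL) {
  ao <- compute_ao_integrals(geom, basis_name)
  tr <- lowdin_transform(ao$overlap)
  sao <- rotate_to_sao(ao, tr)
  n_alpha <- ceiling(sao$n_elec / 2)
  space <- determinant_space(sao$L, n_alpha, sao$n_elec - n_alpha)
  if (is.null(guess) && space$dimension > 2000 && sao$n_elec %% 2 == 0) {
    ## cold large solve: seed Davidson with the Hartree-Fock determinant
    guess <- hf_determinant_guess(ao, tr, space)
  }
  st <- fci_ground_state(sao, tol = tol,
                         guess = if (is.null(guess)) NULL else as.matrix(guess))[[1]]
  list(state = st, energy = st$energy, sao = sao, transform = tr, ao = ao)
}

#' Train a continuation model on a list of geometries
#'
#' @param geometries list of [geometry()]
#' @param basis_name built-in basis name
#' @param tol Davidson residual tolerance
#' @param verbose print per-geometry energies
#' @return a `training_set` with one exact FCI state per geometry
#' @export
train_continuation <- function(geometries, basis_name, tol = 1e-9,
                               verbose = FALSE) {
  training <- training_set()
  guess <- NULL
  for (g in geometries) {
    fs <- fci_training_state(g, basis_name, tol = tol, guess = guess)
    guess <- fs$state$amplitudes
    training <- add_training_state(training, fs$state, g, fs$energy,
                                   basis_name = basis_name)
    if (verbose) message(sprintf("trained state %d: E = %.10f hartree",
                                 n_training(training), fs$energy))
  }
  training
}

#' Continuation-inferred CI amplitudes as a Davidson starting vector
#'
#' The inferred state `sum_a X_a C^(a)` at a geometry is typically an
#' excellent warm start for an exact solve there — the closer the model, the
#' fewer Davidson iterations the training solve needs.
#'
#' @param training a `training_set` holding CI amplitudes
#' @param sao_ints `sao_integrals` at the target geometry
#' @return numeric amplitude vector, or NULL when no amplitudes are stored
#' @export
continuation_guess <- function(training, sao_ints) {
  if (length(training$ci) == 0) return(NULL)
  X <- infer_state(training, sao_ints)$coefficients
  g <- 0
  for (a in seq_along(X)) g <- g + X[a] * training$ci[[a]]$amplitudes
  n <- sqrt(sum(g^2))
  if (n < 1e-12) return(NULL)
  g / n
}

#' Continuation energy (and optionally state) at a test geometry
#'
#' @param training a `training_set`
#' @param geom a [geometry()]
#' @param detail return the full `continuation_result` instead of the energy
#' @return inferred energy in hartree, or a `continuation_result`
#' @export
continuation_energy <- function(training, geom, detail = FALSE) {
  ao <- compute_ao_integrals(geom, training$basis_name)
  sao <- rotate_to_sao(ao, lowdin_transform(ao$overlap),
                       n_elec = training$n_elec)
  res <- infer_state(training, sao)
  if (detail) res else res$energy
}

#' Energy/force provider on the continuation surface
#'
#' Returns a function `f(geom)` giving `list(energy, forces, result)` for use
#' with [run_bomd()]. Forces come from the analytic gradient by default.
#'
#' @param training a `training_set`
#' @param gradient_mode "analytic" or "finite_difference"
#' @return provider closure
#' @export
continuation_pes <- function(training, gradient_mode = "analytic") {
  force(training)
  function(geom) {
    basis <- build_basis(geom, training$basis_name)
    ao <- compute_ao_integrals(geom, basis)
    sao <- rotate_to_sao(ao, lowdin_transform(ao$overlap),
                         n_elec = training$n_elec)
    res <- infer_state(training, sao)
    gr <- analytic_gradient(res, training, geom, basis, mode = gradient_mode)
    list(energy = res$energy, forces = gr$forces, result = res)
  }
}
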