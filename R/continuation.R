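## Eigenvector continuation core. A training set holds, for every pair of
## training states, the spin-summed transition 2-RDMs Gamma_ab and overlaps
## S_ab computed once in the SAO representation. At any test geometry the
## subspace Hamiltonian is the O(N^2 L^4) contraction H_ab = sum Gamma_ab K(R)
## + S_ab E_nuc(R); the lowest root of H X = E S X is the variational
## inferred energy, exact at training geometries and monotonically lowered by
## every added training state.

#' Create an empty continuation training set
#'
#' Metadata (basis, orbital and electron counts) is fixed by the first state
#' added via [add_training_state()].
#' @return an object of class `training_set` with N = 0
#' @export
training_set <- function() {
  structure(list(
    geometries = list(), energies = numeric(0),
    basis_name = NULL, L = NULL, n_elec = NULL, n_alpha = NULL, n_beta = NULL,
    overlap = matrix(0, 0, 0), gamma1 = list(), gamma2 = list(),
    ci = list()
  ), class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set: N = %d states, basis '%s', L = %s>\n",
              length(x$energies),
              if (is.null(x$basis_name)) "?" else x$basis_name,
              if (is.null(x$L)) "?" else x$L))
  invisible(x)
}

n_training <- function(training) length(training$energies)

#' Add a training state to a continuation model
#'
#' Computes the transition 1-/2-RDMs and overlaps of the new CI vector
#' against every state already present (all states share one determinant
#' space; their amplitudes are treated as living in a single abstract Fock
#' space, which is what makes the model geometry-agnostic). The model is
#' ready for inference immediately after every addition.
#'
#' @param training a `training_set`
#' @param state a `ci_vector` expressed in the SAO basis of its own geometry
#' @param geometry the [geometry()] the state was solved at
#' @param energy the training-solver energy in hartree
#' @param basis_name basis-set tag recorded on first addition
#' @return the enlarged `training_set`
#' @export
add_training_state <- function(training, state, geometry, energy,
                               basis_name = NULL) {
  N <- n_training(training)
  if (N == 0) {
    training$L <- state$space$n_orb
    training$n_alpha <- state$space$n_alpha
    training$n_beta <- state$space$n_beta
    training$n_elec <- state$space$n_alpha + state$space$n_beta
    training$basis_name <- basis_name
  } else {
    if (state$space$n_orb != training$L ||
        state$space$n_alpha != training$n_alpha ||
        state$space$n_beta != training$n_beta) {
      stop("training-state dimensions do not match the model")
    }
    if (length(training$ci) == 0) {
      stop("this training set was loaded from disk without CI amplitudes ",
           "and cannot be extended")
    }
    for (g in training$geometries) {
      if (length(g$atomic_numbers) == length(geometry$atomic_numbers) &&
          max(abs(g$coordinates - geometry$coordinates)) < 1e-12) {
        warning("duplicate training geometry added; the new state is ",
                "linearly dependent and will be handled by regularization")
        break
      }
    }
  }
  new_idx <- N + 1L
  training$geometries[[new_idx]] <- geometry
  training$energies[new_idx] <- energy
  training$ci[[new_idx]] <- state
  ## grow the pairwise blocks
  ov <- matrix(0, new_idx, new_idx)
  if (N > 0) ov[1:N, 1:N] <- training$overlap
  g1 <- training$gamma1; g2 <- training$gamma2
  for (a in seq_len(new_idx)) {
    if (a == new_idx) {
      r <- transition_rdms(state, state)
    } else {
      r <- transition_rdms(training$ci[[a]], state)
    }
    g2[[paste(a, new_idx)]] <- r$gamma2
    g1[[paste(a, new_idx)]] <- r$gamma1
    if (a != new_idx) {
      ## hermiticity for real amplitudes: Gamma_ba = Gamma_ab with ijkl->klij
      g2[[paste(new_idx, a)]] <- aperm(r$gamma2, c(3, 4, 1, 2))
      g1[[paste(new_idx, a)]] <- t(r$gamma1)
    }
    ov[a, new_idx] <- r$overlap
    ov[new_idx, a] <- r$overlap
  }
  training$overlap <- ov
  training$gamma1 <- g1
  training$gamma2 <- g2
  training
}

.ts_gamma2 <- function(training, a, b) training$gamma2[[paste(a, b)]]
.ts_gamma1 <- function(training, a, b) training$gamma1[[paste(a, b)]]

#' Assemble the subspace Hamiltonian and overlap at a test geometry
#'
#' `H_ab = sum_ijkl Gamma_ab^ijkl K_ijkl(R) + S_ab E_nuc(R)`; the training
#' overlap matrix does not change with geometry and is returned as stored.
#'
#' @param training a `training_set` with N >= 1
#' @param sao_ints `sao_integrals` at the test geometry (matching L, n_elec)
#' @return list with `H` and `S` (N x N matrices)
#' @export
assemble_subspace_matrices <- function(training, sao_ints) {
  N <- n_training(training)
  if (N < 1) stop("empty training set")
  if (sao_ints$L != training$L) stop("basis size mismatch (L = ", sao_ints$L,
                                     " vs model L = ", training$L, ")")
  if (!is.null(training$basis_name) &&
      !is.null(attr(sao_ints, "basis_name")) &&
      !identical(attr(sao_ints, "basis_name"), training$basis_name)) {
    stop("integrals tagged basis '", attr(sao_ints, "basis_name"),
         "' do not match model basis '", training$basis_name, "'")
  }
  K <- sao_ints$k_tensor
  if (is.null(K)) stop("sao_integrals carry no K tensor")
  H <- matrix(0, N, N)
  for (a in seq_len(N)) {
    for (b in a:N) {
      v <- sum(.ts_gamma2(training, a, b) * K) +
        training$overlap[a, b] * sao_ints$e_nuc
      H[a, b] <- v
      H[b, a] <- v
    }
  }
  list(H = H, S = training$overlap)
}

#' Infer the continued state at a test geometry
#'
#' Solves the generalized eigenproblem `H X = E S X` in the training-state
#' basis by canonical orthogonalization: overlap eigenvalues below
#' `cutoff * max(eigenvalue)` are dropped, the problem is solved in the
#' retained subspace, and the lowest root is the variational inferred
#' ground-state energy.
#'
#' @param training a `training_set` with N >= 1
#' @param sao_ints `sao_integrals` at the test geometry
#' @param cutoff relative overlap-eigenvalue cutoff (default 1e-10)
#' @return object of class `continuation_result`: `coefficients` (length N,
#'   S-normalized), `energy` (lowest root, hartree), `spectrum` (all retained
#'   roots), `rdm1` (L x L inferred SAO 1-RDM), `condition_report`
#' @export
infer_state <- function(training, sao_ints, cutoff = 1e-10) {
  am <- assemble_subspace_matrices(training, sao_ints)
  N <- n_training(training)
  es <- eigen((am$S + t(am$S)) / 2, symmetric = TRUE)
  keep <- es$values >= cutoff * max(es$values)
  if (!any(keep)) stop("internal error: all overlap eigenvalues below cutoff")
  Xb <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  Ht <- crossprod(Xb, am$H %*% Xb)
  ee <- eigen((Ht + t(Ht)) / 2, symmetric = TRUE)
  ord <- order(ee$values)
  vals <- ee$values[ord]
  X <- Xb %*% ee$vectors[, ord[1]]
  ## S-normalize (canonical orthogonalization already ensures this)
  X <- X / sqrt(as.numeric(crossprod(X, am$S %*% X)))
  rdm1 <- matrix(0, training$L, training$L)
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      rdm1 <- rdm1 + X[a] * X[b] * .ts_gamma1(training, a, b)
    }
  }
  structure(list(
    coefficients = as.numeric(X),
    energy = vals[1],
    spectrum = vals,
    rdm1 = (rdm1 + t(rdm1)) / 2,
    condition_report = list(n_training = N, retained = sum(keep),
                            cutoff = cutoff,
                            overlap_eigenvalues = es$values)
  ), class = "continuation_result")
}

#' @export
print.continuation_result <- function(x, ...) {
  cat(sprintf("<continuation_result: E = %.10f hartree, %d/%d subspace vectors retained>\n",
              x$energy, x$condition_report$retained,
              x$condition_report$n_training))
  invisible(x)
}

## X-weighted 2-RDM of the inferred state (SAO, physicists' index order)
.inferred_gamma2 <- function(result, training) {
  X <- result$coefficients
  N <- length(X)
  G <- .ts_gamma2(training, 1, 1) * X[1]^2
  if (N > 1) {
    for (a in seq_len(N)) {
      for (b in seq_len(N)) {
        if (a == 1 && b == 1) next
        G <- G + X[a] * X[b] * .ts_gamma2(training, a, b)
      }
    }
  }
  G
}

#' Electronic observables of the continued state
#'
#' Dipole moment and atomic partial charges from the inferred one-body
#' density matrix. The SAO density is rotated back to the AO basis for
#' Mulliken analysis (`q_A = Z_A - sum_{alpha in A} (rho S)_aa`); Loewdin
#' populations (the natural diagonal in the SAO basis) are also reported.
#'
#' @param result a `continuation_result`
#' @param training the `training_set` used for the inference
#' @param geometry the test [geometry()]
#' @param ao `ao_integrals` at the test geometry
#' @param transform the `sao_transform` at the test geometry
#' @param origin dipole reference point (bohr)
#' @param fragments optional named list of atom-index vectors; per-fragment
#'   charge sums are added to the output
#' @return list with `dipole` (length-3 vector, atomic units),
#'   `dipole_magnitude`, `mulliken_charges`, `lowdin_charges`, and
#'   optionally `fragment_charges`
#' @export
predict_observables <- function(result, training, geometry, ao, transform,
                                origin = c(0, 0, 0), fragments = NULL) {
  if (is.null(result$rdm1)) stop("continuation result carries no 1-RDM")
  Z <- transform$Z
  rho_ao <- Z %*% result$rdm1 %*% t(Z)
  basis <- attr(ao, "basis")
  if (is.null(basis)) stop("ao_integrals carry no basis; dipole integrals unavailable")
  dip <- compute_dipole_integrals(geometry, basis, origin = origin)
  zv <- geometry$atomic_numbers
  nuc <- colSums(sweep(geometry$coordinates, 2, as.numeric(origin), "-") * zv)
  del <- vapply(1:3, function(c) -sum(rho_ao * dip[c, , ]), 0)
  dipole <- del + nuc
  fn_atom <- attr(basis, "fn_atom")
  pop_mul <- diag(rho_ao %*% ao$overlap)
  pop_low <- diag(result$rdm1)
  q_mul <- zv - as.numeric(tapply(pop_mul, fn_atom, sum)[as.character(seq_along(zv))])
  q_low <- zv - as.numeric(tapply(pop_low, fn_atom, sum)[as.character(seq_along(zv))])
  out <- list(dipole = dipole, dipole_magnitude = sqrt(sum(dipole^2)),
              mulliken_charges = q_mul, lowdin_charges = q_low)
  if (!is.null(fragments)) {
    out$fragment_charges <- vapply(fragments, function(ix) sum(q_mul[ix]), 0)
  }
  out
}

#' Analytic nuclear gradient of the inferred energy
#'
#' Because the training amplitudes are geometry-independent and the subspace
#' coefficients are variationally optimal, dE/dR has no response terms: it is
#' the contraction of the inferred 2-RDM with dK/dR (AO-integral derivatives
#' rotated into the SAO basis plus the Pulay term from d(S^(-1/2))/dR) plus
#' the nuclear-repulsion derivative.
#'
#' @param result a `continuation_result` at `geometry`
#' @param training the `training_set` used
#' @param geometry the test [geometry()]
#' @param basis a `basis_set` or basis name for the model's basis
#' @param mode "analytic" or "finite_difference" (central differences of
#'   [infer_state()] energies with step `fd_step`)
#' @param fd_step finite-difference step in bohr (default 1e-4)
#' @return object of class `gradient_result`: `forces` (n_atom x 3 matrix,
#'   hartree/bohr, negative gradient), `gradient` (length 3N vector), and
#'   `components` (integral-derivative vs Pulay vs nuclear breakdown)
#' @export
analytic_gradient <- function(result, training, geometry, basis,
                              mode = c("analytic", "finite_difference"),
                              fd_step = 1e-4) {
  mode <- match.arg(mode)
  nat <- n_atoms(geometry)
  if (mode == "finite_difference") {
    grad <- numeric(3 * nat)
    for (a in seq_len(nat)) {
      for (c in 1:3) {
        k <- 3 * (a - 1) + c
        ep <- .infer_energy_at(training,
                               .displace(geometry, a, c, fd_step), basis)
        em <- .infer_energy_at(training,
                               .displace(geometry, a, c, -fd_step), basis)
        grad[k] <- (ep - em) / (2 * fd_step)
      }
    }
    return(.gradient_result(grad, nat, NULL))
  }
  if (is.character(basis)) basis <- build_basis(geometry, basis)
  ao <- compute_ao_integrals(geometry, basis)
  tr <- lowdin_transform(ao$overlap)
  sao <- rotate_to_sao(ao, tr, n_elec = training$n_elec)
  L <- ao$L
  Z <- tr$Z
  G_sao <- .inferred_gamma2(result, training)       # phys L^4
  f <- 1 / (2 * (training$n_elec - 1))
  ## one-body contraction partner Q_ik = f (sum_j G[i,j,k,j] + sum_j G[j,i,j,k])
  P1 <- apply(G_sao, c(1, 3), function(m) sum(diag(m)))   # sum_j G[i,j,k,j]
  P2 <- apply(G_sao, c(2, 4), function(m) sum(diag(m)))   # sum_i G[i,j,i,l]
  Q <- f * (P1 + P2)
  ## AO-basis weights (Z symmetric, so SAO->AO uses Z itself)
  G_ao <- four_index_transform(G_sao, Z)
  Q_ao <- Z %*% Q %*% t(Z)
  ## derivative integrals
  args <- .shell_args(geometry, basis)
  oei <- cpp_oei_derivs(args)                        # (L, L, 3N)
  W4 <- 0.5 * .phys_to_chem(G_ao)
  W4 <- .symmetrize8(W4)
  g_eri <- as.numeric(cpp_eri_deriv_contract(args, as.numeric(W4)))  # 3 x nat
  ## Pulay: W_x = S^(1/2) dZ_x; contraction partners precomputed
  dZ <- sao_transform_derivative(ao$overlap, aperm(oei$dS, c(3, 1, 2)))
  Shalf <- tr$U %*% (t(tr$U) * sqrt(tr$eigenvalues))
  eri_flat1 <- matrix(sao$eri_sao, L, L^3)
  B <- vector("list", 4)
  for (m in 1:4) {
    ## bring index m first in both tensors, contract the other three
    em <- matrix(aperm(sao$eri_sao, c(m, setdiff(1:4, m))), L, L^3)
    gm <- matrix(aperm(G_sao, c(m, setdiff(1:4, m))), L, L^3)
    B[[m]] <- tcrossprod(em, gm)   # B[[m]][m'', idx] for the W contraction
  }
  h1s_Q <- sao$h1_sao %*% Q
  Q_h1s <- Q %*% sao$h1_sao
  grad <- numeric(3 * nat)
  comp_int <- numeric(3 * nat)
  comp_pulay <- numeric(3 * nat)
  for (k in seq_len(3 * nat)) {
    Wx <- Shalf %*% dZ[k, , ]
    pulay <- 0.5 * sum(vapply(B, function(Bm) sum(Wx * Bm), 0)) +
      sum(Wx * (h1s_Q + t(Q_h1s)))
    int_term <- g_eri[k] + sum(oei$dH[, , k] * Q_ao)
    comp_int[k] <- int_term
    comp_pulay[k] <- pulay
    grad[k] <- int_term + pulay
  }
  d_enuc <- .nuclear_repulsion_grad(geometry)
  grad <- grad + d_enuc
  .gradient_result(grad, nat, list(integral = comp_int, pulay = comp_pulay,
                                   nuclear = d_enuc))
}

.symmetrize8 <- function(W) {
  (W + aperm(W, c(2, 1, 3, 4)) + aperm(W, c(1, 2, 4, 3)) +
     aperm(W, c(2, 1, 4, 3)) + aperm(W, c(3, 4, 1, 2)) +
     aperm(W, c(4, 3, 1, 2)) + aperm(W, c(3, 4, 2, 1)) +
     aperm(W, c(4, 3, 2, 1))) / 8
}

.displace <- function(geom, atom, coord, step) {
  geom$coordinates[atom, coord] <- geom$coordinates[atom, coord] + step
  geom
}

.infer_energy_at <- function(training, geom, basis) {
  if (is.character(basis)) {
    b <- build_basis(geom, basis)
  } else {
    b <- build_basis(geom, attr(basis, "basis_name"))
  }
  ao <- compute_ao_integrals(geom, b)
  sao <- rotate_to_sao(ao, lowdin_transform(ao$overlap),
                       n_elec = training$n_elec)
  infer_state(training, sao)$energy
}

.gradient_result <- function(grad, nat, components) {
  fm <- -matrix(grad, 3, nat)  # coordinate-major per atom
  structure(list(forces = t(fm), gradient = grad, components = components),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("<gradient_result: max |force| = %.3e hartree/bohr>\n",
              max(abs(x$forces))))
  invisible(x)
}
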