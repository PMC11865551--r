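## Determinant-space full configuration interaction in a fixed orthonormal
## orbital space (here: the SAO basis). Dense diagonalization for small
## spaces, direct-sigma Davidson otherwise. Also transition 1-/2-RDMs and
## overlaps between CI vectors — the geometry-agnostic data the continuation
## model is built from.

.space_cache <- new.env(parent = emptyenv())

#' Determinant space for fixed orbital and electron counts
#'
#' Alpha/beta occupation strings (bitmasks, ascending) and the spin-summed
#' single-excitation tables used by the sigma build and RDM kernels.
#' Spaces are memoized per (n_orb, n_alpha, n_beta).
#'
#' @param n_orb number of spatial orbitals (<= 16)
#' @param n_alpha,n_beta electrons per spin channel
#' @return object of class `determinant_space` with `n_orb`, `n_alpha`,
#'   `n_beta`, `alpha_strings`, `beta_strings`, `dimension`
#' @export
determinant_space <- function(n_orb, n_alpha, n_beta) {
  if (n_orb > 16) stop("determinant solver supports at most 16 orbitals")
  if (n_alpha > n_orb || n_beta > n_orb || n_alpha < 0 || n_beta < 0) {
    stop("invalid electron counts for ", n_orb, " orbitals")
  }
  key <- paste(n_orb, n_alpha, n_beta, sep = ":")
  if (!is.null(.space_cache[[key]])) return(.space_cache[[key]])
  sa <- cpp_fci_strings(n_orb, n_alpha)
  sb <- cpp_fci_strings(n_orb, n_beta)
  sp <- structure(list(
    n_orb = as.integer(n_orb),
    n_alpha = as.integer(n_alpha),
    n_beta = as.integer(n_beta),
    alpha_strings = sa,
    beta_strings = sb,
    dimension = length(sa) * length(sb),
    table_alpha = cpp_exc_table(sa, n_orb),
    table_beta = cpp_exc_table(sb, n_orb)
  ), class = "determinant_space")
  .space_cache[[key]] <- sp
  sp
}

#' @export
print.determinant_space <- function(x, ...) {
  cat(sprintf("<determinant_space: %d orbitals, %d alpha + %d beta electrons, dimension %d>\n",
              x$n_orb, x$n_alpha, x$n_beta, x$dimension))
  invisible(x)
}

.same_space <- function(a, b) {
  a$n_orb == b$n_orb && a$n_alpha == b$n_alpha && a$n_beta == b$n_beta
}

## h1/eri(chem) for the sigma build from an sao_integrals object
.solver_ints <- function(sao_ints) {
  L <- sao_ints$L
  list(h1 = sao_ints$h1_sao,
       g2 = matrix(.phys_to_chem(sao_ints$eri_sao), L * L, L * L),
       L = L)
}

.sigma_fun <- function(space, h1, g2, sym = FALSE) {
  Na <- length(space$alpha_strings)
  Nb <- length(space$beta_strings)
  if (sym && space$n_alpha == space$n_beta) {
    return(function(x) cpp_fci_sigma_sym(x, Na, space$table_alpha, h1, g2,
                                         space$n_orb))
  }
  function(x) cpp_fci_sigma(x, Na, Nb, space$table_alpha, space$table_beta,
                            h1, g2, space$n_orb)
}

## determinant-transpose (alpha <-> beta exchange) of a CI vector, Na == Nb
.det_transpose <- function(x, N) as.numeric(t(matrix(x, N, N)))

## Block Davidson for the lowest n_roots eigenpairs, with thick restarts
## (the lowest Ritz vectors and their sigma images are kept when the
## subspace fills) and a fully preallocated, zero-padded subspace so that no
## large matrix subsets are copied per iteration. Deterministic start: unit
## vectors on the lowest-diagonal determinants (or supplied guesses).
.davidson <- function(sigma, hdiag, n_roots = 1L, tol = 1e-9,
                      max_iter = 300L, guess = NULL, maxsub = NULL) {
  n <- length(hdiag)
  if (is.null(maxsub)) maxsub <- max(16L, 4L * n_roots)
  maxsub <- min(n, maxsub)
  nkeep <- min(maxsub - 2L, max(4L, 2L * n_roots))
  V <- matrix(0, n, maxsub)   # orthonormal subspace (unused columns zero)
  AV <- matrix(0, n, maxsub)
  Hs <- matrix(0, maxsub, maxsub)
  nv <- 0L
  ## initial block: supplied guesses plus lowest-diagonal unit vectors
  init <- if (is.null(guess)) NULL else as.matrix(guess)
  ord <- order(hdiag)
  j_unit <- 1L
  want <- max(n_roots, if (is.null(init)) 0L else ncol(init))
  k_init <- 0L
  repeat {
    if (!is.null(init) && k_init < ncol(init)) {
      d <- init[, k_init + 1L]
      k_init <- k_init + 1L
    } else if (nv < n_roots) {
      d <- numeric(n); d[ord[j_unit]] <- 1; j_unit <- j_unit + 1L
    } else {
      break
    }
    for (rep in 1:2) d <- d - V %*% crossprod(V, d)
    nd <- sqrt(sum(d^2))
    if (nd > 1e-8) {
      nv <- nv + 1L
      V[, nv] <- d / nd
      AV[, nv] <- sigma(V[, nv])
      hc <- as.numeric(crossprod(V, AV[, nv]))
      Hs[, nv] <- hc
      Hs[nv, ] <- hc
    }
    if (nv >= want && (is.null(init) || k_init >= ncol(init))) break
  }
  res_norm <- Inf
  for (niter in seq_len(max_iter)) {
    es <- eigen(Hs[seq_len(nv), seq_len(nv), drop = FALSE], symmetric = TRUE)
    sel <- order(es$values)  # eigen() sorts decreasing
    theta <- es$values[sel[seq_len(n_roots)]]
    Yp <- matrix(0, maxsub, n_roots)
    Yp[seq_len(nv), ] <- es$vectors[, sel[seq_len(n_roots)], drop = FALSE]
    X <- V %*% Yp
    AX <- AV %*% Yp
    R <- AX - X %*% diag(theta, n_roots)
    res_norm <- max(sqrt(colSums(R^2)))
    if (res_norm < tol) {
      return(list(values = theta, vectors = X, iterations = niter))
    }
    if (nv + n_roots > maxsub) {
      ## thick restart: keep the lowest nkeep Ritz pairs; in the Ritz basis
      ## the subspace Hamiltonian is diagonal
      kk <- min(nkeep, nv)
      Ykp <- matrix(0, maxsub, kk)
      Ykp[seq_len(nv), ] <- es$vectors[, sel[seq_len(kk)], drop = FALSE]
      V[, seq_len(kk)] <- V %*% Ykp
      AV[, seq_len(kk)] <- AV %*% Ykp
      if (kk < maxsub) {
        V[, (kk + 1L):maxsub] <- 0
        AV[, (kk + 1L):maxsub] <- 0
      }
      Hs[, ] <- 0
      diag(Hs)[seq_len(kk)] <- es$values[sel[seq_len(kk)]]
      nv <- kk
    }
    appended <- FALSE
    for (k in seq_len(n_roots)) {
      denom <- hdiag - theta[k]
      denom[abs(denom) < 1e-8] <- 1e-8
      ## Olsen correction: project the update orthogonal to the Ritz vector
      ## through the preconditioner metric
      pr <- R[, k] / denom
      px <- X[, k] / denom
      lam <- sum(X[, k] * pr) / sum(X[, k] * px)
      d <- pr - lam * px
      for (rep in 1:2) d <- d - V %*% crossprod(V, d)
      nd <- sqrt(sum(d^2))
      if (nd > 1e-8) {
        nv <- nv + 1L
        V[, nv] <- d / nd
        AV[, nv] <- sigma(V[, nv])
        hc <- as.numeric(crossprod(V, AV[, nv]))
        Hs[, nv] <- hc
        Hs[nv, ] <- hc
        appended <- TRUE
      }
    }
    if (!appended) {
      if (res_norm > 1000 * tol) {
        stop("Davidson stagnated with residual ", format(res_norm),
             " above tolerance ", format(tol))
      }
      return(list(values = theta, vectors = X, iterations = niter,
                  stagnated = TRUE, residual = res_norm))
    }
  }
  stop("Davidson failed to converge after ", max_iter,
       " iterations (last residual ", format(res_norm), ")")
}

#' Ground (and low excited) states by full configuration interaction
#'
#' Diagonalizes the electronic Hamiltonian in the determinant space spanned
#' by the SAO orbitals. Spaces with dimension <= `dense_cutoff` are
#' diagonalized densely; larger spaces use a direct-sigma Davidson solver
#' with the determinant-diagonal preconditioner and a deterministic initial
#' guess (unit vector on the lowest-diagonal determinant).
#'
#' @param sao_ints an `sao_integrals` object
#' @param n_alpha,n_beta electrons per spin channel (defaults: n_elec split
#'   evenly, alpha gets the excess for odd counts)
#' @param n_roots number of lowest eigenstates to return
#' @param tol Davidson residual-norm convergence threshold
#' @param guess optional matrix of starting vectors (warm start)
#' @param dense_cutoff dimension at or below which dense diagonalization is
#'   used (default 2000)
#' @param spin_symmetric use the Ms = 0 determinant-transpose symmetry
#'   (valid for singlet ground states with `n_alpha == n_beta`); default:
#'   enabled for single-root solves in such sectors. Set FALSE to target
#'   states outside the spin-symmetric subspace (e.g. Ms = 0 triplets)
#' @return list of `ci_vector` objects (fields `space`, `amplitudes`,
#'   `energy` in hartree including nuclear repulsion)
#' @export
fci_ground_state <- function(sao_ints, n_alpha = NULL, n_beta = NULL,
                             n_roots = 1L, tol = 1e-9, guess = NULL,
                             dense_cutoff = 2000L, spin_symmetric = NULL) {
  ne <- sao_ints$n_elec
  if (is.null(n_alpha)) n_alpha <- ceiling(ne / 2)
  if (is.null(n_beta)) n_beta <- ne - n_alpha
  space <- determinant_space(sao_ints$L, n_alpha, n_beta)
  si <- .solver_ints(sao_ints)
  if (is.null(spin_symmetric)) {
    spin_symmetric <- (n_alpha == n_beta) && n_roots == 1L
  }
  if (space$dimension <= dense_cutoff) {
    H <- .dense_hamiltonian(space, si$h1, si$g2)
    es <- eigen((H + t(H)) / 2, symmetric = TRUE)
    idx <- order(es$values)[seq_len(n_roots)]  # eigen() sorts decreasing
    vals <- es$values[idx]
    vecs <- es$vectors[, idx, drop = FALSE]
  } else {
    sym <- spin_symmetric && n_alpha == n_beta
    sg <- .sigma_fun(space, si$h1, si$g2, sym = sym)
    hd <- cpp_fci_hdiag(space$alpha_strings, space$beta_strings, si$h1, si$g2,
                        space$n_orb)
    if (sym && !is.null(guess)) {
      guess <- as.matrix(guess)
      N <- length(space$alpha_strings)
      guess <- apply(guess, 2, function(v) (v + .det_transpose(v, N)) / 2)
      if (max(abs(guess)) < 1e-12) guess <- NULL  # guess was antisymmetric
    }
    sol <- .davidson(sg, hd, n_roots = n_roots, tol = tol, guess = guess)
    vals <- sol$values
    vecs <- sol$vectors
  }
  lapply(seq_len(n_roots), function(k) {
    v <- vecs[, k]
    v <- v / sqrt(sum(v^2))
    structure(list(space = space, amplitudes = v,
                   energy = vals[k] + sao_ints$e_nuc),
              class = "ci_vector")
  })
}

## Dense Hamiltonian via sigma applied to unit vectors (only used for small
## dimensions).
.dense_hamiltonian <- function(space, h1, g2) {
  n <- space$dimension
  sg <- .sigma_fun(space, h1, g2)
  H <- matrix(0, n, n)
  e <- numeric(n)
  for (j in seq_len(n)) {
    e[] <- 0; e[j] <- 1
    H[, j] <- sg(e)
  }
  H
}

#' @export
print.ci_vector <- function(x, ...) {
  cat(sprintf("<ci_vector: dimension %d, energy %s hartree>\n",
              x$space$dimension,
              if (is.null(x$energy)) "NA" else sprintf("%.10f", x$energy)))
  invisible(x)
}

#' Transition reduced density matrices between two CI vectors
#'
#' Spin-summed transition 1- and 2-RDMs and the overlap:
#' `gamma1[i,j] = <a| sum_s c_is^+ c_js |b>`,
#' `gamma2[i,j,k,l] = <a| sum_st c_is^+ c_jt^+ c_lt c_ks |b>` (note the k,l
#' operator order), `overlap = <a|b>`. Contracting `gamma2` with the K
#' tensor of the bra/ket Hamiltonian plus `overlap * e_nuc` reproduces
#' `<a|H|b>`.
#'
#' @param bra,ket `ci_vector` objects over the same determinant space
#' @return object of class `transition_rdms` with `gamma1` (L x L),
#'   `gamma2` (L^4), `overlap`
#' @export
transition_rdms <- function(bra, ket) {
  if (!.same_space(bra$space, ket$space)) {
    stop("bra and ket live in different determinant spaces")
  }
  sp <- bra$space
  out <- cpp_trans_rdm(bra$amplitudes, ket$amplitudes, sp$table_alpha,
                       sp$table_beta, length(sp$alpha_strings),
                       length(sp$beta_strings), sp$n_orb)
  structure(out, class = "transition_rdms")
}

#' Overlap between two CI vectors
#' @param bra,ket `ci_vector` objects over the same determinant space
#' @return `sum_n C_n^(a) C_n^(b)`
#' @export
ci_overlap <- function(bra, ket) {
  if (!.same_space(bra$space, ket$space)) {
    stop("bra and ket live in different determinant spaces")
  }
  sum(bra$amplitudes * ket$amplitudes)
}

#' Total spin expectation value of a CI vector
#' @param ci a `ci_vector`
#' @return `<S^2>` in units of hbar^2
#' @export
s_squared <- function(ci) {
  sp <- ci$space
  cpp_s2(ci$amplitudes, sp$alpha_strings, sp$beta_strings, sp$n_orb)
}

#' Slater determinant expanded in the determinant basis
#'
#' Expresses a single Slater determinant with occupied orbitals given as
#' columns of `mo_alpha`/`mo_beta` (coefficients in the solver's orthonormal
#' orbital basis) as a CI amplitude vector: the amplitude on a determinant
#' is the product of the corresponding minors (determinants of the occupied
#' sub-matrices). Used to seed Davidson with the Hartree-Fock state, which
#' in a localized basis spreads over many determinants.
#'
#' @param space a [determinant_space()]
#' @param mo_alpha L x n_alpha orbital coefficient matrix
#' @param mo_beta L x n_beta matrix (default: same as alpha)
#' @return normalized amplitude vector of length `space$dimension`
#' @export
determinant_amplitudes <- function(space, mo_alpha, mo_beta = mo_alpha) {
  orbs_of <- function(s) which(bitwAnd(s, bitwShiftL(1L, 0:(space$n_orb - 1))) != 0)
  minors <- function(strings, M) {
    vapply(strings, function(s) det(M[orbs_of(s), , drop = FALSE]), 0)
  }
  ma <- minors(space$alpha_strings, mo_alpha)
  mb <- if (space$n_beta == space$n_alpha && identical(mo_beta, mo_alpha)) {
    ma
  } else {
    minors(space$beta_strings, mo_beta)
  }
  v <- as.numeric(outer(mb, ma))  # beta fastest
  v / sqrt(sum(v^2))
}

#' Hartree-Fock determinant as a Davidson starting vector
#'
#' Runs RHF on the AO integrals and expands the resulting determinant in the
#' SAO determinant basis via [determinant_amplitudes()].
#'
#' @param ao `ao_integrals` (with geometry attached)
#' @param transform the `sao_transform` of the same geometry
#' @param space the target [determinant_space()]
#' @return amplitude vector, or NULL if the SCF fails
#' @export
hf_determinant_guess <- function(ao, transform, space) {
  hf <- tryCatch(suppressWarnings(scf_rhf(ao)), error = function(e) NULL)
  if (is.null(hf)) return(NULL)
  nocc <- max(space$n_alpha, space$n_beta)
  ## MO coefficients re-expressed in the SAO basis: M = Z^{-1} C = S^{1/2} C
  Shalf <- transform$U %*% (t(transform$U) * sqrt(transform$eigenvalues))
  M <- Shalf %*% hf$mo_coeff[, seq_len(nocc), drop = FALSE]
  determinant_amplitudes(space,
                         M[, seq_len(space$n_alpha), drop = FALSE],
                         M[, seq_len(space$n_beta), drop = FALSE])
}

#' Release the FCI workspace buffers
#'
#' The sigma build and RDM kernels keep large scratch tensors alive between
#' calls (reusing faulted pages is much cheaper than reallocating them).
#' Call this after a large-system study to return the memory.
#' @export
release_fci_workspace <- function() {
  cpp_fci_release_workspace()
  invisible(NULL)
}

#' Electronic energy from a 2-RDM contraction with K
#'
#' `sum_ijkl K_ijkl Gamma_ijkl + overlap * e_nuc` — the identity the whole
#' continuation scheme rests on.
#' @param rdms a `transition_rdms`
#' @param sao_ints an `sao_integrals` with a K tensor
#' @return matrix element `<a|H|b>` in hartree
#' @export
contract_energy <- function(rdms, sao_ints) {
  if (is.null(sao_ints$k_tensor)) stop("sao_integrals carry no K tensor")
  sum(sao_ints$k_tensor * rdms$gamma2) + rdms$overlap * sao_ints$e_nuc
}
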