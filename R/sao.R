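## Loewdin symmetric orthogonalization. The SAO basis Z = S^(-1/2) is the
## orthonormal basis closest (in the least-squares sense) to the atomic
## orbitals; training wave-function amplitudes expressed in it transfer
## between geometries. Also: rotation of integrals into the SAO basis,
## the reduced two-body Hamiltonian K that folds the one-body terms into a
## single 2-RDM contraction, and the nuclear derivative of S^(-1/2)
## (the Pulay contribution to forces).

#' Loewdin symmetric orthogonalization transform
#'
#' Computes Z = S^(-1/2) from the eigendecomposition of the AO overlap.
#' Z is symmetric and satisfies t(Z) S Z = I; its columns define the SAO
#' basis, ordered exactly as the AO basis (atom-major).
#'
#' @param overlap symmetric positive-definite L x L overlap matrix
#' @return object of class `sao_transform`: list with `Z` (L x L),
#'   `eigenvalues` of S, and `U` (eigenvectors, kept for the derivative)
#' @export
lowdin_transform <- function(overlap) {
  overlap <- (overlap + t(overlap)) / 2
  e <- eigen(overlap, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    stop("overlap matrix is numerically linearly dependent: smallest ",
         "eigenvalue ", format(min(e$values)))
  }
  Z <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  structure(list(Z = (Z + t(Z)) / 2, eigenvalues = e$values, U = e$vectors),
            class = "sao_transform")
}

#' @export
print.sao_transform <- function(x, ...) {
  cat(sprintf("<sao_transform: L = %d, min overlap eigenvalue %.3e>\n",
              nrow(x$Z), min(x$eigenvalues)))
  invisible(x)
}

#' Four-index transform of a two-electron tensor
#'
#' `out[i',j',k',l'] = sum Z[i,i'] Z[j,j'] Z[k,k'] Z[l,l'] t[i,j,k,l]` via
#' four mode products (dgemm + cyclic permutation); works for any square
#' transformation matrix, physicists' index order.
#' @param tensor L^4 array
#' @param Z L x L transformation matrix
#' @return transformed L^4 array
#' @export
four_index_transform <- function(tensor, Z) {
  L <- nrow(Z)
  t1 <- tensor
  for (m in 1:4) {
    t1 <- array(crossprod(Z, matrix(t1, L, L^3)), c(L, L, L, L))
    t1 <- aperm(t1, c(2, 3, 4, 1))
  }
  t1
}

#' Build the reduced two-body Hamiltonian K
#'
#' K folds the one-electron integrals into the two-electron tensor so that
#' the electronic energy is a single contraction with the spin-summed 2-RDM:
#' K_ijkl = <ij|kl>/2 + (d_jl h_ik + d_ik h_jl) / (2 (N_elec - 1)).
#'
#' @param h1 one-electron matrix (L x L)
#' @param eri two-electron tensor, physicists' notation (L^4)
#' @param n_elec electron count (must be >= 2)
#' @return L^4 array with the symmetry K_ijkl = K_jilk
#' @export
k_tensor <- function(h1, eri, n_elec) {
  if (n_elec < 2) {
    stop("reduced two-body Hamiltonian K is undefined for n_elec < 2 ",
         "(division by N_elec - 1); use the h1/eri form instead")
  }
  L <- nrow(h1)
  Imat <- diag(L)
  f <- 1 / (2 * (n_elec - 1))
  # [i,j,k,l] <- h[i,k] d[j,l]  and  d[i,k] h[j,l]
  t1 <- aperm(array(outer(h1, Imat), c(L, L, L, L)), c(1, 3, 2, 4))
  t2 <- aperm(array(outer(Imat, h1), c(L, L, L, L)), c(1, 3, 2, 4))
  0.5 * eri + f * (t1 + t2)
}

#' Rotate AO integrals into the SAO basis
#'
#' Produces the SAO-basis one- and two-electron integrals and (for two or
#' more electrons) the reduced two-body Hamiltonian K of [k_tensor()].
#'
#' @param ao an `ao_integrals` object
#' @param transform a `sao_transform` for the same geometry
#' @param n_elec electron count; defaults to the electron count of the
#'   geometry the integrals were built from
#' @param with_k build the K tensor (requires `n_elec >= 2`)
#' @return object of class `sao_integrals`: `h1_sao`, `eri_sao` (physicists'),
#'   `k_tensor` (or NULL when `with_k = FALSE`), `e_nuc`, `n_elec`, `L`
#' @export
rotate_to_sao <- function(ao, transform, n_elec = NULL, with_k = TRUE) {
  Z <- transform$Z
  if (nrow(Z) != ao$L) stop("dimension mismatch between integrals and transform")
  if (is.null(n_elec)) {
    geom <- attr(ao, "geometry")
    if (is.null(geom)) stop("n_elec not given and integrals carry no geometry")
    n_elec <- geom$n_elec
  }
  h1 <- crossprod(Z, ao$core_h %*% Z)
  eri <- four_index_transform(ao$eri, Z)
  structure(list(
    h1_sao = (h1 + t(h1)) / 2,
    eri_sao = eri,
    k_tensor = if (with_k) k_tensor((h1 + t(h1)) / 2, eri, n_elec) else NULL,
    e_nuc = ao$e_nuc,
    n_elec = as.integer(n_elec),
    L = ao$L
  ), class = "sao_integrals",
  geometry = attr(ao, "geometry"), basis_name = attr(ao, "basis_name"))
}

#' @export
print.sao_integrals <- function(x, ...) {
  cat(sprintf("<sao_integrals: L = %d, n_elec = %d>\n", x$L, x$n_elec))
  invisible(x)
}

#' Nuclear derivative of the Loewdin transform
#'
#' d(S^(-1/2)) from first-order perturbation theory in the eigenbasis of S:
#' with S = U diag(lambda) U', the derivative in the eigenbasis is the
#' divided difference (lambda_p^(-1/2) - lambda_q^(-1/2)) / (lambda_p -
#' lambda_q) applied elementwise to U' dS U (finite limit -lambda^(-3/2)/2 at
#' degeneracies), equivalent to solving the Sylvester relation
#' S^(1/2) X + X S^(1/2) = -S^(-1/2) dS S^(-1/2).
#'
#' @param overlap L x L SPD overlap matrix
#' @param d_overlap array (3N x L x L) of overlap derivatives, or a single
#'   L x L matrix
#' @return same shape as `d_overlap`: derivative(s) of S^(-1/2)
#' @export
sao_transform_derivative <- function(overlap, d_overlap) {
  tr <- lowdin_transform(overlap)
  U <- tr$U
  lam <- tr$eigenvalues
  sq <- sqrt(lam)
  ## divided-difference kernel, stable at (near-)degeneracy:
  ## (a^-1/2 - b^-1/2)/(a - b) = -1 / (sqrt(a) sqrt(b) (sqrt(a)+sqrt(b)))
  phi <- -1 / (outer(sq, sq) * outer(sq, sq, "+"))
  one <- function(dS) {
    M <- crossprod(U, dS %*% U) * phi
    U %*% M %*% t(U)
  }
  if (is.matrix(d_overlap)) return(one(d_overlap))
  out <- d_overlap
  for (k in seq_len(dim(d_overlap)[1])) out[k, , ] <- one(d_overlap[k, , ])
  out
}
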