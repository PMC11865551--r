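## Restricted Hartree-Fock. Used as the mean-field comparison method for the
## distorted-chain error study and as a convenience starting point; the
## correlated machinery never depends on it.

#' Restricted closed-shell Hartree-Fock
#'
#' Plain SCF with DIIS acceleration on the AO-basis Fock matrix.
#'
#' @param ao an `ao_integrals` object (even electron count)
#' @param max_iter maximum SCF iterations
#' @param conv density RMS convergence threshold
#' @return list with `energy` (hartree, incl. nuclear repulsion),
#'   `mo_coeff`, `mo_energy`, `density` (AO spin-summed), `converged`
#' @export
scf_rhf <- function(ao, max_iter = 100L, conv = 1e-10) {
  geom <- attr(ao, "geometry")
  n_elec <- geom$n_elec
  if (n_elec %% 2 != 0) stop("scf_rhf requires an even electron count")
  nocc <- n_elec / 2
  L <- ao$L
  X <- lowdin_transform(ao$overlap)$Z
  eri_chem <- matrix(.phys_to_chem(ao$eri), L * L, L * L)
  S <- ao$overlap
  H <- ao$core_h
  eri4 <- .phys_to_chem(ao$eri)  # chemists 4D, for the exchange term
  fock_build <- function(D) {
    J <- matrix(eri_chem %*% as.numeric(D), L, L)
    K <- apply_exchange(eri4, D)
    H + J - 0.5 * K
  }
  ## initial guess: core Hamiltonian
  Fm <- H
  D <- NULL
  energy <- Inf
  err_list <- list(); fock_list <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Fo <- crossprod(X, Fm %*% X)
    es <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    C <- X %*% es$vectors[, order(es$values), drop = FALSE]
    eps <- sort(es$values)
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    Dnew <- 2 * tcrossprod(Cocc)
    Fm <- fock_build(Dnew)
    e_new <- 0.5 * sum(Dnew * (H + Fm)) + ao$e_nuc
    ## DIIS
    err <- Fm %*% Dnew %*% S - S %*% Dnew %*% Fm
    err_list <- c(err_list, list(err)); fock_list <- c(fock_list, list(Fm))
    if (length(err_list) > 8) { err_list <- err_list[-1]; fock_list <- fock_list[-1] }
    m <- length(err_list)
    if (m >= 2) {
      B <- matrix(-1, m + 1, m + 1); B[m + 1, m + 1] <- 0
      for (i in seq_len(m)) for (j in seq_len(m))
        B[i, j] <- sum(err_list[[i]] * err_list[[j]])
      rhs <- c(numeric(m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf)) {
        Fm <- Reduce(`+`, Map(`*`, fock_list, cf))
      }
    }
    if (!is.null(D) && sqrt(mean((Dnew - D)^2)) < conv &&
        abs(e_new - energy) < conv * 10) {
      converged <- TRUE
      D <- Dnew; energy <- e_new
      break
    }
    D <- Dnew; energy <- e_new
  }
  if (!converged) warning("SCF did not reach the requested convergence")
  list(energy = energy, mo_coeff = C, mo_energy = eps, density = D,
       converged = converged)
}

## K_pq = sum_rs (pr|sq)_chem D_rs, via one reshape-multiply
apply_exchange <- function(eri_chem4, D) {
  L <- dim(eri_chem4)[1]
  m <- aperm(eri_chem4, c(1, 3, 4, 2))  # m[p,q,r,s] = (pr|sq)
  matrix(matrix(m, L * L, L * L) %*% as.numeric(D), L, L)
}
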