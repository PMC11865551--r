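## AO integral evaluation over the built-in s/p Gaussian engine (or a
## registered external backend), plus nuclear-coordinate derivatives.
## ERI tensors are exposed in physicists' notation <ij|kl>; the engine works
## in chemists' notation internally and the boundary transposition happens
## here, once.

.chem_to_phys <- function(eri) aperm(eri, c(1, 3, 2, 4))
.phys_to_chem <- .chem_to_phys  # the transposition is its own inverse

.nuclear_repulsion <- function(geom) {
  n <- n_atoms(geom)
  if (n < 2) return(0)
  e <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      r <- sqrt(sum((geom$coordinates[a, ] - geom$coordinates[b, ])^2))
      e <- e + geom$atomic_numbers[a] * geom$atomic_numbers[b] / r
    }
  }
  e
}

.nuclear_repulsion_grad <- function(geom) {
  n <- n_atoms(geom)
  g <- matrix(0, n, 3)
  if (n < 2) return(as.numeric(t(g)))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d <- geom$coordinates[a, ] - geom$coordinates[b, ]
      r <- sqrt(sum(d^2))
      f <- -geom$atomic_numbers[a] * geom$atomic_numbers[b] / r^3 * d
      g[a, ] <- g[a, ] + f
      g[b, ] <- g[b, ] - f
    }
  }
  as.numeric(t(g))  # length 3N, coordinate-major per atom
}

#' Compute AO integrals at a geometry
#'
#' Overlap, core Hamiltonian (kinetic + nuclear attraction), two-electron
#' repulsion integrals in physicists' notation `<ij|kl>`, and the classical
#' nuclear repulsion energy, all in hartree/bohr atomic units.
#'
#' @param geom a [geometry()]
#' @param basis a `basis_set` from [build_basis()], or a basis name (built
#'   on the fly)
#' @param backend optional name of a registered external integral backend;
#'   when given, `basis` must be the basis name understood by that backend
#' @return an object of class `ao_integrals` with fields `overlap`, `core_h`
#'   (L x L), `eri` (L^4, physicists' notation), `e_nuc`, `L`; the geometry
#'   and basis are attached as attributes
#' @export
compute_ao_integrals <- function(geom, basis, backend = NULL) {
  if (!is.null(backend)) {
    fn <- get_integral_backend(backend)
    out <- fn(geom, basis)
    class(out) <- "ao_integrals"
    return(out)
  }
  if (is.character(basis)) basis <- build_basis(geom, basis)
  args <- .shell_args(geom, basis)
  core <- cpp_ao_core(args)
  L <- basis_size(basis)
  eri <- .chem_to_phys(cpp_eri(args))
  S <- (core$S + t(core$S)) / 2
  cond <- kappa(S, exact = TRUE)
  if (cond > 1e12) {
    warning("AO overlap matrix is near-singular (condition number ",
            format(cond, digits = 3), ")")
  }
  structure(list(
    overlap = S,
    core_h = (core$T + core$V + t(core$T + core$V)) / 2,
    eri = eri,
    e_nuc = .nuclear_repulsion(geom),
    L = L
  ), class = "ao_integrals",
  geometry = geom, basis = basis, basis_name = attr(basis, "basis_name"))
}

#' @export
print.ao_integrals <- function(x, ...) {
  cat(sprintf("<ao_integrals: L = %d, E_nuc = %.8f hartree>\n", x$L, x$e_nuc))
  invisible(x)
}

#' Electric-dipole integrals
#'
#' `<phi_a | r_c - origin_c | phi_b>` for c in x, y, z.
#'
#' @param geom a [geometry()]
#' @param basis a `basis_set` or basis name
#' @param origin length-3 reference point in bohr (default the origin)
#' @return numeric array of dimension 3 x L x L
#' @export
compute_dipole_integrals <- function(geom, basis, origin = c(0, 0, 0)) {
  if (is.character(basis)) basis <- build_basis(geom, basis)
  D <- cpp_dipole(.shell_args(geom, basis), as.numeric(origin))
  aperm(D, c(3, 1, 2))
}

#' Nuclear-coordinate derivatives of the AO integrals
#'
#' Analytic mode differentiates the Gaussians via the exponent-ladder
#' relation (built-in s/p shells); finite-difference mode applies central
#' differences to [compute_ao_integrals()] and works with any backend.
#'
#' @param geom a [geometry()]
#' @param basis a `basis_set` or basis name
#' @param mode "analytic" or "finite_difference"
#' @param fd_step central-difference step in bohr (default 1e-5)
#' @return list with `d_overlap`, `d_core_h` (arrays 3N x L x L), `d_eri`
#'   (array L x L x L x L x 3N, physicists' notation), `d_e_nuc` (length 3N);
#'   coordinate index runs x,y,z per atom in atom order
#' @export
compute_integral_derivatives <- function(geom, basis,
                                         mode = c("analytic", "finite_difference"),
                                         fd_step = 1e-5) {
  mode <- match.arg(mode)
  if (is.character(basis)) basis <- build_basis(geom, basis)
  L <- basis_size(basis)
  nat <- n_atoms(geom)
  if (mode == "analytic") {
    oei <- cpp_oei_derivs(.shell_args(geom, basis))
    d_eri <- cpp_eri_derivs(.shell_args(geom, basis))
    d_eri <- array(aperm(array(d_eri, c(L, L, L, L, 3 * nat)),
                         c(1, 3, 2, 4, 5)), c(L, L, L, L, 3 * nat))
    return(list(
      d_overlap = aperm(oei$dS, c(3, 1, 2)),
      d_core_h = aperm(oei$dH, c(3, 1, 2)),
      d_eri = d_eri,
      d_e_nuc = .nuclear_repulsion_grad(geom)
    ))
  }
  if (fd_step <= 0) stop("fd_step must be positive")
  dS <- array(0, c(3 * nat, L, L))
  dH <- array(0, c(3 * nat, L, L))
  dE <- array(0, c(L, L, L, L, 3 * nat))
  dEn <- numeric(3 * nat)
  for (a in seq_len(nat)) {
    for (c in 1:3) {
      k <- 3 * (a - 1) + c
      gp <- geom; gp$coordinates[a, c] <- gp$coordinates[a, c] + fd_step
      gm <- geom; gm$coordinates[a, c] <- gm$coordinates[a, c] - fd_step
      bp <- build_basis(gp, attr(basis, "basis_name"))
      bm <- build_basis(gm, attr(basis, "basis_name"))
      ip <- compute_ao_integrals(gp, bp)
      im <- compute_ao_integrals(gm, bm)
      dS[k, , ] <- (ip$overlap - im$overlap) / (2 * fd_step)
      dH[k, , ] <- (ip$core_h - im$core_h) / (2 * fd_step)
      dE[, , , , k] <- (ip$eri - im$eri) / (2 * fd_step)
      dEn[k] <- (ip$e_nuc - im$e_nuc) / (2 * fd_step)
    }
  }
  list(d_overlap = dS, d_core_h = dH, d_eri = dE, d_e_nuc = dEn)
}
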