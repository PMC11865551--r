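# Independent oracles used across the suite.
#
# 1. Closed-form s-type Gaussian integrals (overlap, kinetic, nuclear
#    attraction, ERI) with the Boys function evaluated through erf/quadrature
#    — none of the engine's Hermite recurrences are reused. p-type integrals
#    are obtained from these by central finite differences over the centers
#    (a p function is the derivative of an s function with respect to its
#    center, up to 1/(2a)).
# 2. A Jordan-Wigner/Kronecker construction of the many-body Hamiltonian in
#    the full Fock space, for brute-force FCI checks at tiny L.

# Boys F_0 in closed form
boys0 <- function(x) ifelse(x < 1e-12, 1 - x / 3, 0.5 * sqrt(pi / x) * erf_(sqrt(x)))
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# primitive s-Gaussian closed forms (unnormalized: exp(-a|r-A|^2))
s_overlap <- function(a, b, A, B) {
  p <- a + b
  (pi / p)^1.5 * exp(-a * b / p * sum((A - B)^2))
}
s_kinetic <- function(a, b, A, B) {
  p <- a + b; mu <- a * b / p; R2 <- sum((A - B)^2)
  mu * (3 - 2 * mu * R2) * s_overlap(a, b, A, B)
}
s_nuclear <- function(a, b, A, B, C) {
  # <a| 1/|r-C| |b> (positive; caller applies -Z)
  p <- a + b
  P <- (a * A + b * B) / p
  2 * pi / p * exp(-a * b / p * sum((A - B)^2)) * boys0(p * sum((P - C)^2))
}
s_eri <- function(a, b, c, d, A, B, C, D) {
  # chemists (ab|cd) for s primitives
  p <- a + b; q <- c + d
  P <- (a * A + b * B) / p; Q <- (c * C + d * D) / q
  K1 <- exp(-a * b / p * sum((A - B)^2))
  K2 <- exp(-c * d / q * sum((C - D)^2))
  2 * pi^2.5 / (p * q * sqrt(p + q)) * K1 * K2 *
    boys0(p * q / (p + q) * sum((P - Q)^2))
}

# contracted s-shell integrals from the closed forms, using raw basis data
contracted_s <- function(fn, sh1, sh2, ...) {
  acc <- 0
  for (i in seq_along(sh1$a)) {
    for (j in seq_along(sh2$a)) {
      acc <- acc + sh1$c[i] * sh2$c[j] * fn(sh1$a[i], sh2$a[j], ...)
    }
  }
  acc
}

# normalized primitive coefficients for an s shell
s_shell <- function(exponents, coeffs) {
  cc <- coeffs * (2 * exponents / pi)^0.75
  sh <- list(a = exponents, c = cc)
  n <- contracted_s(function(a, b, A, B) s_overlap(a, b, A, B), sh, sh,
                    c(0, 0, 0), c(0, 0, 0))
  sh$c <- sh$c / sqrt(n)
  sh
}

sto3g_h <- function() s_shell(c(3.42525091, 0.62391373, 0.16885540),
                              c(0.15432897, 0.53532814, 0.44463454))

# ---- Jordan-Wigner Fock-space Hamiltonian oracle (tiny L only) -------------
# Spin-orbital ordering: (1a, 2a, ..., La, 1b, ..., Lb).
jw_operators <- function(n_modes) {
  a1 <- matrix(c(0, 1, 0, 0), 2, 2)  # annihilation: a|1> = |0>
  I2 <- diag(2)
  sz <- diag(c(1, -1))
  ann <- lapply(seq_len(n_modes), function(k) {
    ops <- lapply(seq_len(n_modes), function(m) {
      if (m < k) sz else if (m == k) a1 else I2
    })
    Reduce(kronecker, ops)
  })
  list(a = ann, ad = lapply(ann, t))
}

# Full Fock-space Hamiltonian from h1 and physicists' eri (spatial orbitals)
jw_hamiltonian <- function(h1, eri_phys) {
  L <- nrow(h1)
  ops <- jw_operators(2 * L)
  mode <- function(p, s) if (s == 1) p else L + p
  dim <- 2^(2 * L)
  H <- matrix(0, dim, dim)
  for (p in 1:L) for (q in 1:L) {
    if (abs(h1[p, q]) < 1e-300) next
    for (s in 1:2) {
      H <- H + h1[p, q] * ops$ad[[mode(p, s)]] %*% ops$a[[mode(q, s)]]
    }
  }
  for (i in 1:L) for (j in 1:L) for (k in 1:L) for (l in 1:L) {
    v <- eri_phys[i, j, k, l]
    if (abs(v) < 1e-14) next
    for (s in 1:2) for (t in 1:2) {
      H <- H + 0.5 * v * ops$ad[[mode(i, s)]] %*% ops$ad[[mode(j, t)]] %*%
        ops$a[[mode(l, t)]] %*% ops$a[[mode(k, s)]]
    }
  }
  H
}

# Ground energy of the (n_alpha, n_beta) sector of the JW Hamiltonian
jw_ground_energy <- function(h1, eri_phys, n_alpha, n_beta, e_nuc = 0) {
  L <- nrow(h1)
  H <- jw_hamiltonian(h1, eri_phys)
  occ_bits <- function(state) as.integer(intToBits(state - 1L))[seq_len(2 * L)]
  sel <- which(vapply(seq_len(2^(2 * L)), function(s) {
    b <- occ_bits(s)
    sum(b[1:L]) == n_alpha && sum(b[(L + 1):(2 * L)]) == n_beta
  }, TRUE))
  min(eigen((H[sel, sel] + t(H[sel, sel])) / 2, symmetric = TRUE)$values) + e_nuc
}

# ---- small conveniences ----------------------------------------------------
h_chain <- function(n, spacing) symmetric_stretch_series(n, spacing)[[1]]

solve_sao <- function(geom, basis_name) {
  ao <- compute_ao_integrals(geom, basis_name)
  rotate_to_sao(ao, lowdin_transform(ao$overlap))
}

fci_energy <- function(geom, basis_name, ...) {
  fci_ground_state(solve_sao(geom, basis_name), ...)[[1]]$energy
}

random_spd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) / n + diag(n)
}
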