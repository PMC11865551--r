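# The built-in Gaussian engine checked against independent closed-form
# s-type formulas (Boys function via erf), finite-difference ladders for
# p functions, and physical invariances.

test_that("basis registry builds the documented shell structures", {
  h2 <- h_chain(2, 1.4)
  b <- build_basis(h2, "STO-3G")
  expect_length(b, 2L)
  expect_equal(basis_size(b), 2L)
  expect_equal(basis_size(build_basis(h_chain(10, 1.79), "sto-6g")), 10L)
  expect_equal(basis_size(build_basis(water_geometry(), "6-31g")), 13L)
  expect_error(build_basis(h2, "cc-pvdz"), "unknown basis")
  ## every contracted function has unit self-overlap
  ao <- compute_ao_integrals(water_geometry(), "6-31g")
  expect_lt(max(abs(diag(ao$overlap) - 1)), 1e-12)
})

test_that("H2/STO-3G integrals match the closed-form s-type oracle", {
  g <- h_chain(2, 1.4)
  ao <- compute_ao_integrals(g, "sto-3g")
  expect_equal(ao$e_nuc, 1 / 1.4, tolerance = 1e-14)
  sh <- sto3g_h()
  A <- c(0, 0, 0); B <- c(1.4, 0, 0)
  S12 <- contracted_s(s_overlap, sh, sh, A, B)
  T11 <- contracted_s(s_kinetic, sh, sh, A, A)
  T12 <- contracted_s(s_kinetic, sh, sh, A, B)
  V11 <- -contracted_s(function(a, b, Aa, Bb) {
    s_nuclear(a, b, Aa, Bb, A) + s_nuclear(a, b, Aa, Bb, B)
  }, sh, sh, A, A)
  V12 <- -contracted_s(function(a, b, Aa, Bb) {
    s_nuclear(a, b, Aa, Bb, A) + s_nuclear(a, b, Aa, Bb, B)
  }, sh, sh, A, B)
  expect_equal(ao$overlap[1, 2], S12, tolerance = 1e-10)
  expect_equal(ao$core_h[1, 1], T11 + V11, tolerance = 1e-8)
  expect_equal(ao$core_h[1, 2], T12 + V12, tolerance = 1e-8)
  ## ERI oracle: physicists <ij|kl> = chemists (ik|jl)
  eri_or <- function(i, j, k, l) {
    cents <- list(A, B)
    acc <- 0
    for (w in seq_along(sh$a)) for (x in seq_along(sh$a))
      for (y in seq_along(sh$a)) for (z in seq_along(sh$a)) {
        acc <- acc + sh$c[w] * sh$c[x] * sh$c[y] * sh$c[z] *
          s_eri(sh$a[w], sh$a[x], sh$a[y], sh$a[z],
                cents[[i]], cents[[k]], cents[[j]], cents[[l]])
      }
    acc
  }
  for (idx in list(c(1, 1, 1, 1), c(1, 2, 1, 2), c(1, 1, 2, 2), c(1, 2, 2, 1))) {
    expect_equal(ao$eri[idx[1], idx[2], idx[3], idx[4]],
                 eri_or(idx[1], idx[2], idx[3], idx[4]), tolerance = 1e-10)
  }
})

test_that("p-function integrals agree with center-derivatives of s integrals", {
  ## a single p function is (1/2a) d/dA of the s function with the same
  ## exponent; compare one-electron integrals on a two-atom O-H fragment
  ## against central finite differences of an s-only surrogate system
  a_p <- 1.1; a_s <- 0.6
  A <- c(0.1, -0.2, 0.3); B <- c(1.2, 0.4, -0.3)
  ## surrogate shells: one primitive each
  ps <- function(shift) {
    s_overlap(a_p, a_s, A + shift, B)
  }
  h <- 1e-5
  np <- (2 * a_p / pi)^0.75 * 2 * sqrt(a_p)   # p-primitive norm
  ns <- (2 * a_s / pi)^0.75
  ## d/dAx of the unnormalized s gives 2a * (x-Ax)-type p function
  fd <- (ps(c(h, 0, 0)) - ps(c(-h, 0, 0))) / (2 * h) / (2 * a_p)
  ## build the same overlap through the engine: one p shell + one s shell
  g <- geometry(c(1L, 1L), rbind(A, B))
  basis <- structure(list(
    list(center_atom = 1L, angular_momentum = 1L, exponents = a_p,
         contraction_coeffs = 1, scale = 1),
    list(center_atom = 2L, angular_momentum = 0L, exponents = a_s,
         contraction_coeffs = 1, scale = 1)
  ), class = "basis_set", basis_name = "custom", L = 4L,
  offsets = c(0L, 3L), fn_atom = c(1L, 1L, 1L, 2L))
  ao <- compute_ao_integrals(g, basis)
  expect_equal(ao$overlap[1, 4], fd * np * ns, tolerance = 1e-8)
})

test_that("ERI permutation symmetry holds on random H4 geometries", {
  base <- h_chain(4, 1.6)
  for (g in random_distortion_set(base, 0.35, 2, seed = 3)) {
    eri <- compute_ao_integrals(g, "sto-3g")$eri
    expect_lt(max(abs(eri - aperm(eri, c(2, 1, 4, 3)))), 1e-12)  # <ji|lk>
    expect_lt(max(abs(eri - aperm(eri, c(3, 4, 1, 2)))), 1e-12)  # <kl|ij>
    expect_lt(max(abs(eri - aperm(eri, c(1, 4, 3, 2)))), 1e-12)  # <il|kj>
  }
})

test_that("integrals are invariant under rigid translation", {
  g <- water_geometry()
  ao <- compute_ao_integrals(g, "sto-3g")
  gt <- translate_geometry(g, c(1.3, -0.7, 2.1))
  aot <- compute_ao_integrals(gt, "sto-3g")
  expect_lt(max(abs(ao$overlap - aot$overlap)), 1e-10)
  expect_lt(max(abs(ao$core_h - aot$core_h)), 1e-10)
  expect_lt(max(abs(ao$eri - aot$eri)), 1e-10)
  expect_equal(ao$e_nuc, aot$e_nuc, tolerance = 1e-12)
})

test_that("dipole integrals: parity, origin shift, oracle", {
  g <- geometry(1L, matrix(0, 1, 3))
  b <- build_basis(g, "sto-3g")
  d0 <- compute_dipole_integrals(g, b, origin = c(0, 0, 0))
  expect_lt(max(abs(d0)), 1e-12)  # odd integrand about the center
  ## shifting the origin by d changes the tensor by -d * S
  g2 <- h_chain(2, 1.4)
  b2 <- build_basis(g2, "sto-3g")
  ao2 <- compute_ao_integrals(g2, b2)
  dA <- compute_dipole_integrals(g2, b2, origin = c(0, 0, 0))
  dB <- compute_dipole_integrals(g2, b2, origin = c(0.5, -0.25, 1))
  for (c in 1:3) {
    shift <- c(0.5, -0.25, 1)[c]
    expect_lt(max(abs(dB[c, , ] - (dA[c, , ] - shift * ao2$overlap))), 1e-10)
  }
  ## x-moment between the two s functions: d/dB ladder oracle
  sh <- sto3g_h()
  A <- c(0, 0, 0); B <- c(1.4, 0, 0)
  h <- 1e-5
  ## <a| x |b> = x-weighted overlap; via (x - Bx) + Bx decomposition and the
  ## derivative identity <a|(x-Bx)|b_prim> = dS/dBx / (2b)
  num <- 0
  for (i in seq_along(sh$a)) for (j in seq_along(sh$a)) {
    ds <- (s_overlap(sh$a[i], sh$a[j], A, B + c(h, 0, 0)) -
           s_overlap(sh$a[i], sh$a[j], A, B - c(h, 0, 0))) / (2 * h)
    num <- num + sh$c[i] * sh$c[j] *
      (ds / (2 * sh$a[j]) + B[1] * s_overlap(sh$a[i], sh$a[j], A, B))
  }
  expect_equal(dA[1, 1, 2], num, tolerance = 1e-8)
})

test_that("near-singular overlap warns instead of failing", {
  g <- geometry(c(1L, 1L), rbind(c(0, 0, 0), c(2e-6, 0, 0)))
  expect_warning(compute_ao_integrals(g, "sto-3g"), "near-singular")
})

test_that("analytic integral derivatives match finite differences (s and p)", {
  set.seed(2)
  g <- random_distortion_set(h_chain(4, 1.7), 0.3, 1, seed = 9)[[1]]
  da <- compute_integral_derivatives(g, "sto-3g", mode = "analytic")
  df <- compute_integral_derivatives(g, "sto-3g", mode = "finite_difference")
  expect_lt(max(abs(da$d_overlap - df$d_overlap)), 1e-7)
  expect_lt(max(abs(da$d_core_h - df$d_core_h)), 1e-7)
  expect_lt(max(abs(da$d_eri - df$d_eri)), 1e-7)
  expect_lt(max(abs(da$d_e_nuc - df$d_e_nuc)), 1e-7)
  ## with p shells
  w <- water_geometry(stretch = 1.05)
  dwa <- compute_integral_derivatives(w, "6-31g", mode = "analytic")
  dwf <- compute_integral_derivatives(w, "6-31g", mode = "finite_difference")
  expect_lt(max(abs(dwa$d_overlap - dwf$d_overlap)), 1e-7)
  expect_lt(max(abs(dwa$d_core_h - dwf$d_core_h)), 1e-6)
  expect_lt(max(abs(dwa$d_eri - dwf$d_eri)), 1e-7)
  ## H2 nuclear repulsion derivative along the bond: -/+ 1/R^2
  g2 <- h_chain(2, 1.4)
  d2 <- compute_integral_derivatives(g2, "sto-3g", mode = "analytic")
  expect_equal(d2$d_e_nuc[1], 1 / 1.4^2, tolerance = 1e-12)
  expect_equal(d2$d_e_nuc[4], -1 / 1.4^2, tolerance = 1e-12)
  ## rigid translation: derivative blocks sum to zero over atoms
  nat <- 4
  dS <- da$d_overlap
  for (c in 1:3) {
    tot <- Reduce(`+`, lapply(seq_len(nat), function(a) dS[3 * (a - 1) + c, , ]))
    expect_lt(max(abs(tot)), 1e-10)
  }
  expect_error(compute_integral_derivatives(g2, "sto-3g",
                                            mode = "finite_difference",
                                            fd_step = 0), "positive")
})

test_that("Hartree-Fock on the engine's integrals matches reference values", {
  ## H2/STO-3G at 1.4 bohr: textbook RHF value
  ao <- compute_ao_integrals(h_chain(2, 1.4), "sto-3g")
  hf <- scf_rhf(ao)
  expect_true(hf$converged)
  expect_equal(hf$energy, -1.116714, tolerance = 2e-6)
  ## water/6-31G near experimental geometry: published RHF energy
  aow <- compute_ao_integrals(water_geometry(), "6-31g")
  hfw <- scf_rhf(aow)
  expect_true(hfw$converged)
  expect_equal(hfw$energy, -75.98399, tolerance = 5e-4)
})

test_that("external integral backends plug in behind the same interface", {
  g <- h_chain(2, 1.4)
  ref <- compute_ao_integrals(g, "sto-3g")
  register_integral_backend("mock", function(geom, basis_name) {
    stopifnot(basis_name == "whatever-basis")
    ref
  })
  out <- compute_ao_integrals(g, "whatever-basis", backend = "mock")
  expect_identical(out$eri, ref$eri)
  expect_error(compute_ao_integrals(g, "x", backend = "nope"), "no integral backend")
})
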