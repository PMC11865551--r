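# Eigenvector continuation core: training-set bookkeeping, exactness,
# variational bounds, observables, gradients, persistence.

h4_training <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_continuation(symmetric_stretch_series(4, c(1.4, 1.8, 2.3)),
                                   "sto-6g")
    }
    cache
  }
})

test_that("training-set construction keeps its invariants", {
  geoms <- symmetric_stretch_series(6, c(1.4, 1.9, 2.4))
  tr <- train_continuation(geoms, "sto-6g")
  N <- 3
  ov <- tr$overlap
  expect_equal(diag(ov), rep(1, N), tolerance = 1e-10)
  expect_lt(max(abs(ov - t(ov))), 1e-12)
  expect_true(all(eigen(ov, symmetric = TRUE)$values > -1e-12))
  for (a in 1:N) {
    g2aa <- tr$gamma2[[paste(a, a)]]
    s <- 0
    for (i in 1:6) for (j in 1:6) s <- s + g2aa[i, j, i, j]
    expect_equal(s, 30, tolerance = 1e-9)
    expect_equal(sum(diag(tr$gamma1[[paste(a, a)]])), 6, tolerance = 1e-9)
  }
  ## hermiticity across pairs
  expect_lt(max(abs(tr$gamma2[[paste(1, 3)]] -
                    aperm(tr$gamma2[[paste(3, 1)]], c(3, 4, 1, 2)))), 1e-10)

  ## first state alone has overlap [[1]]
  t1 <- train_continuation(geoms[1], "sto-6g")
  expect_equal(t1$overlap, matrix(1, 1, 1), tolerance = 1e-10)

  ## adding the same state twice: rank-1 overlap block, regularization copes
  fs <- fci_training_state(geoms[[1]], "sto-6g")
  expect_warning(
    t2 <- add_training_state(t1, fs$state, geoms[[1]], fs$energy),
    "duplicate")
  expect_equal(abs(t2$overlap), matrix(1, 2, 2), tolerance = 1e-9)
  sao <- solve_sao(geoms[[2]], "sto-6g")
  res <- infer_state(t2, sao)
  expect_equal(res$condition_report$retained, 1L)
})

test_that("subspace assembly: Rayleigh quotient and training-point identity", {
  tr <- h4_training()
  ## at a training geometry the diagonal reproduces the training energy
  sao1 <- solve_sao(symmetric_stretch_series(4, 1.4)[[1]], "sto-6g")
  am <- assemble_subspace_matrices(tr, sao1)
  expect_equal(am$H[1, 1], tr$energies[1], tolerance = 1e-9)
  expect_lt(max(abs(am$H - t(am$H))), 1e-10)
  expect_identical(am$S, tr$overlap)
  ## N = 1 model: inferred energy is the single-state Rayleigh quotient
  t1 <- train_continuation(symmetric_stretch_series(4, 1.8), "sto-6g")
  sao2 <- solve_sao(symmetric_stretch_series(4, 2.0)[[1]], "sto-6g")
  r1 <- infer_state(t1, sao2)
  am1 <- assemble_subspace_matrices(t1, sao2)
  expect_equal(r1$energy, am1$H[1, 1] / am1$S[1, 1], tolerance = 1e-12)
  ## L mismatch is caught
  expect_error(assemble_subspace_matrices(tr, solve_sao(h_chain(6, 1.8), "sto-6g")),
               "mismatch")
})

test_that("inference is exact at training points and variational everywhere", {
  tr <- h4_training()
  geoms <- symmetric_stretch_series(4, c(1.4, 1.8, 2.3))
  for (i in 1:3) {
    e <- continuation_energy(tr, geoms[[i]])
    expect_equal(e, tr$energies[i], tolerance = 1e-9)
  }
  grid <- seq(1.4, 2.3, length.out = 7)
  for (d in grid) {
    g <- symmetric_stretch_series(4, d)[[1]]
    sao <- solve_sao(g, "sto-6g")
    e_inf <- infer_state(tr, sao)$energy
    e_fci <- fci_ground_state(sao)[[1]]$energy
    expect_gte(e_inf, e_fci - 1e-9)
  }
})

test_that("enlarging the training set never raises the inferred energy", {
  geoms <- symmetric_stretch_series(4, c(1.4, 1.8, 2.3))
  grid <- symmetric_stretch_series(4, seq(1.3, 2.5, length.out = 9))
  saos <- lapply(grid, solve_sao, basis_name = "sto-6g")
  prev <- NULL
  for (n in 1:3) {
    tr <- train_continuation(geoms[seq_len(n)], "sto-6g")
    e <- vapply(saos, function(s) infer_state(tr, s)$energy, 0)
    if (!is.null(prev)) expect_true(all(e <= prev + 1e-9))
    prev <- e
  }
})

test_that("inferred result satisfies its structural invariants", {
  tr <- h4_training()
  sao <- solve_sao(symmetric_stretch_series(4, 2.0)[[1]], "sto-6g")
  res <- infer_state(tr, sao)
  expect_equal(res$energy, min(res$spectrum), tolerance = 1e-12)
  X <- res$coefficients
  expect_equal(as.numeric(t(X) %*% tr$overlap %*% X), 1, tolerance = 1e-10)
  expect_equal(sum(diag(res$rdm1)), 4, tolerance = 1e-8)
})

test_that("observables: symmetry, charge conservation, training-point exactness", {
  ## H2: symmetric neutral molecule -> zero dipole, zero charges
  tr2 <- train_continuation(symmetric_stretch_series(2, c(1.2, 1.6)), "sto-6g")
  g <- h_chain(2, 1.4)
  b <- build_basis(g, "sto-6g")
  ao <- compute_ao_integrals(g, b)
  lt <- lowdin_transform(ao$overlap)
  sao <- rotate_to_sao(ao, lt)
  res <- infer_state(tr2, sao)
  obs <- predict_observables(res, tr2, g, ao, lt)
  expect_lt(obs$dipole_magnitude, 1e-8)
  expect_lt(max(abs(obs$mulliken_charges)), 1e-8)
  expect_equal(sum(obs$mulliken_charges), 0, tolerance = 1e-8)

  ## asymmetric case: charges sum to the net charge; at a training geometry
  ## with exact training states the observables equal the FCI ones
  g4 <- random_distortion_set(h_chain(4, 1.7), 0.25, 1, seed = 31)[[1]]
  fs <- fci_training_state(g4, "sto-6g")
  tr4 <- add_training_state(training_set(), fs$state, g4, fs$energy,
                            basis_name = "sto-6g")
  res4 <- infer_state(tr4, fs$sao)
  obs4 <- predict_observables(res4, tr4, g4, fs$ao, fs$transform)
  expect_equal(sum(obs4$mulliken_charges), 0, tolerance = 1e-8)
  ## FCI reference: 1-RDM of the exact state
  r <- transition_rdms(fs$state, fs$state)
  rho_ao <- fs$transform$Z %*% r$gamma1 %*% t(fs$transform$Z)
  dip <- compute_dipole_integrals(g4, attr(fs$ao, "basis"))
  mu_fci <- vapply(1:3, function(c) -sum(rho_ao * dip[c, , ]), 0) +
    colSums(g4$coordinates * g4$atomic_numbers)
  expect_equal(obs4$dipole, mu_fci, tolerance = 1e-8)
  ## fragment sums
  obs4f <- predict_observables(res4, tr4, g4, fs$ao, fs$transform,
                               fragments = list(left = 1:2, right = 3:4))
  expect_equal(sum(obs4f$fragment_charges), 0, tolerance = 1e-8)
})

test_that("analytic gradients match finite differences and conserve momentum", {
  tr <- h4_training()
  gt <- random_distortion_set(symmetric_stretch_series(4, 1.9)[[1]],
                              0.15, 1, seed = 7)[[1]]
  basis <- build_basis(gt, "sto-6g")
  ao <- compute_ao_integrals(gt, basis)
  sao <- rotate_to_sao(ao, lowdin_transform(ao$overlap), n_elec = 4)
  res <- infer_state(tr, sao)
  ga <- analytic_gradient(res, tr, gt, basis, mode = "analytic")
  gf <- analytic_gradient(res, tr, gt, basis, mode = "finite_difference")
  expect_lt(max(abs(ga$gradient - gf$gradient)), 1e-6)
  expect_lt(max(abs(colSums(ga$forces))), 1e-8)
  ## component breakdown is reported
  expect_named(ga$components, c("integral", "pulay", "nuclear"))
})

test_that("the inferred H2 potential minimum has vanishing gradient", {
  tr <- train_continuation(symmetric_stretch_series(2, c(1.2, 1.5, 1.9)), "sto-6g")
  e_of_d <- function(d) continuation_energy(tr, h_chain(2, d))
  dmin <- stats::optimize(e_of_d, c(1.2, 1.9), tol = 1e-10)$minimum
  gmin <- h_chain(2, dmin)
  res <- continuation_energy(tr, gmin, detail = TRUE)
  gr <- analytic_gradient(res, tr, gmin, "sto-6g")
  ## gradient along the bond axis vanishes at the variational minimum
  expect_lt(abs(gr$gradient[1]), 1e-6)
  expect_lt(abs(gr$gradient[4]), 1e-6)
})

test_that("models round trip through JSON save/load", {
  tr <- h4_training()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(tr, path)
  tr2 <- load_model(path)
  g <- symmetric_stretch_series(4, 2.05)[[1]]
  sao <- solve_sao(g, "sto-6g")
  expect_equal(infer_state(tr2, sao)$energy, infer_state(tr, sao)$energy,
               tolerance = 1e-12)
  ## loaded models cannot be extended (no CI amplitudes on disk)
  fs <- fci_training_state(g, "sto-6g")
  expect_error(add_training_state(tr2, fs$state, g, fs$energy), "cannot be extended")
  ## truncated file: hard error, no partial model
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 500), path)
  expect_error(load_model(path), "no partial model")
  ## basis tag mismatch refused at inference
  tr3 <- tr
  tr3$basis_name <- "sto-3g"
  expect_error(infer_state(tr3, sao), "do not match")
})

test_that("inference is continuous along a smooth path", {
  tr <- h4_training()
  grid <- seq(1.5, 2.2, length.out = 15)
  e <- vapply(grid, function(d) continuation_energy(tr, h_chain(4, d)), 0)
  ## second differences stay small: no jumps beyond smooth curvature
  d2 <- diff(diff(e))
  expect_lt(max(abs(d2)), 5e-3)
  expect_true(all(is.finite(e)))
})
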